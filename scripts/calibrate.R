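#!/usr/bin/env Rscript
# Reproduces the calibration of the packaged default error model: the
# smallest (sigma_theta, sigma_step) on the grid whose PI-only median place
# stability crosses below chance within 3 minutes (iPI) and 6 minutes (aPI)
# in the standard kite arena, starting oriented at the centre.
#
# Usage: Rscript scripts/calibrate.R [--trials N] [--seed S]

suppressPackageStartupMessages({
  library(optparse)
  library(idioloc)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--trials", type = "integer", default = 100L),
  make_option("--seed", type = "integer", default = 20L)
)))

em <- calibrate_noise(target_times = list(iPI = 180, aPI = 360),
                      trials = opts$trials, master_seed = opts$seed)
cr <- attr(em, "crossings")
cat(sprintf("selected sigma_theta = %g rad*s^(-1/2) (iPI crossing %.0f s)\n",
            em$sigma_theta, cr$iPI))
cat(sprintf("selected sigma_step  = %g (aPI crossing %.0f s)\n",
            em$sigma_step, cr$aPI))
cat("packaged defaults live in default_error_model()\n")
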