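#!/usr/bin/env Rscript
# Regional covariate effects on the odds-ratio scale: refit the pooled BYM
# model with the four regional covariates (proportions aged 60+,
# overweight, ever-smokers, drinkers), in constant-effect mode and in the
# smoothly time-varying mode, and export exp(coefficient) summaries.
# The generating truth here has a known positive overweight effect.

suppressPackageStartupMessages(library(stprev))
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

truth <- chns_like_preset("bym", with_covariates = TRUE)
truth$fixed$beta_cov <- c(overweight = 1.5)
sim <- simulate_bym(truth, seed = 20260924L)

basis <- sim$basis
# constant-effect mode over all four covariates
fit_c <- run_mcmc(model_spec("bym", covariate_mode = "constant"),
                  sim$panel, basis,
                  mcmc = mcmc_config(n_iter = 12000L, burn_in = 6000L,
                                     thin = 6L, seed = 20260925L))
tab_c <- covariate_report(fit_c)
utils::write.csv(tab_c, "results/tables/covariate_or_constant.csv",
                 row.names = FALSE)
cat("\nConstant-effect odds ratios:\n")
print(tab_c, digits = 3)

# time-varying mode for the covariate of interest only; regional
# proportions offer little cross-region contrast, so a full time-varying
# expansion of all four covariates would be hopelessly confounded with
# the global trend
pan_ow <- sim$panel
pan_ow$covariates <- pan_ow$covariates["overweight"]
fit_tv <- run_mcmc(model_spec("bym", covariate_mode = "time_varying"),
                   pan_ow, basis,
                   mcmc = mcmc_config(n_iter = 12000L, burn_in = 6000L,
                                      thin = 6L, seed = 20260925L))
tab_tv <- covariate_report(fit_tv)
utils::write.csv(tab_tv, "results/tables/covariate_or_time_varying.csv",
                 row.names = FALSE)
cat("\nTime-varying overweight odds ratio by wave:\n")
print(tab_tv, digits = 3)
cat("\nTrue overweight log-odds coefficient: 1.5 (odds ratio",
    sprintf("%.2f).\n", exp(1.5)))
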