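#!/usr/bin/env Rscript
# Fit the spatio-temporal shared component model jointly for both sexes:
# posterior risk surfaces, the time-varying shared weight delta_t, the
# variance shares eta_j(t), and the DIC decomposition.

suppressPackageStartupMessages(library(stprev))
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
dir.create("results/fits", showWarnings = FALSE, recursive = TRUE)

panel <- read_panel_counts("results/data/panel_two_sex.csv", study7_graph())
basis <- build_basis(panel$waves, interior_knots = 0)
fit <- run_mcmc(model_spec("scm"), panel, basis,
                mcmc = mcmc_config(n_iter = 20000L, burn_in = 10000L,
                                   thin = 10L, seed = 20260922L))

cat(sprintf("SCM: DIC = %.1f (Dbar = %.1f, pD = %.1f), max monitored R-hat = %.3f\n",
            fit$dic[["DIC"]], fit$dic[["Dbar"]], fit$dic[["pD"]],
            max(stprev:::monitored_rhat(fit))))

surf <- summarize_risk(fit, panel, force = TRUE)
utils::write.csv(surf, "results/tables/scm_risk.csv", row.names = FALSE)

de <- delta_eta_report(fit)
utils::write.csv(de, "results/tables/scm_delta_eta.csv", row.names = FALSE)
cat("Shared weight delta_t (posterior median) by wave:\n")
print(de[, c("year", "delta_median", "delta_lo", "delta_hi")], digits = 3)
cat("Waves whose 95% interval covers the generating truth delta = 1:",
    sum(de$delta_lo <= 1 & 1 <= de$delta_hi), "of", nrow(de), "\n")
cat("Variance-share draws above 1 (anticorrelated shared/gender split):",
    sum(attr(de, "flagged")), "draw-waves flagged\n")

save_fit(fit, "results/fits/scm")
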