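#!/usr/bin/env Rscript
# Generate the survey-like synthetic panels used by the rest of the
# workflow: a two-sex shared-component panel and a pooled single-outcome
# panel on the 7-province graph and 9 waves (1991-2015), with the four
# drifting regional covariates. Writes the CSV panels, the adjacency edge
# list and the latent truth to results/data/.

suppressPackageStartupMessages(library(stprev))
seed <- 20260920L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

truth_scm <- chns_like_preset("scm", with_covariates = TRUE)
sim_scm <- simulate_scm(truth_scm, seed = seed)
truth_bym <- chns_like_preset("bym", with_covariates = TRUE)
sim_bym <- simulate_bym(truth_bym, seed = seed)

write_panel_counts(sim_scm$panel, "results/data/panel_two_sex.csv")
write_panel_counts(sim_bym$panel, "results/data/panel_pooled.csv")
write_adjacency(study7_graph(), "results/data/adjacency.txt")
saveRDS(list(scm = sim_scm, bym = sim_bym, seed = seed),
        "results/data/truth.rds")

pooled <- function(panel, t) sum(panel$O[, , t]) / sum(panel$n[, , t])
cat("Two-sex panel: pooled prevalence",
    sprintf("%.3f at 1991 rising to %.3f at 2015\n",
            pooled(sim_scm$panel, 1), pooled(sim_scm$panel, 9)))
cat("Male vs female at 2015:",
    sprintf("%.3f vs %.3f\n",
            sum(sim_scm$panel$O[1, , 9]) / sum(sim_scm$panel$n[1, , 9]),
            sum(sim_scm$panel$O[2, , 9]) / sum(sim_scm$panel$n[2, , 9])))
cat("Files written under results/data/\n")
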