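#!/usr/bin/env Rscript
# Global spatial-autocorrelation screening: Moran's I with a permutation
# test on the crude prevalence of every wave and sex, the step that
# motivates spatial modelling at all. Writes the screening table.

suppressPackageStartupMessages(library(stprev))
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

panel <- read_panel_counts("results/data/panel_two_sex.csv", study7_graph())
tab <- moran_screening(panel, n_perm = 9999, seed = 20260920L)
utils::write.csv(tab, "results/tables/moran_screening.csv",
                 row.names = FALSE)

sig <- tab[tab$p_value <= 0.1, ]
cat("Moran's I screening over", nrow(tab), "wave-sex combinations;",
    nrow(sig), "significant at the 10% level.\n")
cat("The synthetic generator's province effects are only mildly spatially",
    "structured, so most waves show weak global clustering -- in the real",
    "survey the observed clustering is what justifies the CAR priors.\n")
print(tab, digits = 3)
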