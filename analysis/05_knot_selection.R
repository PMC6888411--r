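#!/usr/bin/env Rscript
# DIC-guided forward selection of interior spline knots for the male BYM
# model: start from one knot at the centred reference year (2004 -> 0) and
# add candidate knots (the centred interior waves) only while DIC drops by
# more than 2.

suppressPackageStartupMessages(library(stprev))
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

panel <- read_panel_counts("results/data/panel_two_sex.csv", study7_graph())
pan <- panel_one_sex(panel, "m")

res <- forward_knot_selection(
  pan, model_spec("bym"),
  fit_fn = fit_dic_fn(mcmc = mcmc_config(seed = 20260923L)),
  dic_drop_threshold = 2)

utils::write.csv(res$trace, "results/tables/knot_selection_trace.csv",
                 row.names = FALSE)
cat("Chosen interior knots (centred years):",
    paste(res$knots, collapse = ", "), "\n")
cat("DIC trace:\n")
print(res$trace)
cat("The generating truth uses a single knot at 0; extra knots appear",
    "when the desk-scale DIC estimate rewards the added region-level",
    "spline flexibility by more than the threshold.\n")
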