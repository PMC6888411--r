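#' Region-by-wave binomial prevalence panel
#'
#' Container for the modelled data: hypertension-style case counts `O` and
#' denominators `n` indexed by sex (1 for single-outcome BYM fits, 2 for the
#' shared component model), region and wave, with optional regional
#' covariates (proportions in `[0, 1]`, constant across sexes).
#'
#' @param graph a [region_graph()].
#' @param waves ordered calendar years.
#' @param O integer array of cases. Either `N x T` (single sex) or
#'   `2 x N x T` (`j = 1` male, `j = 2` female).
#' @param n totals array, same shape as `O`, all entries `>= 1`.
#' @param sexes labels: `"all"` for a single-outcome panel, or
#'   `c("m", "f")`.
#' @param covariates optional named list of `N x T` matrices of regional
#'   proportions (e.g. `age60plus`, `overweight`, `ever_smoker`, `drinker`).
#' @return object of class `panel_counts` with fields `graph`, `waves`,
#'   `sexes`, `n_sexes`, `O` and `n` (always `n_sexes x N x T` arrays) and
#'   `covariates`.
#' @export
panel_counts <- function(graph, waves, O, n, sexes = "all",
                         covariates = NULL) {
  stopifnot(inherits(graph, "region_graph"))
  N <- graph$n_regions
  T_ <- length(waves)
  if (is.unsorted(waves, strictly = TRUE)) stop("waves must be increasing")
  sexes <- as.character(sexes)
  if (!identical(sexes, "all") && !identical(sexes, c("m", "f"))) {
    stop("sexes must be 'all' or c('m', 'f')")
  }
  J <- length(sexes)
  to3d <- function(x, what) {
    if (length(dim(x)) == 2L) {
      if (J != 1L) stop(what, " is 2-d but panel has two sexes")
      x <- array(x, dim = c(1L, nrow(x), ncol(x)))
    }
    if (!identical(dim(x), c(J, N, T_))) {
      stop(what, " must be ", J, " x ", N, " x ", T_, " (sex x region x wave)")
    }
    storage.mode(x) <- "double"
    x
  }
  O <- to3d(O, "O"); n <- to3d(n, "n")
  if (any(n < 1)) stop("all totals must be >= 1")
  if (any(O < 0) || any(O > n)) stop("need 0 <= O <= n elementwise")
  if (any(O != round(O)) || any(n != round(n))) {
    stop("O and n must be integer-valued")
  }
  if (!is.null(covariates)) {
    if (is.null(names(covariates)) || any(!nzchar(names(covariates)))) {
      stop("covariates must be a named list")
    }
    for (nm in names(covariates)) {
      x <- covariates[[nm]]
      if (!is.matrix(x) || !identical(dim(x), c(N, T_))) {
        stop("covariate '", nm, "' must be an N x T matrix")
      }
      if (any(x < 0 | x > 1)) {
        stop("covariate '", nm, "' must hold proportions in [0, 1]")
      }
    }
  }
  structure(
    list(graph = graph, waves = as.numeric(waves), sexes = sexes,
         n_sexes = J, O = O, n = n, covariates = covariates),
    class = "panel_counts"
  )
}

#' @export
print.panel_counts <- function(x, ...) {
  cat("<panel_counts> ", x$graph$n_regions, " regions x ",
      length(x$waves), " waves, sexes: ", paste(x$sexes, collapse = "/"),
      if (!is.null(x$covariates))
        paste0(", covariates: ", paste(names(x$covariates), collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Read a prevalence panel from CSV
#'
#' Long format, one row per region-year(-sex): mandatory columns `region`,
#' `year`, `sex` (`m`/`f`/`all`), `cases`, `total`; any further columns are
#' treated as regional covariates and must agree across sexes within a
#' region-year. Region order follows `graph`; every region-year(-sex) cell
#' must be present exactly once.
#'
#' @param path CSV path.
#' @param graph a [region_graph()] fixing the region set and order.
#' @return a [panel_counts()].
#' @export
read_panel_counts <- function(path, graph) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("region", "year", "sex", "cases", "total")
  if (!all(need %in% names(df))) {
    stop("panel CSV must have columns: ", paste(need, collapse = ", "),
         "; missing: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  extra <- setdiff(names(df), need)
  unknown <- setdiff(unique(df$region), graph$region_ids)
  if (length(unknown)) {
    stop("CSV regions not in graph: ", paste(unknown, collapse = ", "))
  }
  if (!all(graph$region_ids %in% df$region)) {
    stop("CSV missing regions: ",
         paste(setdiff(graph$region_ids, df$region), collapse = ", "))
  }
  waves <- sort(unique(df$year))
  sexes <- sort(unique(df$sex))
  if (identical(sexes, "all")) sexes <- "all"
  else if (setequal(sexes, c("m", "f"))) sexes <- c("m", "f")
  else stop("sex column must be all 'all', or the pair 'm'/'f'")
  N <- graph$n_regions; T_ <- length(waves); J <- length(sexes)
  O <- array(NA_real_, c(J, N, T_)); n <- array(NA_real_, c(J, N, T_))
  covs <- if (length(extra)) {
    stats::setNames(lapply(extra, function(e) matrix(NA_real_, N, T_)), extra)
  } else NULL
  for (r in seq_len(nrow(df))) {
    i <- match(df$region[r], graph$region_ids)
    t <- match(df$year[r], waves)
    j <- match(df$sex[r], sexes)
    if (!is.na(O[j, i, t])) {
      stop("duplicate row for ", df$region[r], "/", df$year[r], "/",
           df$sex[r])
    }
    O[j, i, t] <- df$cases[r]; n[j, i, t] <- df$total[r]
    for (e in extra) {
      v <- df[[e]][r]
      if (!is.na(covs[[e]][i, t]) && abs(covs[[e]][i, t] - v) > 1e-12) {
        stop("covariate '", e, "' disagrees across sexes for ",
             df$region[r], "/", df$year[r])
      }
      covs[[e]][i, t] <- v
    }
  }
  if (anyNA(O) || anyNA(n)) stop("panel CSV has missing region-year-sex cells")
  panel_counts(graph, waves, O, n, sexes = sexes, covariates = covs)
}

#' Write a prevalence panel to CSV
#'
#' Inverse of [read_panel_counts()]; numeric covariates are written with 12
#' significant digits so the file round-trips exactly at that precision.
#'
#' @param panel a [panel_counts()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_counts <- function(panel, path) {
  stopifnot(inherits(panel, "panel_counts"))
  rows <- expand.grid(
    sex = panel$sexes,
    region = panel$graph$region_ids,
    year = panel$waves,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  j <- match(rows$sex, panel$sexes)
  i <- match(rows$region, panel$graph$region_ids)
  t <- match(rows$year, panel$waves)
  df <- data.frame(region = rows$region, year = rows$year, sex = rows$sex,
                   cases = as.integer(panel$O[cbind(j, i, t)]),
                   total = as.integer(panel$n[cbind(j, i, t)]),
                   stringsAsFactors = FALSE)
  for (nm in names(panel$covariates)) {
    df[[nm]] <- signif(panel$covariates[[nm]][cbind(i, t)], 12)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract one sex from a two-sex panel
#'
#' The BYM model is fitted separately per sex; this carves the single-sex
#' panel out of an SCM-style two-sex panel.
#'
#' @param panel a two-sex [panel_counts()].
#' @param sex `"m"` or `"f"`.
#' @return single-sex [panel_counts()] (with `sexes = "all"`).
#' @export
panel_one_sex <- function(panel, sex) {
  stopifnot(inherits(panel, "panel_counts"), panel$n_sexes == 2L)
  j <- match(sex, panel$sexes)
  if (is.na(j)) stop("sex must be one of: ", paste(panel$sexes, collapse = ", "))
  panel_counts(panel$graph, panel$waves,
               O = panel$O[j, , , drop = TRUE],
               n = panel$n[j, , , drop = TRUE],
               sexes = "all", covariates = panel$covariates)
}
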