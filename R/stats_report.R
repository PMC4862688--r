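# Rank-correlation analysis linking permutant properties to misfolding
# populations, binomial population errors, report assembly.

#' Spearman rank correlation with mid-rank ties
#'
#' Fractional (mid) ranks are assigned to ties and the Pearson correlation
#' of the ranks is returned.  Mid-ranking matters: tied populations are
#' common in misfolding statistics and alter the coefficient.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return rho in `[-1, 1]`, or `NA` (with a warning) when an input is
#'   constant.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warn("constant input: rank correlation undefined")
    return(NA_real_)
  }
  cor(rank(x), rank(y))
}

#' Population fractions with binomial standard errors
#'
#' @param outcomes a tibble with a `final_label` column (e.g. from
#'   [first_passage_campaign()]), or a named count vector.
#' @param n total number of trials (defaults to the number of rows).
#' @param all_labels optional label set to report (zero counts included).
#' @return tibble: `label`, `count`, `fraction`, `se`
#'   (`se = sqrt(p (1 - p) / n)`).
#' @export
population_summary <- function(outcomes, n = NULL, all_labels = NULL) {
  counts <- if (is.data.frame(outcomes)) {
    table(outcomes$final_label)
  } else {
    outcomes
  }
  n <- n %||% sum(counts)
  labels <- all_labels %||% names(counts)
  cnt <- as.integer(counts[labels])
  cnt[is.na(cnt)] <- 0L
  p <- cnt / n
  tibble(label = labels, count = cnt, fraction = p,
         se = sqrt(p * (1 - p) / n))
}

#' Packaged reference misfolding statistics
#'
#' Per-protein, per-fold reference values (relative contact order, folding
#' barrier, stability, and end-of-campaign population) for seven tandem
#' repeat proteins -- SH3, PDZ, TNfn3, UBQ, SH2, Titin I27 and GB1 -- from
#' published coarse-grained misfolding campaigns of 1024 trajectories.
#' K = 0 is the native fold; K > 0 labels circular-permutant misfolds by
#' their cut position.
#'
#' @return tibble: `protein`, `K`, `rco`, `dG_f`, `dG_s`, `population`.
#' @export
misfolding_reference <- function() {
  path <- system.file("extdata", "misfolding_reference.tsv",
                      package = "swapfold")
  as_tibble(read.delim(path, sep = "\t"))
}

#' Rank correlations between permutant properties and populations
#'
#' For each protein with at least `min_states` folds, the Spearman
#' correlation (mid-rank ties) of each of RCO, dG_f and dG_s against the
#' final population.  Values are full precision; round only for display.
#'
#' @param table a propensity table as returned by [misfolding_reference()]
#'   (columns `protein`, `K`, `rco`, `dG_f`, `dG_s`, `population`).
#' @param min_states minimum number of folds per protein.
#' @return tibble: `protein`, `n_states`, `rho_rco`, `rho_dGf`, `rho_dGs`.
#' @export
correlation_report <- function(table, min_states = 3) {
  table %>%
    group_by(.data$protein) %>%
    filter(n() >= min_states) %>%
    summarise(
      n_states = n(),
      rho_rco = spearman_rho(.data$rco, .data$population),
      rho_dGf = spearman_rho(.data$dG_f, .data$population),
      rho_dGs = spearman_rho(.data$dG_s, .data$population),
      .groups = "drop"
    )
}
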