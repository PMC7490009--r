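#' @title Per-cell aggregation and condition comparison
#' @name cell_stats
#' @description
#' Translation sites are aggregated into a per-cell colocalized fraction
#' (associated mRNAs / cytoplasmic mRNAs). Cells enter the condition-level
#' analysis only if they contain more than five and fewer than 36 mRNAs,
#' i.e. 6-35 inclusive; conditions are summarized as mean with standard
#' error of the mean over included cells and compared by a two-sample
#' t-test (Welch by default).
NULL

#' Summarize one cell
#'
#' @param sites data.frame of quantified translation sites for one cell
#'   (one row per cytoplasmic mRNA, with an `associated` column).
#' @param cell_id identifier carried through.
#' @param condition condition name carried through.
#' @return One-row data.frame: `cell_id`, `condition`, `n_mRNA`,
#'   `n_associated`, `fraction` (NA when the cell has no mRNAs), and the
#'   `included` flag.
#' @export
cell_summary <- function(sites, cell_id, condition) {
  n <- nrow(sites)
  n_assoc <- if (n == 0) 0L else sum(sites$associated, na.rm = TRUE)
  data.frame(
    cell_id = cell_id,
    condition = condition,
    n_mRNA = n,
    n_associated = n_assoc,
    fraction = if (n == 0) NA_real_ else n_assoc / n,
    included = n > 5 && n < 36
  )
}

#' Summarize one condition over included cells
#'
#' @param cells data.frame of [cell_summary()] rows for one condition.
#' @return List: `condition`, `n_cells` (included), `mean_fraction`,
#'   `sem` (sample SD / sqrt(n_cells)).
#' @export
condition_summary <- function(cells) {
  inc <- cells[cells$included & !is.na(cells$fraction), , drop = FALSE]
  if (nrow(inc) < 2)
    stop("condition summary needs at least 2 included cells, got ",
         nrow(inc))
  f <- inc$fraction
  list(condition = unique(inc$condition)[1],
       n_cells = nrow(inc),
       mean_fraction = mean(f),
       sem = stats::sd(f) / sqrt(length(f)))
}

#' Two-sample t-test between per-cell fractions
#'
#' Welch's unequal-variance test by default (`var_equal = TRUE` gives the
#' pooled-variance Student test), two-sided. Degenerate inputs are handled
#' explicitly: two zero-variance samples with equal means give `t = 0,
#' p = 1`; zero variance with unequal means is an error.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @param var_equal use the pooled-variance variant.
#' @return List with `t` and `p`.
#' @export
two_sample_ttest <- function(a, b, var_equal = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) return(list(t = 0, p = 1))
    stop("degenerate t-test: zero variance in both samples with unequal ",
         "means")
  }
  ht <- stats::t.test(a, b, var.equal = var_equal,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), p = unname(ht$p.value))
}

#' All pairwise condition comparisons
#'
#' @param cells data.frame of [cell_summary()] rows across conditions.
#' @param var_equal passed to [two_sample_ttest()].
#' @return data.frame with one row per condition pair: names, t, p.
#' @export
pairwise_condition_tests <- function(cells, var_equal = FALSE) {
  inc <- cells[cells$included & !is.na(cells$fraction), , drop = FALSE]
  conds <- unique(inc$condition)
  if (length(conds) < 2) return(data.frame())
  pairs <- utils::combn(conds, 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- inc$fraction[inc$condition == pairs[1, i]]
    b <- inc$fraction[inc$condition == pairs[2, i]]
    tt <- two_sample_ttest(a, b, var_equal)
    data.frame(condition_a = pairs[1, i], condition_b = pairs[2, i],
               t = tt$t, p = tt$p)
  }))
}
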