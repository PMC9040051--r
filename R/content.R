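# Gene-content statistics: subgenome bias with exact binomial CIs,
# background-normalized bias, and duplicate-retention chi-square tests.

#' Subgenome gene-content bias with exact binomial statistics
#'
#' For paternal and maternal subgenome gene counts, computes
#' `delta = (n_pat - n_mat) / (n_pat + n_mat)` (the difference between the
#' paternal and maternal proportions), the Clopper-Pearson exact 95% CI on
#' the paternal proportion transformed to the delta scale (`2p - 1`), and
#' the two-sided exact binomial p-value against equal content.
#'
#' @param n_pat,n_mat Gene counts on the paternal and maternal subgenomes.
#' @return Object of class `bias_result`: `delta`, `ci95`, `p`, and the
#'   underlying counts.
#' @export
subgenome_bias <- function(n_pat, n_mat) {
  n <- n_pat + n_mat
  if (n <= 0) stop("n_pat + n_mat must be positive")
  bt <- stats::binom.test(n_pat, n, 0.5)
  structure(list(n_pat = n_pat, n_mat = n_mat,
                 delta = (n_pat - n_mat) / n,
                 ci95 = as.numeric(2 * bt$conf.int - 1),
                 p = bt$p.value),
            class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf("subgenome bias: delta = %.3f (95%% CI %.3f to %.3f), p = %.3g\n",
              x$delta, x$ci95[1], x$ci95[2], x$p))
  invisible(x)
}

#' Gene-content bias relative to the genome-wide background
#'
#' Tests a category's paternal proportion against the paternal proportion
#' of the non-organelle-targeted (NOT) genes rather than against 0.5,
#' using the exact (Fisher) two-proportion test, and reports the direction
#' of the difference.
#'
#' @param category,not `bias_result`s for the category and background.
#' @return List: `direction` (`"paternal"`, `"maternal"` or `"none"`),
#'   `difference` (category minus background paternal proportion), `p`.
#' @export
normalized_bias <- function(category, not) {
  tabm <- rbind(c(category$n_pat, category$n_mat),
                c(not$n_pat, not$n_mat))
  ft <- stats::fisher.test(tabm)
  d <- category$n_pat / (category$n_pat + category$n_mat) -
    not$n_pat / (not$n_pat + not$n_mat)
  list(direction = if (d > 0) "paternal" else if (d < 0) "maternal"
       else "none",
       difference = d, p = ft$p.value)
}

#' Duplicate-retention test against the background
#'
#' Pearson chi-square (1 df, no continuity correction) of a category's
#' retained-duplicate vs single-copy counts against the
#' non-organelle-targeted background, with the direction of departure.
#' A warning flag is raised when any expected cell count is below 1.
#'
#' @param category_retained,category_single Category counts.
#' @param not_retained,not_single Background counts.
#' @return List: `chisq`, `p`, `direction` (+1 category retention above
#'   background, -1 below, 0 equal), `low_expected` flag.
#' @export
retention_test <- function(category_retained, category_single,
                           not_retained, not_single) {
  tabm <- rbind(c(category_retained, category_single),
                c(not_retained, not_single))
  expected <- outer(rowSums(tabm), colSums(tabm)) / sum(tabm)
  low <- any(expected < 1)
  ct <- suppressWarnings(stats::chisq.test(tabm, correct = FALSE))
  r_cat <- category_retained / (category_retained + category_single)
  r_not <- not_retained / (not_retained + not_single)
  list(chisq = unname(ct$statistic), p = ct$p.value,
       direction = sign(r_cat - r_not), low_expected = low)
}
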