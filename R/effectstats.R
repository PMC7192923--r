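## Cliff's delta effect sizes and the shared nonparametric tests.

# Rank-based Cliff's delta, equivalent to full pairwise enumeration
# (ties count one half each way).
cliffs_delta_rank <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y), ties.method = "average")
  rx <- sum(r[seq_len(m)])
  # rx - m(m+1)/2 = #(x > y) + 0.5 #(x == y) over all pairs
  wins <- rx - m * (m + 1) / 2
  (2 * wins - m * n) / (m * n)
}

# Brute-force pairwise Cliff's delta; the testing oracle.
cliffs_delta_brute <- function(x, y) {
  mean(sign(outer(x, y, "-")))
}

#' Effect-size bin for a Cliff's delta value
#'
#' Thresholds on |d|: negligible below 0.147, small up to 0.33, medium up
#' to 0.474, large above 0.474. Boundary values fall in the lower bin
#' (the published inequalities are strict).
#'
#' @param d Cliff's delta value(s), in [-1, 1].
#' @return Character vector of bin labels.
#' @export
effect_size_bin <- function(d) {
  a <- abs(d)
  ifelse(a > 0.474, "large",
         ifelse(a > 0.33, "medium",
                ifelse(a > 0.147, "small", "negligible")))
}

#' Cliff's delta effect size
#'
#' `d = (#(x_i > y_j) - #(x_i < y_j)) / (|x| * |y|)` over all pairs,
#' computed by a rank-based method exactly equivalent to pairwise
#' enumeration (ties contribute zero).
#'
#' @param x,y Non-empty numeric samples.
#' @param method `"rank"` (default, O((m+n) log(m+n))) or `"brute"`
#'   (explicit pairwise enumeration, for verification).
#' @return A list: `d`, `bin` (see [effect_size_bin()]), `n_x`, `n_y`.
#' @export
cliffs_delta <- function(x, y, method = c("rank", "brute")) {
  method <- match.arg(method)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  d <- if (method == "rank") cliffs_delta_rank(x, y)
       else cliffs_delta_brute(x, y)
  list(d = d, bin = effect_size_bin(d), n_x = length(x), n_y = length(y))
}

#' Paired signed-rank or unpaired rank-sum test
#'
#' Two-sided Wilcoxon tests as used throughout the analyses: signed-rank
#' for paired samples, rank-sum for independent samples. Exact p-values
#' are used for small samples without ties and the normal approximation
#' otherwise (the switch point is the stats-package default, n = 50).
#'
#' @param x,y Numeric samples (equal length when `paired`).
#' @param paired Logical.
#' @return A list: `p` (NA, flagged, for the degenerate all-ties paired
#'   case), `test` name, `defined` flag.
#' @export
paired_and_unpaired_tests <- function(x, y, paired = FALSE) {
  test <- if (paired) "wilcoxon_signed_rank" else "wilcoxon_rank_sum"
  if (paired) {
    stopifnot(length(x) == length(y))
    if (all(x == y))
      return(list(p = NA_real_, test = test, defined = FALSE))
  }
  p <- suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                           exact = NULL)$p.value)
  list(p = p, test = test, defined = !is.na(p))
}

#' Group comparison report
#'
#' Combines the rank test and Cliff's delta for a two-group comparison,
#' the summary used for every feature contrast in the pipeline.
#'
#' @param x,y Numeric samples.
#' @param paired Logical.
#' @return A list: `p`, `test`, `d`, `bin`.
#' @export
effect_report <- function(x, y, paired = FALSE) {
  tst <- paired_and_unpaired_tests(x, y, paired)
  cd <- cliffs_delta(x, y)
  list(p = tst$p, test = tst$test, d = cd$d, bin = cd$bin)
}
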