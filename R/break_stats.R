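#' Break-calling threshold from a control distance distribution
#'
#' In a break-apart assay the two probe signals of an intact allele sit a
#' few hundred nm apart; the upper quantile (default the 99th) of the
#' control (untreated) pair-distance distribution defines the threshold
#' above which an allele is called broken. The linear-interpolation
#' quantile estimator (type 7, the common scientific-software default) is
#' used.
#'
#' @param control_distances pair distances (nm) from control cells.
#' @param q quantile in `(0, 1)`, default 0.99.
#' @return Threshold in nm.
#' @export
broken_threshold <- function(control_distances, q = 0.99) {
  control_distances <- control_distances[!is.na(control_distances)]
  if (length(control_distances) == 0L) stop("broken_threshold: no control distances")
  if (length(control_distances) < 10L)
    warning("broken_threshold: fewer than 10 control distances; threshold is unreliable")
  stopifnot(q > 0, q < 1)
  stats::quantile(control_distances, probs = q, type = 7, names = FALSE)
}

#' Classify alleles as broken by distance threshold
#'
#' An allele is called broken when its pair distance strictly exceeds the
#' threshold; equality is an intact call (the threshold is a quantile of
#' the control distribution, which contains the boundary).
#'
#' @param distances pair distances (nm).
#' @param threshold_nm threshold from [broken_threshold()] (positive).
#' @return A `break_call_set`: list with `threshold_nm`, `calls` (logical
#'   per allele) and `broken_fraction` (`mean(calls)`).
#' @export
classify_broken <- function(distances, threshold_nm) {
  stopifnot(threshold_nm > 0)
  calls <- distances > threshold_nm
  structure(list(threshold_nm = threshold_nm, calls = calls,
                 broken_fraction = mean(calls)),
            class = "break_call_set")
}

#' Empirical tail-significance test (k-sigma rule)
#'
#' Tests whether the tail of an empirical distribution has strictly
#' positive probability measure. With observed tail proportion `P*` out of
#' `n` points, the true P differs from `P*` by at most
#' `x = k * sigma / sqrt(n)` where `sigma = sqrt(P (1 - P))` and P is
#' approximated by the plug-in `P*`. If the margin `P* - x` is positive,
#' the tail is non-empty with reliability > 0.997 at the default `k = 3`
#' (the three-sigma rule).
#'
#' @param p_star observed tail proportion in `[0, 1]`.
#' @param n number of observations (positive).
#' @param k_sigma sigma multiplier (default 3).
#' @return A `tail_test_result`: list with `p_star`, `n`, `sigma`, `x`,
#'   `margin` and `significant` (`margin > 0`).
#' @export
tail_test <- function(p_star, n, k_sigma = 3) {
  if (p_star < 0 || p_star > 1) stop("tail_test: p_star must be in [0, 1]")
  stopifnot(n > 0, k_sigma > 0)
  sigma <- sqrt(p_star * (1 - p_star))
  x <- k_sigma * sigma / sqrt(n)
  margin <- p_star - x
  structure(list(p_star = p_star, n = n, k_sigma = k_sigma,
                 sigma = sigma, x = x, margin = margin,
                 significant = margin > 0),
            class = "tail_test_result")
}

#' @export
print.tail_test_result <- function(x, ...) {
  cat(sprintf("tail test: P* = %.4g (n = %d), x = %.4g, margin = %.4g -> %s\n",
              x$p_star, as.integer(x$n), x$x, x$margin,
              if (x$significant) "tail non-empty (significant)" else "not significant"))
  invisible(x)
}

#' Chi-square association between break status and territory localisation
#'
#' Pearson chi-square (df = 1, no continuity correction by default) on a
#' 2x2 table with groups in the rows (e.g. broken vs intact alleles) and
#' localisation in the columns (outside vs inside the chromosome
#' territory, in that order). The statistic is computed from the 2x2
#' closed form `N (ad - bc)^2 / (r1 r2 c1 c2)`. The fold ratio is the
#' outside proportion of row 1 over that of row 2.
#'
#' @param counts 2x2 matrix or table of non-negative counts; rows are the
#'   groups being compared, column 1 is "outside".
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @return List with `statistic`, `df` (1), `p_value`, `fold` and the
#'   input `table`.
#' @export
territory_association <- function(counts, correct = FALSE) {
  tbl <- as.matrix(counts)
  if (!all(dim(tbl) == c(2L, 2L))) stop("territory_association: counts must be 2x2")
  if (any(tbl < 0)) stop("territory_association: negative counts")
  rs <- rowSums(tbl); cs <- colSums(tbl); n <- sum(tbl)
  if (any(rs == 0) || any(cs == 0))
    stop("territory_association: a zero row or column sum makes the test undefined")
  delta <- abs(tbl[1, 1] * tbl[2, 2] - tbl[1, 2] * tbl[2, 1])
  if (correct) delta <- max(0, delta - n / 2)
  stat <- n * delta^2 / (rs[1] * rs[2] * cs[1] * cs[2])
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  fold <- (tbl[1, 1] / rs[1]) / (tbl[2, 1] / rs[2])
  list(statistic = unname(stat), df = 1L, p_value = unname(p),
       fold = unname(fold), table = tbl, correct = correct)
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two groups
#'
#' Used to compare 4C-seq signal over translocation-partner genes with the
#' signal over other genes. The exact null distribution is used for small
#' samples (smaller group of at most 8) without ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @param alternative `"two.sided"` (default) or `"greater"` (`group_a`
#'   stochastically larger).
#' @return List with `U` (the rank-sum statistic for `group_a`),
#'   `p_value` and `exact` (whether the exact distribution was used).
#' @export
mann_whitney <- function(group_a, group_b,
                         alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- !ties && min(length(group_a), length(group_b)) <= 8L
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            alternative = alternative,
                                            exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}
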