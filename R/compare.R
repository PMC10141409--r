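#' Two-sample permutation test for a difference in means
#'
#' Two-sided test of the difference in group means. With
#' `exact = TRUE` (the default whenever the number of distinct group
#' assignments does not exceed `n_permutations`) every assignment is
#' enumerated and the p-value is the exact proportion of assignments with
#' `|statistic| >= |observed|`. Otherwise `n_permutations` random
#' reassignments are drawn and the add-one estimate
#' `p = (1 + #extreme) / (n_permutations + 1)` is reported. The test is
#' distribution-free, which suits the skewed per-segment NRMS
#' populations it is used on.
#'
#' @param group_a,group_b numeric vectors (>= 3 values each).
#' @param n_permutations number of random permutations (or enumeration
#'   budget for the exact decision).
#' @param seed integer seed for the random permutations.
#' @param exact force or forbid exhaustive enumeration; `NULL` decides
#'   automatically.
#' @return A list of class `ferro_perm`: `statistic` (mean(a) − mean(b)),
#'   `p_value`, `n_permutations` (permutations actually used), `exact`,
#'   `seed`, `group_sizes`.
#' @export
permutation_test <- function(group_a, group_b, n_permutations = 1e4,
                             seed = 0, exact = NULL) {
  a <- as.numeric(group_a)
  b <- as.numeric(group_b)
  if (length(a) < 3 || length(b) < 3) {
    abort("each group needs at least 3 values.",
          class = "ferrotrace_invalid_parameter")
  }
  na <- length(a)
  pool <- c(a, b)
  n <- length(pool)
  obs <- mean(a) - mean(b)
  tol <- 1e-12 * max(1, abs(obs))
  n_comb <- choose(n, na)
  if (is.null(exact)) exact <- n_comb <= n_permutations
  if (exact) {
    idx <- utils::combn(n, na)
    tot <- sum(pool)
    sa <- colSums(matrix(pool[idx], nrow = na))
    stat <- sa / na - (tot - sa) / (n - na)
    p <- mean(abs(stat) >= abs(obs) - tol)
    used <- ncol(idx)
  } else {
    B <- as.integer(n_permutations)
    count <- withr::with_seed(seed, {
      cnt <- 0L
      for (i in seq_len(B)) {
        ia <- sample.int(n, na)
        sa <- sum(pool[ia])
        stat <- sa / na - (sum(pool) - sa) / (n - na)
        if (abs(stat) >= abs(obs) - tol) cnt <- cnt + 1L
      }
      cnt
    })
    p <- (1 + count) / (B + 1)
    used <- B
  }
  structure(
    list(statistic = obs, p_value = p, n_permutations = used,
         exact = exact, seed = seed, group_sizes = c(na, n - na)),
    class = "ferro_perm")
}

#' @export
print.ferro_perm <- function(x, ...) {
  cat(sprintf(
    "Permutation test (difference of means): stat = %.6g, p = %.4g (%s, %d permutations, n = %d + %d)\n",
    x$statistic, x$p_value, if (x$exact) "exact" else "sampled",
    x$n_permutations, x$group_sizes[1], x$group_sizes[2]))
  invisible(x)
}

# Frozen default classification thresholds: midpoints between the apo and
# holo preset population means of the two features (per-trace NRMS of the
# 1 kHz-filtered trapped segment, and the deltaT/T0 step ratio).
.default_thresholds <- list(nrms = 0.0063, ratio = 0.06025)

#' Default isoform classification thresholds
#'
#' Midpoints between the apo- and holo-preset population means of the two
#' discriminating features: NRMS of the filtered trapped segment and the
#' step ratio deltaT/T0.
#' @return Named list with elements `nrms` and `ratio`.
#' @export
default_thresholds <- function() .default_thresholds

#' Classify a ferritin isoform from trace features
#'
#' Applies the two-parameter decision rule: a holo-ferritin produces a
#' *smaller* NRMS (rigid, mineral-stabilised shell) and a *larger*
#' fractional transmission step deltaT/T0 (larger, more polarizable
#' particle). The call is `"holo"` only if both features agree, `"apo"`
#' only if both are reversed, otherwise (including exact threshold ties)
#' `"undetermined"`.
#'
#' @param summary a one-row data frame or named list with elements `nrms`
#'   and `ratio`.
#' @param thresholds named list with `nrms` and `ratio` thresholds.
#' @return One-row tibble: `label`, `nrms`, `ratio`, `thr_nrms`,
#'   `thr_ratio`.
#' @export
classify_isoform <- function(summary, thresholds = default_thresholds()) {
  if (is.data.frame(summary)) summary <- as.list(summary[1, ])
  if (is.null(summary$nrms) || is.null(summary$ratio) ||
      is.na(summary$nrms) || is.na(summary$ratio)) {
    abort("`summary` must provide `nrms` and `ratio`.",
          class = "ferrotrace_invalid_parameter")
  }
  lab <- if (summary$nrms < thresholds$nrms && summary$ratio > thresholds$ratio) {
    "holo"
  } else if (summary$nrms > thresholds$nrms && summary$ratio < thresholds$ratio) {
    "apo"
  } else "undetermined"
  tibble(label = lab, nrms = summary$nrms, ratio = summary$ratio,
         thr_nrms = thresholds$nrms, thr_ratio = thresholds$ratio)
}
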