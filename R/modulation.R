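#' Cohen's d between two activity traces
#'
#' `(mean(after) - mean(before)) / pooled SD` with the usual pooled
#' standard deviation.
#'
#' @param before,after numeric traces (e.g. dF/F0 before and after a drug).
#' @return Cohen's d.
#' @export
cohens_d <- function(before, after) {
  n1 <- length(before)
  n2 <- length(after)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * var(before) + (n2 - 1) * var(after)) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled standard deviation")
  (mean(after) - mean(before)) / sqrt(sp2)
}

#' Call a drug-induced change in activity level
#'
#' Effect size is Cohen's d of `after` vs `before`; significance comes from
#' a permutation test that shuffles individual datapoints between the two
#' traces (`n_perm` shuffles, default 1000) to build the null distribution
#' of mean differences; the two-sided p-value uses the add-one estimator.
#' A neuron is called modulated when `p < alpha` (default 0.01) and
#' `|d| > d_min` (default 0.2, a small effect size); the direction is the
#' sign of d. The modulation index is the relative change
#' `(mean(after) - mean(before)) / mean(before)` (guarded near zero
#' baselines). An optional block permutation (contiguous blocks of
#' `block_s` seconds) is available for autocorrelated traces but is off by
#' default.
#'
#' @param before,after numeric traces.
#' @param n_perm number of permutations (>= 100).
#' @param alpha significance level.
#' @param d_min minimum absolute effect size.
#' @param seed integer seed for the permutations.
#' @param block_s block length in seconds for block permutation
#'   (NULL = plain datapoint shuffling).
#' @param rate sampling rate in Hz, required when `block_s` is set.
#' @return an object of class `modulation_call`: list with `cohen_d`,
#'   `p_value`, `direction` (`"increase"`, `"decrease"` or `"none"`) and
#'   `modulation_index`.
#' @export
modulation_call <- function(before, after, n_perm = 1000, alpha = 0.01,
                            d_min = 0.2, seed = 1L, block_s = NULL,
                            rate = NULL) {
  stopifnot(length(before) >= 2, length(after) >= 2, n_perm >= 100)
  d <- cohens_d(before, after)
  obs <- mean(after) - mean(before)
  pooled <- c(before, after)
  n <- length(pooled)
  n_b <- length(before)
  total <- sum(pooled)

  null_diff <- with_seed(seed, {
    if (is.null(block_s)) {
      perm_mean_diffs(pooled, n_b, n_perm)
    } else {
      stopifnot(!is.null(rate))
      bl <- max(1L, round(block_s * rate))
      block_id <- (seq_len(n) - 1L) %/% bl
      blocks <- split(seq_len(n), block_id)
      vapply(seq_len(n_perm), function(i) {
        idx <- unlist(blocks[sample.int(length(blocks))], use.names = FALSE)
        s_b <- sum(pooled[idx[seq_len(n_b)]])
        (total - s_b) / (n - n_b) - s_b / n_b
      }, 0)
    }
  })
  p <- (1 + sum(abs(null_diff) >= abs(obs))) / (n_perm + 1)
  direction <- if (p < alpha && abs(d) > d_min) {
    if (d > 0) "increase" else "decrease"
  } else {
    "none"
  }
  mb <- mean(before)
  mi <- obs / (if (abs(mb) > 1e-9) mb else 1e-9)
  structure(list(cohen_d = d, p_value = p, direction = direction,
                 modulation_index = mi),
            class = "modulation_call")
}
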