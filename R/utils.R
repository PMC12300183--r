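# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Format a p-value, reporting underflow as a floor rather than 0
#'
#' Double precision cannot represent p-values below about 2.2e-16; a global
#' test on thousands of proteins routinely underflows.  The floor label is
#' what should be printed, never a literal zero.
#'
#' @param p numeric p-value (possibly 0 after underflow).
#' @param floor smallest p-value reported verbatim.
#' @return character scalar, e.g. `"0.0132"` or `"< 2.2e-16"`.
#' @export
format_pvalue <- function(p, floor = 2.2e-16) {
  if (is.na(p)) return(NA_character_)
  if (p < floor) paste("<", format(floor)) else format(p, digits = 4)
}

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Sample k elements from an index pool (safe for pools of length 1)
#' @noRd
sample_idx <- function(pool, k) pool[sample.int(length(pool), k)]

#' Multiplicative log-normal noise factors with mean 1 and the given CV
#' @noRd
noise_factor <- function(n, cv) {
  if (cv < 0) stopf("noise CV must be >= 0")
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Row-wise two-sample homoscedastic t-test on two matrices of replicates
#'
#' Vectorized pooled-variance (Student) t-test, the workhorse behind both the
#' per-protein redox comparison and the abundance permutation machinery.
#' Rows with fewer than two observations in either group, or with zero
#' pooled variance, get NA statistics.
#'
#' @param x,y numeric matrices, one row per protein, columns = replicates.
#' @return data.frame with n1, n2, mean1, mean2, diff, se, t, df, p.
#' @noRd
row_ttest <- function(x, y) {
  n1 <- rowSums(!is.na(x))
  n2 <- rowSums(!is.na(y))
  m1 <- rowMeans(x, na.rm = TRUE)
  m2 <- rowMeans(y, na.rm = TRUE)
  m1[n1 == 0] <- NA_real_
  m2[n2 == 0] <- NA_real_
  ss1 <- rowSums((x - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((y - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  ok <- n1 >= 2 & n2 >= 2
  sp2 <- ifelse(ok & df > 0, (ss1 + ss2) / df, NA_real_)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  t <- ifelse(ok & se > 0, diff / se, NA_real_)
  p <- ifelse(is.na(t), NA_real_, 2 * stats::pt(-abs(t), df))
  data.frame(n1 = n1, n2 = n2, mean1 = m1, mean2 = m2, diff = diff,
             se = se, t = t, df = df, p = p)
}
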