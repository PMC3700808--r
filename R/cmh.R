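#' Cochran-Mantel-Haenszel chi-square test over stratified 2x2 tables
#'
#' Tests association between two binary variables across strata. For each
#' stratum with cell counts `a, b, c, d` (rows: real/control, columns:
#' removed/not removed) and total `n`, the expectation and variance of the
#' top-left cell under the null are `E = (a+b)(a+c)/n` and
#' `V = (a+b)(c+d)(a+c)(b+d) / (n^2 (n-1))`. The statistic is
#' `(|sum(a) - sum(E)| - cc)^2 / sum(V)` with continuity correction
#' `cc = 0.5` (default on; following the convention of R's stock CMH
#' implementation the correction is only applied when the absolute deviation
#' is at least 0.5, so it can never overshoot) and is referred to a
#' chi-square distribution with one degree of freedom. Strata with a zero
#' row or column margin carry no information and are skipped (their count is
#' reported).
#'
#' @param tables Tibble (or data frame) with integer columns `a`, `b`, `c`,
#'   `d`; one row per stratum. Optional column `label` names the strata.
#' @param correction Apply the 0.5 continuity correction (default `TRUE`).
#' @return Object of class `cmh_result`: `statistic`, `p_value`,
#'   `real_frequency` (`sum(a)/sum(a+b)`), `control_frequency`
#'   (`sum(c)/sum(c+d)`), `n_strata` (informative strata), `n_skipped`,
#'   `correction`. When every stratum is degenerate the statistic is `NA` and
#'   the result is flagged via `degenerate = TRUE`.
#' @export
#' @examples
#' cmh_test(tibble::tibble(a = 1, b = 0, c = 225, d = 775), correction = FALSE)
cmh_test <- function(tables, correction = TRUE) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
  a <- as.numeric(tables$a); b <- as.numeric(tables$b)
  cc <- as.numeric(tables$c); d <- as.numeric(tables$d)
  if (any(c(a, b, cc, d) < 0)) abort("cell counts must be non-negative")
  n <- a + b + cc + d
  if (any(n == 0)) abort("every stratum must have a positive total")
  row1 <- a + b; col1 <- a + cc
  keep <- row1 > 0 & (cc + d) > 0 & col1 > 0 & (b + d) > 0 & n > 1
  n_skipped <- sum(!keep)
  real_freq <- if (sum(a + b) > 0) sum(a) / sum(a + b) else NA_real_
  ctrl_freq <- if (sum(cc + d) > 0) sum(cc) / sum(cc + d) else NA_real_
  out <- list(
    statistic = NA_real_, p_value = NA_real_,
    real_frequency = real_freq, control_frequency = ctrl_freq,
    n_strata = sum(keep), n_skipped = n_skipped,
    correction = correction, degenerate = FALSE
  )
  if (!any(keep)) {
    out$degenerate <- TRUE
    class(out) <- "cmh_result"
    return(out)
  }
  a <- a[keep]; b <- b[keep]; cc <- cc[keep]; d <- d[keep]; n <- n[keep]
  e <- (a + b) * (a + cc) / n
  v <- (a + b) * (cc + d) * (a + cc) * (b + d) / (n^2 * (n - 1))
  sv <- sum(v)
  if (sv == 0) {
    out$degenerate <- TRUE
    class(out) <- "cmh_result"
    return(out)
  }
  delta <- abs(sum(a) - sum(e))
  dev <- delta - if (correction && delta >= 0.5) 0.5 else 0
  out$statistic <- dev^2 / sv
  out$p_value <- pchisq(out$statistic, df = 1, lower.tail = FALSE)
  class(out) <- "cmh_result"
  out
}

#' @export
print.cmh_result <- function(x, ...) {
  cat("Cochran-Mantel-Haenszel chi-square test\n")
  cat(sprintf("  statistic = %.4g (df = 1), p = %.4g%s\n",
              x$statistic, x$p_value,
              if (x$correction) ", continuity corrected" else ""))
  cat(sprintf("  real frequency = %.4g, control frequency = %.4g\n",
              x$real_frequency, x$control_frequency))
  cat(sprintf("  strata: %d informative, %d skipped\n", x$n_strata, x$n_skipped))
  if (x$degenerate) cat("  note: statistic undefined (all strata degenerate)\n")
  invisible(x)
}

#' @method tidy cmh_result
#' @export
tidy.cmh_result <- function(x, ...) {
  tibble(
    statistic = x$statistic, p.value = x$p_value, df = 1,
    real_frequency = x$real_frequency,
    control_frequency = x$control_frequency,
    method = paste0("Cochran-Mantel-Haenszel chi-square",
                    if (x$correction) " (continuity corrected)" else "")
  )
}

#' @method glance cmh_result
#' @export
glance.cmh_result <- function(x, ...) {
  tibble(
    statistic = x$statistic, p.value = x$p_value,
    n_strata = x$n_strata, n_skipped = x$n_skipped,
    degenerate = x$degenerate
  )
}
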