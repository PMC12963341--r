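#' Brunner-Munzel rank test for two independent samples
#'
#' Nonparametric test of the relative effect p = P(X < Y) + 0.5 P(X = Y),
#' robust to unequal variances and ties (ties are handled through midranks).
#' The studentized statistic is referred to a t distribution with
#' Satterthwaite-approximated degrees of freedom.
#'
#' Degenerate samples (both rank variances zero, i.e. complete separation or
#' two constant samples) are flagged: the relative effect is still reported
#' (0, 1/2 or 1) but the statistic is infinite and the p-value is set to 0
#' (separation) or 1 (identical constants).
#'
#' @param x,y numeric vectors, each of length >= 2
#' @param alternative one of "two.sided", "less", "greater"; the alternative
#'   is formulated in terms of the relative effect (greater means
#'   P(X < Y) + 0.5 P(X = Y) > 1/2, i.e. y tends to be larger)
#' @return an object of class `bm_test`: list with `statistic`, `df`,
#'   `estimate` (the relative effect), `p.value`, `n` (group sizes),
#'   `alternative`, and `degenerate` flag
#' @examples
#' brunner_munzel(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
brunner_munzel <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each sample must contain at least 2 values")
  N <- n1 + n2

  R  <- rank(c(x, y))          # pooled midranks
  R1 <- R[seq_len(n1)]
  R2 <- R[n1 + seq_len(n2)]
  r1 <- rank(x)                # within-group midranks
  r2 <- rank(y)
  m1 <- mean(R1); m2 <- mean(R2)

  phat <- (m2 - (n2 + 1) / 2) / n1

  S1 <- sum((R1 - r1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  S2 <- sum((R2 - r2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)

  v1 <- S1 / (N - n1)^2 / n1
  v2 <- S2 / (N - n2)^2 / n2
  sigma2 <- v1 + v2

  if (sigma2 <= 0) {
    # complete separation or constant samples
    est <- phat
    if (isTRUE(all.equal(m1, m2))) {
      out <- list(statistic = 0, df = NA_real_, estimate = 0.5, p.value = 1,
                  n = c(n1 = n1, n2 = n2), alternative = alternative,
                  degenerate = TRUE)
    } else {
      out <- list(statistic = sign(m2 - m1) * Inf, df = NA_real_,
                  estimate = est, p.value = 0,
                  n = c(n1 = n1, n2 = n2), alternative = alternative,
                  degenerate = TRUE)
    }
    class(out) <- "bm_test"
    return(out)
  }

  W  <- (m2 - m1) / (N * sqrt(sigma2))
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))

  p <- switch(alternative,
    two.sided = 2 * stats::pt(abs(W), df, lower.tail = FALSE),
    greater   = stats::pt(W, df, lower.tail = FALSE),
    less      = stats::pt(W, df, lower.tail = TRUE)
  )

  out <- list(statistic = W, df = df, estimate = phat, p.value = p,
              n = c(n1 = n1, n2 = n2), alternative = alternative,
              degenerate = FALSE)
  class(out) <- "bm_test"
  out
}

#' @export
print.bm_test <- function(x, ...) {
  cat("Brunner-Munzel test\n")
  cat(sprintf("  W = %.4f, df = %.2f, p-value = %.4g (%s)\n",
              x$statistic, x$df, x$p.value, x$alternative))
  cat(sprintf("  relative effect P(X<Y)+0.5P(X=Y) = %.4f  (n1 = %d, n2 = %d)\n",
              x$estimate, x$n[1], x$n[2]))
  if (x$degenerate) cat("  note: degenerate samples (zero rank variance)\n")
  invisible(x)
}

#' Median and interquartile range
#'
#' Quartiles use the linear-interpolation convention between order statistics
#' (type 7, the base-R default), fixed package-wide.
#'
#' @param values numeric vector, length >= 1
#' @return named numeric vector c(median, q1, q3)
#' @examples
#' median_iqr(1:5)  # 3, 2, 4
#' @export
median_iqr <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty input")
  if (anyNA(values)) stop("missing values not allowed")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Mean, sample standard deviation and standard error of the mean
#'
#' SD uses the n-1 denominator; for a single value the SD is reported as 0 by
#' convention and flagged via the `sd_defined` attribute.
#'
#' @param values numeric vector, length >= 1
#' @return named numeric vector c(mean, sd, sem) with attribute `sd_defined`
#' @export
mean_sd_sem <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n == 0) stop("empty input")
  if (anyNA(values)) stop("missing values not allowed")
  m <- mean(values)
  s <- if (n > 1) stats::sd(values) else 0
  out <- c(mean = m, sd = s, sem = s / sqrt(n))
  attr(out, "sd_defined") <- n > 1
  out
}
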