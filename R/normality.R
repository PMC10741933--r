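#' D'Agostino-Pearson K-squared normality test
#'
#' Omnibus test combining transformed sample skewness and kurtosis into
#' `K2 = Zs^2 + Zk^2`, referred to a chi-squared distribution with 2 df.
#' Unlike Shapiro-Wilk it has no practical sample-size ceiling, which is why
#' it governs the ANOVA / Mann-Whitney routing at biobank scale. The
#' moment approximations require `n >= 8`; below 20 the test is known to be
#' anticonservative and [routeTest()] falls back to Shapiro-Wilk.
#'
#' @param x numeric vector, `n >= 8`.
#' @return list with `statistic` (K2), `p.value`, and the component
#'   `z.skew` / `z.kurtosis` normal deviates.
#' @references D'Agostino, Belanger & D'Agostino Jr (1990), The American
#'   Statistician 44(4), 316-321.
#' @examples
#' dagostinoK2(rnorm(100))
#' @export
dagostinoK2 <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) {
    cogageError("input", "K-squared test requires at least 8 observations")
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    cogageError("degenerate", "zero variance sample")
  }
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)

  ## skewness component (D'Agostino 1970)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  if (y == 0) y <- 1
  zs <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  ## kurtosis component (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  varb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(varb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  term1 <- 1 - 2 / (9 * A)
  denom <- 1 + xk * sqrt(2 / (A - 4))
  term2 <- sign(denom) * abs((1 - 2 / A) / abs(denom))^(1 / 3)
  zk <- (term1 - term2) / sqrt(2 / (9 * A))

  k2 <- zs^2 + zk^2
  list(
    statistic = k2,
    p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
    z.skew = zs, z.kurtosis = zk
  )
}

## Normality p-value used for routing: K2 for n >= 20, Shapiro-Wilk for
## smaller groups where the K2 approximations break down.
.normalityP <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || stats::sd(x) == 0) return(0)
  if (length(x) >= 20L) dagostinoK2(x)$p.value else stats::shapiro.test(x)$p.value
}
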