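# Closed-form least-squares helpers. These tiny fits are exercised on exact
# synthetic inputs where lm()/summary.lm() emits perfect-fit warnings; the
# closed forms are silent and numerically equivalent.

# Straight line y = a + b x with coefficient covariance.
ols_line <- function(x, y) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  b <- sum((x - xb) * (y - yb)) / sxx
  a <- yb - b * xb
  res <- y - a - b * x
  s2 <- sum(res^2) / max(n - 2, 1)
  vc <- s2 * matrix(c(1 / n + xb^2 / sxx, -xb / sxx,
                      -xb / sxx, 1 / sxx), 2, 2)
  list(a = a, b = b, vcov = vc, residuals = res,
       a_stderr = sqrt(vc[1, 1]), b_stderr = sqrt(vc[2, 2]))
}

# Through-origin line y = b x.
ols_origin <- function(x, y) {
  sxx <- sum(x^2)
  b <- sum(x * y) / sxx
  res <- y - b * x
  s2 <- sum(res^2) / max(length(x) - 1, 1)
  list(b = b, b_stderr = sqrt(s2 / sxx), residuals = res)
}
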