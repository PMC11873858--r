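# Truncated-normal draws via the inverse-CDF method (deterministic given the
# RNG stream).  Tail-safe: when the truncation region sits deep in a tail the
# naive CDF difference underflows, so the upper-tail representation and an
# exponential tail approximation are used instead.

# standard normal truncated to (a, b), with u ~ U(0,1); vectorized
rtnorm_std <- function(a, b, u) {
  z <- numeric(length(u))
  right <- is.finite(a) & a > 3.5          # whole region in the upper tail
  left <- is.finite(b) & b < -3.5
  mid <- !right & !left
  if (any(mid)) {
    pa <- pnorm(a[mid]); pb <- pnorm(b[mid])
    z[mid] <- qnorm(pa + u[mid] * (pb - pa))
  }
  if (any(right)) {
    ar <- a[right]; br <- b[right]
    qa <- pnorm(ar, lower.tail = FALSE)
    qb <- ifelse(is.finite(br), pnorm(br, lower.tail = FALSE), 0)
    zz <- qnorm(qa - u[right] * (qa - qb), lower.tail = FALSE)
    bad <- !is.finite(zz)
    if (any(bad)) {     # exponential tail approximation, rate a
      frac <- ifelse(is.finite(br[bad]), -expm1(-ar[bad] * (br[bad] - ar[bad])), 1)
      zz[bad] <- ar[bad] - log1p(-u[right][bad] * frac) / ar[bad]
    }
    z[right] <- zz
  }
  if (any(left)) {
    al <- a[left]; bl <- b[left]
    qa <- ifelse(is.finite(al), pnorm(-al, lower.tail = FALSE), 0)
    qb <- pnorm(-bl, lower.tail = FALSE)
    zz <- qnorm(qb - u[left] * (qb - qa), lower.tail = FALSE)
    bad <- !is.finite(zz)
    if (any(bad)) {
      mb <- -bl[bad]
      frac <- ifelse(is.finite(al[bad]), -expm1(-mb * (-al[bad] - mb)), 1)
      zz[bad] <- mb - log1p(-u[left][bad] * frac) / mb
    }
    z[left] <- -zz
  }
  pmin(pmax(z, a + 1e-12), b - 1e-12)
}

# N(mean, sd^2) truncated to (lo, hi); draws from the session RNG
rtnorm <- function(n, mean = 0, sd = 1, lo = -Inf, hi = Inf) {
  u <- runif(n)
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  mean + sd * rtnorm_std(a, b, u)
}
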