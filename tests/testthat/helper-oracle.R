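# Brute-force oracles used by both the unit tests and the acceptance suite.

# type-7 quantile by hand: linear interpolation between order statistics
q_type7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

# fences recomputed from first principles (tukey / sixsigma / mad)
brute_fences <- function(x, rule) {
  x <- x[!is.na(x)]
  if (rule == "tukey") {
    q1 <- q_type7(x, 0.25); q3 <- q_type7(x, 0.75)
    c(q1 - 1.5 * (q3 - q1), q3 + 1.5 * (q3 - q1))
  } else if (rule == "sixsigma") {
    mu <- sum(x) / length(x)
    s <- sqrt(sum((x - mu)^2) / (length(x) - 1))
    c(mu - 3 * s, mu + 3 * s)
  } else if (rule == "mad") {
    med <- q_type7(x, 0.5)
    m <- 1.4826 * q_type7(abs(x - med), 0.5)
    c(med - 3 * m, med + 3 * m)
  } else stop("no brute-force oracle for rule ", rule)
}
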