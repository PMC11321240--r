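# Independent reference implementations used as oracles. These deliberately
# share no code with the package: Butterworth coefficients are derived from
# the analog prototype by hand, and filtering is a naive difference-equation
# loop.

# digital Butterworth via analog prototype + bilinear transform;
# W = cutoff as a fraction of Nyquist (as in signal::butter)
oracle_butter <- function(order, W, type = c("low", "high")) {
  type <- match.arg(type)
  wc <- tan(pi * W / 2) # prewarped analog cutoff (T = 2 convention)
  k <- seq_len(order)
  p_proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  if (type == "low") {
    p_a <- wc * p_proto
    z_digital <- rep(-1 + 0i, order)
  } else {
    p_a <- wc / p_proto
    z_digital <- rep(1 + 0i, order)
  }
  p_digital <- (1 + p_a) / (1 - p_a)
  poly_from_roots <- function(r) {
    cf <- 1 + 0i
    for (ri in r) cf <- c(cf, 0) - c(0, cf * ri)
    cf
  }
  a <- Re(poly_from_roots(p_digital))
  b <- Re(poly_from_roots(z_digital))
  # unit gain at DC (low-pass) or Nyquist (high-pass)
  zref <- if (type == "low") 1 else -1
  gain <- sum(a * zref^(seq_along(a) - 1)) / sum(b * zref^(seq_along(b) - 1))
  list(b = b * gain, a = a)
}

# naive direct-form I recursion
oracle_filter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  n <- length(x); nb <- length(b); na <- length(a)
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(nb)) {
      if (i - j + 1 >= 1) acc <- acc + b[j] * x[i - j + 1]
    }
    for (j in 2:na) {
      if (i - j + 1 >= 1) acc <- acc - a[j] * y[i - j + 1]
    }
    y[i] <- acc
  }
  y
}

# zero-phase filtering with the package's documented padding rule:
# odd reflection of 3 * order samples at both ends, forward then reverse pass
oracle_zero_phase <- function(b, a, x) {
  pad <- 3L * (max(length(a), length(b)) - 1L)
  n <- length(x)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- oracle_filter(b, a, xp)
  y <- rev(oracle_filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

# full envelope reference: rectify, HP 20 Hz, LP 10 Hz, clip at zero
oracle_envelope <- function(x, rate, hp = 20, lp = 10, order = 4) {
  cf_h <- oracle_butter(order, 2 * hp / rate, "high")
  cf_l <- oracle_butter(order, 2 * lp / rate, "low")
  env <- oracle_zero_phase(cf_h$b, cf_h$a, abs(x))
  env <- oracle_zero_phase(cf_l$b, cf_l$a, env)
  pmax(env, 0)
}
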