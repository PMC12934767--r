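# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# single positive number / integer / proportion checks used by constructors
check_number <- function(x, name, lo = -Inf, hi = Inf,
                         lo_open = FALSE, hi_open = FALSE,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (integer && x != round(x)) {
    abort(sprintf("`%s` must be a whole number.", name))
  }
  lo_ok <- if (lo_open) x > lo else x >= lo
  hi_ok <- if (hi_open) x < hi else x <= hi
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` = %s is outside %s%s, %s%s.", name, format(x),
      if (lo_open) "(" else "[", format(lo), format(hi),
      if (hi_open) ")" else "]"
    ))
  }
  invisible(x)
}

# Deterministic child seed derived from a master seed and an operation name,
# so that independent stochastic stages never share an RNG stream. Plain
# polynomial string hash; kept below 2^31 - 1.
child_seed <- function(seed, name) {
  h <- 0
  for (cc in utf8ToInt(name)) h <- (h * 31 + cc) %% 1000003L
  as.integer((abs(seed) %% 2147482L) * 1000L + h %% 1000L)
}

# Two-sided Fisher exact p for a 2x2 table [[a, b], [c, d]] under the
# point-mass-inclusive rule: sum the probabilities of all tables (fixed
# margins) no more probable than the observed one. Vectorised over inputs.
fisher2x2_p <- function(a, b, c, d) {
  n <- length(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    r1 <- a[i] + b[i]
    r2 <- c[i] + d[i]
    k <- a[i] + c[i]
    x <- max(0L, k - r2):min(r1, k)
    probs <- dhyper(x, r1, r2, k)
    p_obs <- dhyper(a[i], r1, r2, k)
    out[i] <- min(1, sum(probs[probs <= p_obs * (1 + 1e-07)]))
  }
  out
}

# Beta-binomial draws under the (mu, rho) intra-class-correlation
# parameterisation; rho = 0 degenerates to the binomial.
rbetabinom <- function(n, size, mu, rho) {
  stopifnot(all(mu >= 0 & mu <= 1), all(rho >= 0 & rho < 1))
  mu <- rep_len(mu, n)
  rho <- rep_len(rho, n)
  size <- rep_len(size, n)
  out <- integer(n)
  fixed <- rho == 0 | mu == 0 | mu == 1
  if (any(fixed)) {
    out[fixed] <- rbinom(sum(fixed), size[fixed], mu[fixed])
  }
  if (any(!fixed)) {
    a <- mu[!fixed] * (1 - rho[!fixed]) / rho[!fixed]
    b <- (1 - mu[!fixed]) * (1 - rho[!fixed]) / rho[!fixed]
    p <- rbeta(sum(!fixed), a, b)
    out[!fixed] <- rbinom(sum(!fixed), size[!fixed], p)
  }
  out
}

# Empirical p-value with add-one pseudocount (never exactly zero).
empirical_p <- function(n_as_extreme, n_iter) {
  (1 + n_as_extreme) / (1 + n_iter)
}
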