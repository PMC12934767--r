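#' Beta-binomial log-likelihood
#'
#' Log-likelihood of reference counts under a beta-binomial with mean `mu`
#' and intra-class correlation `rho`, using the parameterisation
#' `alpha = mu (1 - rho) / rho`, `beta = (1 - mu)(1 - rho) / rho`;
#' `rho = 0` is evaluated as the binomial limit.
#'
#' @param ref Reference-allele counts.
#' @param total Total counts (positive).
#' @param mu Mean allelic ratio in (0, 1).
#' @param rho Overdispersion in \[0, 1).
#' @return The summed log-likelihood.
#' @examples
#' bb_loglik(5, 10, 0.5, 0) # log C(10,5) + 10 log 0.5
#' @export
bb_loglik <- function(ref, total, mu, rho) {
  if (mu <= 0 || mu >= 1) abort("mu must lie in (0, 1)")
  if (rho < 0 || rho >= 1) abort("rho must lie in [0, 1)")
  if (any(total <= 0)) abort("totals must be positive")
  if (any(ref < 0 | ref > total)) abort("ref counts must lie in [0, total]")
  if (rho == 0) {
    return(sum(dbinom(ref, total, mu, log = TRUE)))
  }
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  sum(lchoose(total, ref) + lbeta(ref + a, total - ref + b) - lbeta(a, b))
}

#' Fit a beta-binomial to allelic counts
#'
#' Bounded maximum-likelihood estimation of `(mu, rho)` with a fixed,
#' deterministic multi-start scheme: the likelihood is screened on a grid
#' (`mu` in 0.1..0.9, `rho` in {0.001, 0.05, 0.2}) plus a method-of-moments
#' start, Nelder-Mead is run from the best starts, and the pure-binomial
#' boundary fit (`rho = 0`, `mu` = pooled ratio) competes as a candidate.
#' Identical data always give the identical fit.
#'
#' @param ref,total Count vectors (at least 2 observations with positive
#'   totals).
#' @return An object of class `bb_fit` with elements `mu`, `rho`,
#'   `loglik`, `n_obs`, `converged`.
#' @examples
#' set.seed(1)
#' n <- rpois(50, 40) + 1
#' k <- rbinom(50, n, 0.4)
#' bb_fit(k, n)
#' @export
bb_fit <- function(ref, total) {
  keep <- total > 0
  ref <- ref[keep]
  total <- total[keep]
  if (length(ref) < 2) abort("need at least 2 observations with reads")
  ratio <- ref / total

  eps <- 1e-06
  if (all(abs(ratio - ratio[1]) < 1e-12)) {
    mu <- clamp(ratio[1], eps, 1 - eps)
    return(new_bb_fit(mu, 0, bb_loglik(ref, total, mu, 0),
                      length(ref), TRUE))
  }

  nll <- function(par) {
    mu <- plogis(par[1])
    rho <- 0.95 * plogis(par[2])
    -bb_loglik(ref, total, clamp(mu, eps, 1 - eps), rho)
  }

  mu_grid <- seq(0.1, 0.9, by = 0.2)
  rho_grid <- c(0.001, 0.05, 0.2)
  # moment start
  mu0 <- clamp(mean(ratio), eps, 1 - eps)
  vr <- var(ratio)
  nbar <- mean(total)
  rho0 <- clamp((vr * nbar / (mu0 * (1 - mu0)) - 1) / (nbar - 1),
                0.001, 0.9)
  starts <- rbind(
    expand.grid(mu = mu_grid, rho = rho_grid),
    data.frame(mu = mu0, rho = rho0)
  )
  start_vals <- apply(starts, 1, function(s) {
    -bb_loglik(ref, total, s[["mu"]], s[["rho"]])
  })
  use <- utils::head(order(start_vals), 3)
  use <- sort(unique(c(use, nrow(starts)))) # always keep the moment start

  best <- NULL
  for (i in use) {
    par0 <- c(qlogis(starts$mu[i]), qlogis(starts$rho[i] / 0.95))
    opt <- optim(par0, nll, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  mu_hat <- clamp(plogis(best$par[1]), eps, 1 - eps)
  rho_hat <- 0.95 * plogis(best$par[2])
  ll_hat <- bb_loglik(ref, total, mu_hat, rho_hat)

  # binomial boundary candidate
  mu_b <- clamp(sum(ref) / sum(total), eps, 1 - eps)
  ll_b <- bb_loglik(ref, total, mu_b, 0)
  if (ll_b >= ll_hat) {
    return(new_bb_fit(mu_b, 0, ll_b, length(ref), TRUE))
  }
  new_bb_fit(mu_hat, rho_hat, ll_hat, length(ref),
             best$convergence == 0)
}

new_bb_fit <- function(mu, rho, loglik, n_obs, converged) {
  structure(list(mu = mu, rho = rho, loglik = loglik, n_obs = n_obs,
                 converged = converged),
            class = "bb_fit")
}

#' @export
print.bb_fit <- function(x, ...) {
  cat(sprintf("<bb_fit> mu = %.4f, rho = %.4f, loglik = %.3f (n = %d%s)\n",
              x$mu, x$rho, x$loglik, x$n_obs,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Beta-binomial likelihood-ratio test between two groups
#'
#' Compares a null model with one beta-binomial distribution shared by
#' both groups against an alternative with group-specific `(mu, rho)`.
#' The statistic `2 (ll_a + ll_b - ll_pooled)` is floored at zero and
#' referred to a chi-square with 2 degrees of freedom (two extra free
#' parameters under the alternative).
#'
#' @param ref_a,total_a Counts for group A.
#' @param ref_b,total_b Counts for group B.
#' @return An object of class `bb_lrt`: `statistic`, `p_value`, `df`, and
#'   the three component `bb_fit`s.
#' @examples
#' set.seed(1)
#' n <- rpois(40, 50) + 1
#' a <- rbinom(40, n, 0.5); b <- rbinom(40, n, 0.3)
#' bb_lrt(a, n, b, n)
#' @export
bb_lrt <- function(ref_a, total_a, ref_b, total_b) {
  fit_a <- bb_fit(ref_a, total_a)
  fit_b <- bb_fit(ref_b, total_b)
  fit_0 <- bb_fit(c(ref_a, ref_b), c(total_a, total_b))
  stat <- max(0, 2 * (fit_a$loglik + fit_b$loglik - fit_0$loglik))
  structure(
    list(statistic = stat,
         p_value = pchisq(stat, df = 2, lower.tail = FALSE),
         df = 2L, fit_a = fit_a, fit_b = fit_b, fit_null = fit_0),
    class = "bb_lrt"
  )
}

#' @export
print.bb_lrt <- function(x, ...) {
  cat(sprintf("<bb_lrt> LRT = %.3f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
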