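#' Tidy a beta-binomial fit
#'
#' @param x A `bb_fit`.
#' @param ... Unused.
#' @return One row per parameter (`mu`, `rho`) with the estimate.
#' @export
tidy.bb_fit <- function(x, ...) {
  tibble(term = c("mu", "rho"), estimate = c(x$mu, x$rho))
}

#' @rdname tidy.bb_fit
#' @export
glance.bb_fit <- function(x, ...) {
  tibble(logLik = x$loglik, n_obs = x$n_obs, converged = x$converged)
}

#' Tidy a beta-binomial likelihood-ratio test
#'
#' @param x A `bb_lrt`.
#' @param ... Unused.
#' @return A one-row tibble with group estimates, the statistic and p.
#' @export
tidy.bb_lrt <- function(x, ...) {
  tibble(
    mu_a = x$fit_a$mu, rho_a = x$fit_a$rho,
    mu_b = x$fit_b$mu, rho_b = x$fit_b$rho,
    mu_null = x$fit_null$mu, rho_null = x$fit_null$rho,
    statistic = x$statistic, df = x$df, p_value = x$p_value
  )
}

#' @rdname tidy.bb_lrt
#' @export
glance.bb_lrt <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         logLik_alt = x$fit_a$loglik + x$fit_b$loglik,
         logLik_null = x$fit_null$loglik)
}

#' Tidy a concordance record
#'
#' @param x A `concordance_record`.
#' @param ... Unused.
#' @return The per-individual tibble with the pair identifiers attached.
#' @export
tidy.concordance_record <- function(x, ...) {
  x$individuals %>%
    mutate(candidate_snp_id = x$candidate_snp_id,
           tag_snp_id = x$tag_snp_id)
}

#' @rdname tidy.concordance_record
#' @export
glance.concordance_record <- function(x, ...) {
  tibble(candidate_snp_id = x$candidate_snp_id,
         tag_snp_id = x$tag_snp_id, n_het = x$n_het,
         n_total = x$n_total, mean_si = x$mean_si, reason = x$reason)
}
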