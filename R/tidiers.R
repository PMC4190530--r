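# broom-style tidy()/glance() methods for fitted objects.

#' @exportS3Method generics::tidy
tidy.stoich_fit <- function(x, ...) {
  tibble(
    term = c("n_hat", "log_k_s0"),
    estimate = c(x$n_hat, x$log_k_s0),
    std.error = c(x$se_n,
                  summary(x$fit)$coefficients["(Intercept)", "Std. Error"])
  )
}

#' @exportS3Method generics::glance
glance.stoich_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = x$n_obs, s0 = x$s0)
}

#' @exportS3Method generics::tidy
tidy.complexation_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$covariance), 0))
  tibble(
    term = c("k11", "k12"),
    estimate = c(x$k11, x$k12),
    std.error = unname(se)
  )
}

#' @exportS3Method generics::glance
glance.complexation_fit <- function(x, ...) {
  tibble(
    fit_method = x$fit_method,
    s0 = x$s0,
    r.squared = x$r_squared %||% NA_real_,
    convergence = x$convergence %||% NA_character_
  )
}

#' @exportS3Method generics::tidy
tidy.profile_class <- function(x, ...) {
  tibble(label = x$label, curvature = x$curvature,
         curvature_pvalue = x$curvature_pvalue, alpha = x$alpha)
}

#' @exportS3Method generics::tidy
tidy.pmf_profile <- function(x, ...) {
  out <- as_tibble(x)
  out$estimator <- attr(x, "estimator")
  out
}

#' @exportS3Method generics::glance
glance.pmf_profile <- function(x, ...) {
  tibble(
    estimator = attr(x, "estimator"),
    temperature_K = attr(x, "temperature_K"),
    n_repeats = nrow(attr(x, "work")),
    n_grid = nrow(x),
    delta_end_kcal_mol = x$pmf_kcal_mol[nrow(x)] - x$pmf_kcal_mol[1]
  )
}
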