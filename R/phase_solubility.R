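# Phase-solubility analysis: diagram classification and stability-constant
# estimation for 1:1 / 1:2 drug-cyclodextrin complexation.

# Resolve the intrinsic solubility: supplied value wins, otherwise the mean
# of the zero-cyclodextrin measurements. The intercept of every linearization
# hinges on it, so the resolution rule is explicit and shared by all fits.
.resolve_s0 <- function(data, s0, what = "dataset") {
  if (!is.null(s0)) {
    .check_scalar(s0, "s0", positive = TRUE)
    return(s0)
  }
  zero <- data$s_total_M[data$cd_total_M == 0]
  if (length(zero) == 0) {
    abort(sprintf(
      "Cannot infer `s0`: %s has no cd_total_M == 0 measurements; supply `s0` explicitly.",
      what
    ))
  }
  mean(zero)
}

.check_phase_data <- function(data) {
  .require_columns(data, c("cd_total_M", "s_total_M"),
                   "a phase-solubility dataset")
  .check_numeric(data$cd_total_M, "cd_total_M", nonneg = TRUE)
  if (any(data$s_total_M <= 0)) {
    abort("`s_total_M` must be > 0 for every point.")
  }
  invisible(data)
}

.new_complexation_fit <- function(s0, k11, k12, fit_method, covariance,
                                  fit = NULL, extra = list()) {
  structure(
    c(list(s0 = s0, k11 = k11, k12 = k12, fit_method = fit_method,
           covariance = covariance, fit = fit), extra),
    class = "complexation_fit"
  )
}

#' Classify a phase-solubility diagram as A_L or A_p
#'
#' Fits the quadratic \eqn{S_{tot} = a + b\,[CD] + c\,[CD]^2} and decides
#' from the curvature term: a significantly positive `c` indicates a
#' positively deviating diagram (`A_p`, higher-order complexation), an
#' insignificant `c` a linear diagram (`A_L`, first-order complexation), and
#' a significantly negative `c` is reported as `indeterminate` (negative
#' deviation falls outside the 1:1/1:2 model).
#'
#' @param data A phase-solubility data frame with columns `cd_total_M`,
#'   `s_total_M` (extra columns are ignored). At least 4 distinct
#'   concentrations are required.
#' @param alpha Significance level for the curvature test (default 0.05).
#' @return An object of class `profile_class`: a list with `label`
#'   (`"A_L"`, `"A_p"` or `"indeterminate"`), `curvature_pvalue`,
#'   `curvature` (the `c` estimate) and the underlying `lm` fit.
#' @export
#' @examples
#' d <- sim_phase_solubility(1e-5, k11 = 6.5, k12 = 12370, noise_cv = 0)
#' classify_profile(d)$label # "A_p"
classify_profile <- function(data, alpha = 0.05) {
  .check_phase_data(data)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).")
  }
  n_distinct <- length(unique(data$cd_total_M))
  if (n_distinct < 4) {
    abort(sprintf(
      "classify_profile needs >= 4 distinct cd_total_M values (got %d).",
      n_distinct
    ))
  }
  fit <- lm(s_total_M ~ cd_total_M + I(cd_total_M^2), data = data)
  cf <- summary(fit)$coefficients
  curv <- cf["I(cd_total_M^2)", "Estimate"]
  pval <- cf["I(cd_total_M^2)", "Pr(>|t|)"]
  if (!is.finite(pval)) {
    # Degenerate (zero-residual) fit: fall back to the relative size of the
    # curvature contribution at the largest concentration.
    rel <- abs(curv) * max(data$cd_total_M)^2 / mean(data$s_total_M)
    label <- if (rel < 1e-8) "A_L" else if (curv > 0) "A_p" else "indeterminate"
    pval <- if (rel < 1e-8) 1 else 0
  } else if (pval < alpha && curv > 0) {
    label <- "A_p"
  } else if (pval < alpha && curv < 0) {
    label <- "indeterminate"
  } else {
    label <- "A_L"
  }
  structure(
    list(label = label, curvature_pvalue = pval, curvature = curv,
         alpha = alpha, fit = fit),
    class = "profile_class"
  )
}

#' @export
print.profile_class <- function(x, ...) {
  cat(sprintf("Phase-solubility profile: %s (curvature p = %.3g)\n",
              x$label, x$curvature_pvalue))
  invisible(x)
}

#' Estimate the effective complexation stoichiometry by log-log regression
#'
#' For the equilibrium \eqn{D + n\,CD \leftrightarrow D\,CD_n}, the excess
#' solubility obeys \eqn{\log(S_{tot} - S_0) = n \log[CD] + \log(K S_0)},
#' so the slope of the log-log plot estimates the effective number of
#' cyclodextrin molecules bound per drug molecule. Base-10 logarithms are
#' used; the slope is base-invariant.
#'
#' Points with `cd_total_M == 0` are excluded (the transform is undefined
#' there); any remaining point with `s_total_M <= s0` is a hard error rather
#' than a silent drop, because dropping low points biases the slope.
#'
#' @inheritParams classify_profile
#' @param s0 Intrinsic solubility, mol/L. Default: mean of the
#'   `cd_total_M == 0` measurements.
#' @return An object of class `stoich_fit`: list with `n_hat`, `se_n`,
#'   `log_k_s0` (intercept, log10 scale), `r_squared`, `s0`, `n_obs` and the
#'   underlying `lm` fit. [tidy()] and [glance()] methods are provided.
#' @export
#' @examples
#' d <- sim_phase_solubility(1e-4, k11 = 1000, noise_cv = 0, replicates = 1)
#' fit_loglog_stoichiometry(d)$n_hat # exactly 1
fit_loglog_stoichiometry <- function(data, s0 = NULL) {
  .check_phase_data(data)
  s0 <- .resolve_s0(data, s0)
  pts <- data[data$cd_total_M > 0, , drop = FALSE]
  bad <- which(pts$s_total_M <= s0)
  if (length(bad) > 0) {
    abort(sprintf(
      "log-log stoichiometry fit is undefined: s_total_M <= s0 (= %g) at %d nonzero-CD row%s (%s). Not dropping them silently; inspect or raise `s0`.",
      s0, length(bad), if (length(bad) > 1) "s" else "",
      paste(utils::head(bad, 10), collapse = ", ")
    ))
  }
  if (length(unique(pts$cd_total_M)) < 3) {
    abort("log-log stoichiometry fit needs >= 3 distinct nonzero cd_total_M values.")
  }
  df <- tibble(
    log_cd = log10(pts$cd_total_M),
    log_excess = log10(pts$s_total_M - s0)
  )
  fit <- lm(log_excess ~ log_cd, data = df)
  sm <- summary(fit)
  structure(
    list(
      n_hat = unname(coef(fit)["log_cd"]),
      se_n = unname(sm$coefficients["log_cd", "Std. Error"]),
      log_k_s0 = unname(coef(fit)["(Intercept)"]),
      r_squared = sm$r.squared,
      s0 = s0,
      n_obs = nrow(df),
      fit = fit
    ),
    class = "stoich_fit"
  )
}

#' @export
print.stoich_fit <- function(x, ...) {
  cat(sprintf(
    "Log-log stoichiometry fit: n_hat = %.3f (SE %.3g), R^2 = %.4f, n = %d\n",
    x$n_hat, x$se_n, x$r_squared, x$n_obs
  ))
  invisible(x)
}

#' Estimate K1:1 from the slope of a linear (A_L) phase-solubility diagram
#'
#' For pure 1:1 complexation the diagram is linear and the stability constant
#' follows from its slope \eqn{m}:
#' \deqn{K_{1:1} = \frac{m}{S_0 (1 - m)}.}
#' The slope of an admissible 1:1 diagram lies strictly in (0, 1); slopes
#' outside that range are an error, not a clamped estimate.
#'
#' @inheritParams fit_loglog_stoichiometry
#' @return A `complexation_fit` with `fit_method = "al_slope"`, `k12 = 0`,
#'   a delta-method standard error for `k11`, and the slope and its SE in
#'   `$slope` / `$slope_se`.
#' @export
#' @examples
#' d <- sim_phase_solubility(1e-3, k11 = 1000, noise_cv = 0, replicates = 1,
#'                           cd_grid = seq(0, 0.1, by = 0.02))
#' fit_al_k11(d)$k11
fit_al_k11 <- function(data, s0 = NULL) {
  .check_phase_data(data)
  s0 <- .resolve_s0(data, s0)
  if (length(unique(data$cd_total_M)) < 3) {
    abort("A_L slope fit needs >= 3 distinct cd_total_M values.")
  }
  fit <- lm(s_total_M ~ cd_total_M, data = data)
  m <- unname(coef(fit)["cd_total_M"])
  if (m <= 0) {
    abort(sprintf("A_L slope = %.4g <= 0: no complexation signal; K1:1 undefined.", m))
  }
  if (m >= 1) {
    abort(sprintf(
      "A_L slope = %.4g >= 1 is physically inadmissible for a 1:1 model (K1:1 would be negative).",
      m
    ))
  }
  se_m <- summary(fit)$coefficients["cd_total_M", "Std. Error"]
  k11 <- m / (s0 * (1 - m))
  # delta method: dK/dm = 1 / (s0 (1 - m)^2)
  se_k11 <- se_m / (s0 * (1 - m)^2)
  covariance <- matrix(c(se_k11^2, 0, 0, 0), 2, 2,
                       dimnames = list(c("k11", "k12"), c("k11", "k12")))
  .new_complexation_fit(
    s0, k11, 0, "al_slope", covariance, fit,
    extra = list(slope = m, slope_se = se_m,
                 r_squared = summary(fit)$r.squared)
  )
}

#' Estimate K1:1 and K1:2 by the linearized A_p regression
#'
#' For coexisting 1:1 and 1:2 complexes, plotting
#' \eqn{(S_{tot} - S_0)/[CD]} against \eqn{[CD]} gives a straight line with
#' intercept \eqn{K_{1:1} S_0} and slope \eqn{K_{1:1} K_{1:2} S_0}. Ordinary
#' least squares on that transform yields both constants; their covariance is
#' propagated from the regression by the delta method.
#'
#' A non-positive intercept (negative K1:1) is an error. A slightly negative
#' slope — the degenerate pure-1:1 case under noise — is clamped to
#' `k12 = 0` and the raw value kept in `$k12_raw`.
#'
#' @inheritParams fit_loglog_stoichiometry
#' @return A `complexation_fit` with `fit_method = "ap_linearized"` and a
#'   2x2 delta-method covariance for `(k11, k12)`.
#' @export
#' @examples
#' d <- sim_phase_solubility(1e-5, k11 = 100, k12 = 50, noise_cv = 0)
#' fit <- fit_ap_linearized(d)
#' c(fit$k11, fit$k12)
fit_ap_linearized <- function(data, s0 = NULL) {
  .check_phase_data(data)
  s0 <- .resolve_s0(data, s0)
  pts <- data[data$cd_total_M > 0, , drop = FALSE]
  if (length(unique(pts$cd_total_M)) < 3) {
    abort("A_p linearized fit needs >= 3 distinct nonzero cd_total_M values.")
  }
  df <- tibble(
    cd = pts$cd_total_M,
    y = (pts$s_total_M - s0) / pts$cd_total_M
  )
  fit <- lm(y ~ cd, data = df)
  b0 <- unname(coef(fit)["(Intercept)"])
  b1 <- unname(coef(fit)["cd"])
  if (b0 <= 0) {
    abort(sprintf(
      "A_p linearized intercept = %.4g <= 0 implies a negative K1:1; the 1:1/1:2 model does not describe these data.",
      b0
    ))
  }
  k11 <- b0 / s0
  k12_raw <- b1 / b0
  k12 <- max(k12_raw, 0)
  # delta method on (b0, b1) -> (k11, k12) = (b0/s0, b1/b0)
  V <- vcov(fit)
  J <- matrix(c(1 / s0, 0,
                -b1 / b0^2, 1 / b0),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("k11", "k12"), c("(Intercept)", "cd")))
  covariance <- J %*% V %*% t(J)
  dimnames(covariance) <- list(c("k11", "k12"), c("k11", "k12"))
  .new_complexation_fit(
    s0, k11, k12, "ap_linearized", covariance, fit,
    extra = list(k12_raw = k12_raw, intercept = b0, slope = b1,
                 r_squared = summary(fit)$r.squared)
  )
}

#' Estimate K1:1 and K1:2 by direct nonlinear least squares
#'
#' Fits the forward model \eqn{S_{tot} = S_0(1 + K_{1:1}[CD] +
#' K_{1:1}K_{1:2}[CD]^2)} over \eqn{K_{1:1}, K_{1:2} \ge 0} by
#' Levenberg-Marquardt with box constraints and an analytic Jacobian,
#' initialized from the linearized estimates (clipped to the bounds).
#'
#' With the default `weighting = "relative"` the residuals are divided by the
#' observed solubilities, i.e. the fit minimizes squared *relative* error.
#' This matches the multiplicative (constant-CV) error structure of
#' chromatographic solubility measurements, under which an unweighted fit
#' would let the largest concentrations dominate and determine
#' \eqn{K_{1:1}} poorly. Set `weighting = "absolute"` for the plain
#' sum-of-squares objective; the two coincide on noiseless data.
#'
#' @inheritParams fit_loglog_stoichiometry
#' @param start Optional named list/vector with starting values `k11`, `k12`;
#'   default: the [fit_ap_linearized()] estimates.
#' @param weighting `"relative"` (default) or `"absolute"` residual scaling.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return A `complexation_fit` with `fit_method = "ap_nonlinear"`,
#'   covariance from the local quadratic approximation where available, and
#'   `$convergence` (the optimizer's stop message).
#' @export
fit_ap_nonlinear <- function(data, s0 = NULL, start = NULL,
                             weighting = c("relative", "absolute"),
                             max_iter = 200) {
  .check_phase_data(data)
  weighting <- match.arg(weighting)
  s0 <- .resolve_s0(data, s0)
  if (length(unique(data$cd_total_M)) < 4) {
    abort("A_p nonlinear fit needs >= 4 distinct cd_total_M values.")
  }
  if (is.null(start)) {
    lin <- fit_ap_linearized(data, s0 = s0)
    start <- list(k11 = max(lin$k11, 1e-8), k12 = max(lin$k12, 0))
  }
  cd <- data$cd_total_M
  s_obs <- data$s_total_M
  w <- if (weighting == "relative") 1 / s_obs else rep(1, length(s_obs))
  resid_fn <- function(par) {
    (s0 * (1 + par[1] * cd + par[1] * par[2] * cd^2) - s_obs) * w
  }
  jac_fn <- function(par) {
    cbind(s0 * (cd + par[2] * cd^2) * w,
          s0 * par[1] * cd^2 * w)
  }
  fit <- minpack.lm::nls.lm(
    par = c(k11 = start$k11, k12 = start$k12),
    lower = c(0, 0),
    fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(maxiter = max_iter)
  )
  est <- fit$par
  if (!fit$info %in% 1:4) {
    grad <- crossprod(jac_fn(est), resid_fn(est))
    abort(sprintf(
      "A_p nonlinear fit did not converge (best iterate k11 = %g, k12 = %g; gradient norm %.3g; %s).",
      est[1], est[2], sqrt(sum(grad^2)), fit$message
    ))
  }
  dof <- length(s_obs) - 2L
  sigma2 <- if (dof > 0) fit$deviance / dof else NA_real_
  covariance <- tryCatch({
    J <- jac_fn(est)
    sigma2 * solve(crossprod(J))
  }, error = function(e) matrix(NA_real_, 2, 2))
  dimnames(covariance) <- list(c("k11", "k12"), c("k11", "k12"))
  .new_complexation_fit(
    s0, unname(est[1]), unname(est[2]), "ap_nonlinear", covariance,
    fit,
    extra = list(convergence = fit$message, iterations = fit$niter,
                 weighting = weighting)
  )
}

#' @export
print.complexation_fit <- function(x, ...) {
  cat(sprintf(
    "Complexation model (%s): S0 = %.4g M, K1:1 = %.4g L/mol, K1:2 = %.4g L/mol\n",
    x$fit_method, x$s0, x$k11, x$k12
  ))
  invisible(x)
}

#' Predict total drug solubility from a 1:1/1:2 complexation model
#'
#' Evaluates \eqn{S_{tot} = S_0(1 + K_{1:1}[CD] + K_{1:1}K_{1:2}[CD]^2)}.
#' By default `[CD]` is the total cyclodextrin concentration, the convention
#' under which phase-solubility constants are routinely reported. With
#' `free_cd_correction = TRUE` the mass balance
#' \deqn{[CD]_{tot} = [CD] + S_0 K_{1:1} [CD] + 2 S_0 K_{1:1} K_{1:2} [CD]^2}
#' is solved for the free concentration on \eqn{[0, [CD]_{tot}]} and the
#' model is evaluated there — the equilibrium expressions are written in free
#' concentration, and the correction makes that approximation explicit.
#'
#' @param s0 Intrinsic solubility, mol/L; or a `complexation_fit` (then
#'   `k11`/`k12` are taken from it).
#' @param k11,k12 Stability constants, L/mol.
#' @param cd_total Total cyclodextrin concentration(s), mol/L (>= 0);
#'   vectorized.
#' @param free_cd_correction Solve the cyclodextrin mass balance for the
#'   free concentration before evaluating the model? Default `FALSE`.
#' @return Numeric vector of total solubilities, mol/L.
#' @export
#' @examples
#' predict_total_solubility(1e-4, 1000, 0, cd_total = 0.01) # 1.1e-3
predict_total_solubility <- function(s0, k11 = NULL, k12 = NULL, cd_total,
                                     free_cd_correction = FALSE) {
  if (inherits(s0, "complexation_fit")) {
    model <- s0
    s0 <- model$s0
    k11 <- model$k11
    k12 <- model$k12
  }
  .check_scalar(s0, "s0", positive = TRUE)
  .check_scalar(k11, "k11", nonneg = TRUE)
  .check_scalar(k12, "k12", nonneg = TRUE)
  .check_numeric(cd_total, "cd_total", nonneg = TRUE)

  eval_model <- function(cd) s0 * (1 + k11 * cd + k11 * k12 * cd^2)
  if (!free_cd_correction) {
    return(eval_model(cd_total))
  }
  vapply(cd_total, function(ct) {
    if (ct == 0) return(s0)
    balance <- function(cf) cf + s0 * k11 * cf + 2 * s0 * k11 * k12 * cf^2 - ct
    # balance(0) = -ct < 0 and balance(ct) >= 0, so a root always exists
    root <- tryCatch(
      uniroot(balance, interval = c(0, ct), tol = .Machine$double.eps^0.75),
      error = function(e) {
        abort(sprintf(
          "No free-CD root in [0, %g]; the model parameters are inconsistent (%s).",
          ct, conditionMessage(e)
        ))
      }
    )
    eval_model(root$root)
  }, numeric(1))
}

#' @export
predict.complexation_fit <- function(object, cd_total,
                                     free_cd_correction = FALSE, ...) {
  predict_total_solubility(object, cd_total = cd_total,
                           free_cd_correction = free_cd_correction)
}
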