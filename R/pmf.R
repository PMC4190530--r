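# Potential-of-mean-force reconstruction from ensembles of constant-velocity
# pulling work curves: Jarzynski exponential average, second-order cumulant
# expansion, and mean work, with jackknife uncertainties over repeats.

# Long work tibble -> list(lambda, W [repeat x grid], temperature)
.work_matrix <- function(work, temperature = NULL) {
  .require_columns(work, c("lambda_A", "repeat_id", "work_kcal_mol"),
                   "a work ensemble")
  temperature <- temperature %||% attr(work, "temperature_K")
  if (is.null(temperature)) {
    abort("`temperature` is required (not found in the ensemble's attributes).")
  }
  .check_scalar(temperature, "temperature", positive = TRUE)
  bad <- unique(work$repeat_id[!is.finite(work$work_kcal_mol)])
  if (length(bad) > 0) {
    abort(sprintf("Non-finite work values in repeat%s %s.",
                  if (length(bad) > 1) "s" else "",
                  paste(sort(bad), collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(work[, c("lambda_A", "repeat_id", "work_kcal_mol")],
                             names_from = "repeat_id",
                             values_from = "work_kcal_mol")
  wide <- dplyr::arrange(wide, .data$lambda_A)
  lambda <- wide$lambda_A
  if (anyNA(wide) || length(lambda) < 2) {
    abort("All repeats must share one common lambda grid with >= 2 points.")
  }
  d <- diff(lambda)
  if (!(all(d > 0) || all(d < 0))) {
    abort("`lambda_A` grid must be strictly monotone.")
  }
  W <- t(as.matrix(wide[, -1, drop = FALSE]))
  # Work curves normally start at 0; a common offset is harmless because
  # every estimator re-anchors the profile at the first grid point.
  list(lambda = lambda, W = W, temperature = temperature)
}

.new_pmf_profile <- function(lambda, pmf, sd, estimator, temperature, W) {
  out <- tibble(lambda_A = lambda, pmf_kcal_mol = pmf - pmf[1],
                sd_kcal_mol = sd)
  attr(out, "estimator") <- estimator
  attr(out, "temperature_K") <- temperature
  attr(out, "work") <- W
  class(out) <- c("pmf_profile", class(out))
  out
}

# -(1/beta) log mean exp(-beta W) per grid column, evaluated with
# log-sum-exp so large beta*W cannot overflow or underflow.
.jarzynski_cols <- function(W, beta) {
  apply(W, 2, function(w) {
    z <- -beta * w
    m <- max(z)
    -(m + log(mean(exp(z - m)))) / beta
  })
}

.jackknife_sd <- function(values) {
  n <- length(values)
  if (n < 2) return(NA_real_)
  sqrt((n - 1) / n * sum((values - mean(values))^2))
}

# Leave-one-out profiles for an estimator working on the work matrix.
.jackknife_profile_sd <- function(W, estimator_fn) {
  n <- nrow(W)
  if (n < 2) return(rep(NA_real_, ncol(W)))
  loo <- vapply(seq_len(n),
                function(i) estimator_fn(W[-i, , drop = FALSE]),
                numeric(ncol(W)))
  apply(loo, 1, .jackknife_sd)
}

#' Reconstruct a PMF by the Jarzynski equality
#'
#' Applies the Jarzynski identity
#' \eqn{e^{-\beta \Delta F(\lambda)} = \langle e^{-\beta W(\lambda)}\rangle}
#' to an ensemble of pulling work curves:
#' \deqn{F(\lambda) = -\frac{1}{\beta}\ln \frac{1}{N}\sum_i
#'   e^{-\beta W_i(\lambda)}, \qquad \beta = 1/(RT),}
#' evaluated with a log-sum-exp formulation that is stable for arbitrarily
#' large \eqn{\beta W}. The profile is anchored to 0 at the first grid point
#' (the bound end of the pull). Per-point uncertainties are leave-one-out
#' jackknife standard deviations over the repeats (`NA` for a single
#' repeat).
#'
#' @param work A long work-ensemble tibble with columns `lambda_A`,
#'   `repeat_id`, `work_kcal_mol` (as produced by [sim_pull_ensemble()] or
#'   [read_work_ensemble()]); all repeats must share the grid and start at
#'   zero work.
#' @param temperature Temperature in K; defaults to the ensemble's
#'   `temperature_K` attribute.
#' @return A `pmf_profile` tibble: `lambda_A`, `pmf_kcal_mol`,
#'   `sd_kcal_mol`, with the estimator, temperature and work matrix kept as
#'   attributes for downstream jackknifing.
#' @seealso [cumulant_pmf()], [mean_work_pmf()], [pmf_delta()]
#' @export
jarzynski_pmf <- function(work, temperature = NULL) {
  wm <- .work_matrix(work, temperature)
  beta <- 1 / (.R_KCAL * wm$temperature)
  est <- function(W) {
    f <- .jarzynski_cols(W, beta)
    f - f[1]
  }
  f <- est(wm$W)
  sd <- .jackknife_profile_sd(wm$W, est)
  .new_pmf_profile(wm$lambda, f, sd, "jarzynski", wm$temperature, wm$W)
}

#' Reconstruct a PMF by the second-order cumulant expansion
#'
#' Estimates \deqn{F(\lambda) = \overline{W}(\lambda) -
#'   \frac{\beta}{2}\,s^2_W(\lambda)} with the unbiased work variance. For
#' Gaussian work distributions this equals the Jarzynski limit, and for the
#' very small repeat counts typical of steered-pulling studies it is far
#' less noisy than the raw exponential average.
#'
#' @inheritParams jarzynski_pmf
#' @return A `pmf_profile` tibble (see [jarzynski_pmf()]). Requires at
#'   least 2 repeats.
#' @export
cumulant_pmf <- function(work, temperature = NULL) {
  wm <- .work_matrix(work, temperature)
  if (nrow(wm$W) < 2) {
    abort("cumulant_pmf needs >= 2 repeats (the work variance is undefined for 1).")
  }
  beta <- 1 / (.R_KCAL * wm$temperature)
  est <- function(W) {
    f <- colMeans(W) - beta / 2 * apply(W, 2, var)
    f - f[1]
  }
  f <- est(wm$W)
  sd <- if (nrow(wm$W) >= 3) .jackknife_profile_sd(wm$W, est) else rep(NA_real_, ncol(wm$W))
  .new_pmf_profile(wm$lambda, f, sd, "cumulant2", wm$temperature, wm$W)
}

#' Mean-work profile of a pulling ensemble
#'
#' The average work \eqn{\overline{W}(\lambda)}, anchored at the first grid
#' point. By the second law it lies on or above the true PMF (and above any
#' Jarzynski reconstruction of the same ensemble); the gap is the average
#' dissipation.
#'
#' @inheritParams jarzynski_pmf
#' @return A `pmf_profile` tibble with estimator `"mean_work"`.
#' @export
mean_work_pmf <- function(work, temperature = NULL) {
  wm <- .work_matrix(work, temperature)
  est <- function(W) {
    f <- colMeans(W)
    f - f[1]
  }
  f <- est(wm$W)
  sd <- .jackknife_profile_sd(wm$W, est)
  .new_pmf_profile(wm$lambda, f, sd, "mean_work", wm$temperature, wm$W)
}

#' Free-energy difference between two points of a reconstructed PMF
#'
#' Linearly interpolates the profile at two reaction-coordinate values and
#' returns \eqn{\Delta G = F(\lambda_b) - F(\lambda_a)} with a leave-one-out
#' jackknife standard deviation: each repeat is removed in turn, the profile
#' re-estimated with the same estimator, and the SD of the resulting
#' endpoint differences reported — the repeat-based uncertainty convention
#' of small-N steered-pulling studies.
#'
#' @param profile A `pmf_profile` from [jarzynski_pmf()], [cumulant_pmf()]
#'   or [mean_work_pmf()].
#' @param lambda_a,lambda_b Reaction-coordinate values, A; must lie within
#'   the profile's grid range.
#' @return A one-row tibble: `lambda_a`, `lambda_b`, `dg_kcal_mol`,
#'   `sd_kcal_mol`.
#' @export
pmf_delta <- function(profile, lambda_a, lambda_b) {
  if (!inherits(profile, "pmf_profile")) {
    abort("`profile` must be a `pmf_profile` object.")
  }
  .check_scalar(lambda_a, "lambda_a")
  .check_scalar(lambda_b, "lambda_b")
  rng <- range(profile$lambda_A)
  for (v in c(lambda_a, lambda_b)) {
    if (v < rng[1] || v > rng[2]) {
      abort(sprintf("Coordinate %g A is outside the profile grid [%g, %g].",
                    v, rng[1], rng[2]))
    }
  }
  if (lambda_a == lambda_b) {
    return(tibble(lambda_a = lambda_a, lambda_b = lambda_b,
                  dg_kcal_mol = 0, sd_kcal_mol = 0))
  }
  interp_delta <- function(lambda, f) {
    fa <- approx(lambda, f, xout = lambda_a)$y
    fb <- approx(lambda, f, xout = lambda_b)$y
    fb - fa
  }
  dg <- interp_delta(profile$lambda_A, profile$pmf_kcal_mol)

  W <- attr(profile, "work")
  estimator <- attr(profile, "estimator")
  temperature <- attr(profile, "temperature_K")
  n <- nrow(W)
  if (n < 2) {
    abort("Jackknife uncertainty needs >= 2 repeats in the source ensemble.")
  }
  beta <- 1 / (.R_KCAL * temperature)
  est <- switch(
    estimator,
    jarzynski = function(W) .jarzynski_cols(W, beta),
    cumulant2 = function(W) {
      if (nrow(W) < 2) abort("cumulant2 jackknife needs >= 3 repeats.")
      colMeans(W) - beta / 2 * apply(W, 2, var)
    },
    mean_work = colMeans,
    abort(sprintf("Unknown estimator `%s`.", estimator))
  )
  loo <- vapply(seq_len(n), function(i) {
    f <- est(W[-i, , drop = FALSE])
    interp_delta(profile$lambda_A, f - f[1])
  }, numeric(1))
  tibble(lambda_a = lambda_a, lambda_b = lambda_b,
         dg_kcal_mol = dg, sd_kcal_mol = .jackknife_sd(loo))
}
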