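#' Simulate a phase-solubility dataset
#'
#' Generates saturation-solubility measurements of a drug across a grid of
#' total cyclodextrin concentrations from the 1:1/1:2 complexation equilibrium
#' \deqn{S_{tot} = S_0 (1 + K_{1:1}[CD] + K_{1:1}K_{1:2}[CD]^2),}
#' optionally degraded with multiplicative lognormal noise. Lognormal noise is
#' used because chromatographic quantification error scales with concentration;
#' the multiplier has unit mean so the noiseless model is also the expectation.
#'
#' @param s0 Intrinsic (cyclodextrin-free) drug solubility, mol/L (> 0).
#' @param k11 1:1 stability constant, L/mol (>= 0).
#' @param k12 1:2 stability constant (second cyclodextrin joining the 1:1
#'   complex), L/mol (>= 0).
#' @param cd_grid Total cyclodextrin concentrations, mol/L (>= 0). The default
#'   mirrors a 0-50% w/v hydroxypropyl-beta-cyclodextrin dilution series
#'   (0-403 mmol/L).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (0 disables noise). Default 0.02.
#' @param replicates Measurements per concentration (>= 1).
#' @param temperature Sample temperature, K. Recorded in the output; the
#'   equilibrium constants are temperature-specific inputs.
#' @param seed Optional integer seed; output is bit-reproducible given a seed.
#' @return A tibble with columns `cd_total_M`, `s_total_M`, `replicate`,
#'   `temperature_K`, carrying the generating parameters in
#'   `attr(, "params")` so recovery tests are self-describing.
#' @seealso [fit_ap_linearized()], [fit_loglog_stoichiometry()],
#'   [predict_total_solubility()]
#' @export
#' @examples
#' d <- sim_phase_solubility(s0 = 1e-4, k11 = 1000, k12 = 0,
#'                           noise_cv = 0, replicates = 1)
#' head(d)
sim_phase_solubility <- function(s0, k11, k12 = 0,
                                 cd_grid = c(0, 0.00806, 0.0403, 0.0806,
                                             0.1612, 0.2418, 0.403),
                                 noise_cv = 0.02, replicates = 3,
                                 temperature = 298, seed = NULL) {
  .check_scalar(s0, "s0", positive = TRUE)
  .check_scalar(k11, "k11", nonneg = TRUE)
  .check_scalar(k12, "k12", nonneg = TRUE)
  .check_numeric(cd_grid, "cd_grid", nonneg = TRUE)
  .check_scalar(noise_cv, "noise_cv", nonneg = TRUE)
  replicates <- .check_count(replicates, "replicates", min = 1L)
  .check_scalar(temperature, "temperature", positive = TRUE)

  cd <- rep(cd_grid, each = replicates)
  s_true <- s0 * (1 + k11 * cd + k11 * k12 * cd^2)
  mult <- .with_seed(seed, {
    if (noise_cv > 0) {
      sdlog <- sqrt(log1p(noise_cv^2))
      stats::rlnorm(length(cd), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      rep(1, length(cd))
    }
  })
  out <- tibble(
    cd_total_M = cd,
    s_total_M = s_true * mult,
    replicate = rep(seq_len(replicates), times = length(cd_grid)),
    temperature_K = temperature
  )
  attr(out, "params") <- list(s0 = s0, k11 = k11, k12 = k12,
                              noise_cv = noise_cv, seed = seed)
  out
}

#' Simulate constant-velocity pulling work curves on a model landscape
#'
#' Integrates overdamped (Brownian) Langevin motion of a single coordinate
#' in a model potential while a harmonic restraint of stiffness `spring_k`
#' moves away at constant `velocity`, mimicking constant-velocity steered
#' molecular dynamics. The external work
#' \deqn{W(\lambda) = k_s \int (\lambda(t) - x(t))\, v \, dt}
#' is accumulated by the trapezoidal rule and reported on a uniform grid of
#' the restraint position \eqn{\lambda}. The Euler-Maruyama update is
#' \deqn{x_{i+1} = x_i + \frac{-U'(x_i) - k_s (x_i - \lambda_i)}{\gamma}\,dt
#'   + \sqrt{2 R T \, dt / \gamma}\; \xi_i .}
#'
#' @param pmf A [`pmf_form`][pmf_forms] object (the underlying free-energy
#'   landscape the work curves should reconstruct).
#' @param spring_k Restraint stiffness, kcal/mol/A^2 (> 0).
#' @param velocity Pulling speed, A/ns (> 0). 1 A/ns is a typical steered-MD
#'   choice and the default.
#' @param friction Drag coefficient \eqn{\gamma}, kcal ns/(mol A^2) (> 0).
#' @param temperature Bath temperature, K.
#' @param duration Pull length in ns; the restraint travels
#'   `velocity * duration` Angstrom.
#' @param dt Integration step, ns. Must satisfy the stability bound
#'   `dt < friction / (10 * (spring_k + max curvature of pmf))`; violating it
#'   raises an error stating the bound.
#' @param n_repeats Number of independent pulls (>= 1).
#' @param lambda_start Initial restraint position (and particle position), A.
#' @param lambda_bins Nominal number of grid intervals for reporting work
#'   curves (default 200).
#' @param seed Optional integer seed for reproducibility.
#' @return A long tibble with columns `lambda_A`, `repeat_id`,
#'   `work_kcal_mol`; every repeat starts at zero work. Attributes:
#'   `temperature_K`, `pmf`, `spring_k`, `velocity`, `friction`.
#' @seealso [jarzynski_pmf()], [cumulant_pmf()]
#' @export
sim_pull_ensemble <- function(pmf, spring_k, velocity = 1, friction = 0.3,
                              temperature = 300, duration = 5, dt = 2e-4,
                              n_repeats = 3, lambda_start = 0,
                              lambda_bins = 200, seed = NULL) {
  if (!inherits(pmf, "pmf_form")) {
    abort("`pmf` must be a `pmf_form` object (see `pmf_quadratic()` etc.).")
  }
  .check_scalar(spring_k, "spring_k", positive = TRUE)
  .check_scalar(velocity, "velocity", positive = TRUE)
  .check_scalar(friction, "friction", positive = TRUE)
  .check_scalar(temperature, "temperature", positive = TRUE)
  .check_scalar(duration, "duration", positive = TRUE)
  .check_scalar(dt, "dt", positive = TRUE)
  n_repeats <- .check_count(n_repeats, "n_repeats", min = 1L)
  .check_scalar(lambda_start, "lambda_start")
  lambda_bins <- .check_count(lambda_bins, "lambda_bins", min = 1L)

  lambda_end <- lambda_start + velocity * duration
  curv <- pmf$curvature_max(sort(c(lambda_start, lambda_end)))
  dt_max <- friction / (10 * (spring_k + max(curv, 0)))
  if (dt >= dt_max) {
    abort(sprintf(
      "`dt` = %g ns is too large for stable integration; need dt < %g ns (friction / (10 * (spring_k + max curvature))).",
      dt, dt_max
    ))
  }

  n_steps <- max(1L, as.integer(round(duration / dt)))
  record_at <- unique(as.integer(round(seq(0L, n_steps, length.out = lambda_bins + 1L))))
  lambda_grid <- lambda_start + velocity * dt * record_at
  noise_sd <- sqrt(2 * .R_KCAL * temperature * dt / friction)

  work_mat <- .with_seed(seed, {
    x <- rep(lambda_start, n_repeats)
    W <- numeric(n_repeats)
    lam <- lambda_start
    f_prev <- spring_k * (lam - x) * velocity # zero at start
    out <- matrix(0, nrow = n_repeats, ncol = length(record_at))
    rec <- 1L
    if (record_at[1L] == 0L) rec <- 2L
    for (i in seq_len(n_steps)) {
      drift <- (-pmf$gradient(x) - spring_k * (x - lam)) / friction
      x <- x + drift * dt + noise_sd * stats::rnorm(n_repeats)
      lam <- lambda_start + velocity * i * dt
      f_cur <- spring_k * (lam - x) * velocity
      W <- W + 0.5 * (f_prev + f_cur) * dt
      f_prev <- f_cur
      if (rec <= length(record_at) && i == record_at[rec]) {
        out[, rec] <- W
        rec <- rec + 1L
      }
    }
    out
  })

  out <- tibble(
    lambda_A = rep(lambda_grid, each = n_repeats),
    repeat_id = rep(seq_len(n_repeats), times = length(lambda_grid)),
    work_kcal_mol = as.vector(work_mat)
  )
  out <- dplyr::arrange(out, .data$repeat_id, .data$lambda_A)
  attr(out, "temperature_K") <- temperature
  attr(out, "pmf") <- pmf
  attr(out, "spring_k") <- spring_k
  attr(out, "velocity") <- velocity
  attr(out, "friction") <- friction
  out
}

#' Simulate a piecewise-Gaussian centroid-distance trajectory
#'
#' Emits a distance time series built from ordered segments, each with its own
#' mean and standard deviation — a minimal stand-in for the centroid-distance
#' regimes seen when a drug binds, enters and is covered by cyclodextrin
#' molecules during a simulation.
#'
#' @param segments A data frame with columns `state`, `duration_ns`,
#'   `mean_A`, `sd_A`; one row per regime, in temporal order.
#' @param dt Sampling interval, ns (> 0).
#' @param seed Optional integer seed.
#' @return A tibble with columns `time_ns`, `distance_A`, `state`
#'   (class `distance_series`). Distances are truncated at zero.
#' @export
#' @examples
#' seg <- tibble::tibble(state = c("inclusion", "dual"),
#'                       duration_ns = c(0.5, 1.5),
#'                       mean_A = c(5.297, 5.120), sd_A = c(0.373, 0.883))
#' traj <- sim_state_trajectory(seg, dt = 0.002, seed = 1)
sim_state_trajectory <- function(segments, dt = 0.002, seed = NULL) {
  if (!is.data.frame(segments) || nrow(segments) == 0) {
    abort("`segments` must be a data frame with at least one row.")
  }
  .require_columns(segments, c("state", "duration_ns", "mean_A", "sd_A"),
                   "`segments`")
  .check_numeric(segments$duration_ns, "segments$duration_ns")
  if (any(segments$duration_ns <= 0)) {
    abort("`segments$duration_ns` must be > 0 for every segment.")
  }
  .check_numeric(segments$sd_A, "segments$sd_A", nonneg = TRUE)
  .check_scalar(dt, "dt", positive = TRUE)

  n_per <- pmax(1L, as.integer(round(segments$duration_ns / dt)))
  values <- .with_seed(seed, {
    unlist(purrr::map(seq_len(nrow(segments)), function(i) {
      stats::rnorm(n_per[i], mean = segments$mean_A[i], sd = segments$sd_A[i])
    }))
  })
  out <- tibble(
    time_ns = dt * (seq_along(values) - 1L),
    distance_A = pmax(values, 0),
    state = rep(segments$state, times = n_per)
  )
  class(out) <- c("distance_series", class(out))
  out
}
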