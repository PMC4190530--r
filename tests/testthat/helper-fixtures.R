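# Shared fixture builders. Everything is generated in code; no stored data.

# Noiseless phase-solubility dataset straight from the equilibrium model.
noiseless_phase <- function(s0, k11, k12 = 0,
                            cd_grid = c(0, 0.00806, 0.0403, 0.0806,
                                        0.1612, 0.2418, 0.403),
                            temperature = 298) {
  sim_phase_solubility(s0, k11, k12, cd_grid = cd_grid, noise_cv = 0,
                       replicates = 1, temperature = temperature)
}

# Work ensemble with i.i.d. Gaussian work at each grid point (zero at the
# first point), the analytic reference case for the Jarzynski estimator:
# F(lambda) -> mu(lambda) - beta * sigma^2 / 2.
gaussian_work_ensemble <- function(mu, sigma, n_repeats, temperature,
                                   lambda = seq_along(mu) - 1, seed = 1) {
  stopifnot(length(mu) == length(lambda))
  withr::with_seed(seed, {
    W <- vapply(seq_along(mu), function(j) {
      if (j == 1) rep(0, n_repeats) else stats::rnorm(n_repeats, mu[j], sigma)
    }, numeric(n_repeats))
    out <- tibble::tibble(
      lambda_A = rep(lambda, each = n_repeats),
      repeat_id = rep(seq_len(n_repeats), times = length(lambda)),
      work_kcal_mol = as.vector(W)
    )
    attr(out, "temperature_K") <- temperature
    out
  })
}

# Work ensemble built from explicit per-repeat curves (rows of `mat`).
work_from_matrix <- function(mat, lambda = seq_len(ncol(mat)) - 1,
                             temperature = 300) {
  out <- tibble::tibble(
    lambda_A = rep(lambda, each = nrow(mat)),
    repeat_id = rep(seq_len(nrow(mat)), times = length(lambda)),
    work_kcal_mol = as.vector(mat)
  )
  attr(out, "temperature_K") <- temperature
  out
}

# Temperature at which beta = 1/(R T) equals 1 (mol K / kcal units).
temp_beta1 <- function() 1 / gas_constant_kcal()
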