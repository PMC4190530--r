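# Synthetic-data generators: forward models, noise structure, determinism.

test_that("noiseless phase-solubility data lie exactly on the forward model", {
  flat <- sim_phase_solubility(1e-4, k11 = 0, k12 = 0, noise_cv = 0,
                               replicates = 2)
  expect_equal(flat$s_total_M, rep(1e-4, nrow(flat)))

  one_to_one <- sim_phase_solubility(1e-4, k11 = 1000, k12 = 0,
                                     cd_grid = 0.01, noise_cv = 0,
                                     replicates = 1)
  expect_equal(one_to_one$s_total_M, 1.1e-3)

  # closed-form evaluation frozen from an independent hand calculation:
  # 1e-5 * (1 + 6.5*0.4 + 6.5*12370*0.16) = 0.128684
  mixed <- sim_phase_solubility(1e-5, k11 = 6.5, k12 = 12370,
                                cd_grid = 0.4, noise_cv = 0, replicates = 1)
  expect_equal(mixed$s_total_M, 0.128684, tolerance = 1e-12)
})

test_that("lognormal noise has unit mean and the requested CV", {
  d <- sim_phase_solubility(1e-4, k11 = 500, cd_grid = 0.05, noise_cv = 0.1,
                            replicates = 4000, seed = 7)
  truth <- 1e-4 * (1 + 500 * 0.05)
  ratio <- d$s_total_M / truth
  expect_equal(mean(ratio), 1, tolerance = 3 * 0.1 / sqrt(4000))
  expect_equal(sd(ratio) / mean(ratio), 0.1, tolerance = 0.01)
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- sim_phase_solubility(1e-5, 100, 50, noise_cv = 0.02, seed = 11)
  b <- sim_phase_solubility(1e-5, 100, 50, noise_cv = 0.02, seed = 11)
  expect_identical(a$s_total_M, b$s_total_M)
  c <- sim_phase_solubility(1e-5, 100, 50, noise_cv = 0.02, seed = 12)
  expect_false(identical(a$s_total_M, c$s_total_M))

  w1 <- sim_pull_ensemble(pmf_quadratic(1), spring_k = 20, duration = 0.5,
                          dt = 1e-3, n_repeats = 3, seed = 5)
  w2 <- sim_pull_ensemble(pmf_quadratic(1), spring_k = 20, duration = 0.5,
                          dt = 1e-3, n_repeats = 3, seed = 5)
  expect_identical(w1$work_kcal_mol, w2$work_kcal_mol)

  t1 <- sim_state_trajectory(tibble::tibble(state = "a", duration_ns = 1,
                                            mean_A = 5, sd_A = 0.5), seed = 3)
  t2 <- sim_state_trajectory(tibble::tibble(state = "a", duration_ns = 1,
                                            mean_A = 5, sd_A = 0.5), seed = 3)
  expect_identical(t1$distance_A, t2$distance_A)
})

test_that("invalid generator specifications name the offending field", {
  expect_error(sim_phase_solubility(-1, 100), "`s0`")
  expect_error(sim_phase_solubility(1e-4, -5), "`k11`")
  expect_error(sim_phase_solubility(1e-4, 100, noise_cv = -0.1), "`noise_cv`")
  expect_error(sim_phase_solubility(1e-4, 100, replicates = 0), "`replicates`")
  expect_error(sim_phase_solubility(1e-4, 100, cd_grid = c(0.1, -0.2)),
               "`cd_grid`")
  expect_error(sim_state_trajectory(tibble::tibble()), "segments")
  expect_error(
    sim_state_trajectory(tibble::tibble(state = "a", duration_ns = -1,
                                        mean_A = 5, sd_A = 0)),
    "duration_ns"
  )
})

test_that("pulling on a flat landscape with negligible thermal noise costs no work", {
  # dissipation scales with friction (gamma v L), so drag must be tiny too
  w <- sim_pull_ensemble(pmf_flat(), spring_k = 1, velocity = 1,
                         friction = 1e-4, temperature = 1e-12, duration = 1,
                         dt = 5e-6, n_repeats = 1, seed = 1)
  expect_lt(max(abs(w$work_kcal_mol)), 1e-3)
})

test_that("quasi-static pulling work approaches the PMF difference", {
  # stiff spring, weak drag, noise off: W(end) ~ U(end) - U(start)
  w <- sim_pull_ensemble(pmf_quadratic(0.5), spring_k = 20, velocity = 1,
                         friction = 0.02, temperature = 1e-12, duration = 3,
                         dt = 5e-5, n_repeats = 1, seed = 1)
  w_end <- max(w$work_kcal_mol)
  expect_lt(abs(w_end - 0.5 * 0.5 * 9), 0.3)
})

test_that("mean pulling work dominates the true PMF difference (second law)", {
  pmf <- pmf_quadratic(1)
  w <- sim_pull_ensemble(pmf, spring_k = 30, velocity = 1, friction = 0.3,
                         temperature = 300, duration = 2, dt = 2e-4,
                         n_repeats = 120, seed = 21)
  by_lambda <- dplyr::summarise(
    dplyr::group_by(w, lambda_A),
    mean_w = mean(work_kcal_mol),
    se = sd(work_kcal_mol) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  truth <- pmf$energy(by_lambda$lambda_A) - pmf$energy(0)
  expect_true(all(by_lambda$mean_w >= truth - 3 * by_lambda$se))
})

test_that("integrator refuses an unstable time step and states the bound", {
  expect_error(
    sim_pull_ensemble(pmf_quadratic(5), spring_k = 100, friction = 0.1,
                      duration = 1, dt = 0.01, n_repeats = 1),
    "dt <"
  )
})

test_that("piecewise trajectories reproduce the requested segment statistics", {
  const <- sim_state_trajectory(
    tibble::tibble(state = "inclusion", duration_ns = 1, mean_A = 5.297,
                   sd_A = 0),
    dt = 0.01, seed = 1
  )
  expect_true(all(const$distance_A == 5.297))

  seg <- tibble::tibble(state = c("first", "second"),
                        duration_ns = c(4, 4),
                        mean_A = c(5.120, 6.735),
                        sd_A = c(0.883, 0.538))
  traj <- sim_state_trajectory(seg, dt = 0.002, seed = 9)
  n <- 2000
  first <- traj$distance_A[traj$state == "first"]
  second <- traj$distance_A[traj$state == "second"]
  expect_equal(mean(first), 5.120, tolerance = 3 * 0.883 / sqrt(n) / 5.120)
  expect_equal(mean(second), 6.735, tolerance = 3 * 0.538 / sqrt(n) / 6.735)
})
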