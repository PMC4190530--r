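# Phase-solubility diagram classification and stability-constant estimation.

test_that("diagram classification separates linear and positively curved profiles", {
  linear <- noiseless_phase(1e-4, k11 = 1000)
  expect_identical(suppressWarnings(classify_profile(linear))$label, "A_L")

  curved <- noiseless_phase(1e-5, k11 = 6.5, k12 = 12370)
  expect_identical(suppressWarnings(classify_profile(curved))$label, "A_p")

  # significantly negative curvature is flagged, not forced into A_L
  neg <- tibble::tibble(cd_total_M = seq(0, 0.4, length.out = 9))
  neg$s_total_M <- 1e-4 * (1 + 2 * neg$cd_total_M - 3 * neg$cd_total_M^2)
  expect_identical(suppressWarnings(classify_profile(neg))$label,
                   "indeterminate")

  few <- noiseless_phase(1e-4, 100, cd_grid = c(0, 0.1, 0.2))
  expect_error(classify_profile(few), ">= 4 distinct")
  expect_error(classify_profile(linear, alpha = 2), "alpha")
})

test_that("noiseless 1:1 data never classify as A_p (property over k11, alpha)", {
  for (k11 in c(5, 100, 1000, 5000)) {
    d <- noiseless_phase(1e-4, k11 = k11)
    for (alpha in c(0.01, 0.05)) {
      expect_false(suppressWarnings(classify_profile(d, alpha))$label == "A_p")
    }
  }
})

test_that("log-log slope is exactly 1 for pure 1:1 and in (1,2) for mixed data", {
  pure <- noiseless_phase(1e-4, k11 = 750)
  fit <- suppressWarnings(fit_loglog_stoichiometry(pure))
  expect_equal(fit$n_hat, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  mixed <- noiseless_phase(1e-5, k11 = 6.5, k12 = 12370)
  n_hat <- suppressWarnings(fit_loglog_stoichiometry(mixed))$n_hat
  # frozen value from an independent least-squares oracle on this grid
  expect_equal(n_hat, 1.9975800339970042, tolerance = 1e-9)
  expect_gt(n_hat, 1)
  expect_lt(n_hat, 2)

  gentle <- noiseless_phase(1e-4, k11 = 100, k12 = 5)
  n2 <- suppressWarnings(fit_loglog_stoichiometry(gentle))$n_hat
  expect_gt(n2, 1)
  expect_lt(n2, 2)
})

test_that("log-log fit refuses points at or below the intrinsic solubility", {
  d <- noiseless_phase(1e-4, k11 = 100)
  d$s_total_M[3] <- 0.9e-4
  expect_error(fit_loglog_stoichiometry(d), "s_total_M <= s0")
  expect_error(fit_loglog_stoichiometry(d), "row")
})

test_that("replicated noiseless data give the same slope as replicate means", {
  reps <- sim_phase_solubility(1e-4, 200, 10, noise_cv = 0, replicates = 3)
  avg <- dplyr::summarise(dplyr::group_by(reps, cd_total_M),
                          s_total_M = mean(s_total_M), .groups = "drop")
  f1 <- suppressWarnings(fit_loglog_stoichiometry(reps, s0 = 1e-4))
  f2 <- suppressWarnings(fit_loglog_stoichiometry(avg, s0 = 1e-4))
  expect_equal(f1$n_hat, f2$n_hat, tolerance = 1e-12)
})

test_that("A_L slope formula recovers K1:1 and rejects inadmissible slopes", {
  # exact slope 0.5 with s0 = 1e-3: K = 0.5 / (1e-3 * 0.5) = 1000
  d <- tibble::tibble(cd_total_M = seq(0, 0.1, by = 0.02))
  d$s_total_M <- 1e-3 + 0.5 * d$cd_total_M
  fit <- suppressWarnings(fit_al_k11(d, s0 = 1e-3))
  expect_equal(fit$k11, 1000, tolerance = 1e-9)
  expect_equal(fit$k12, 0)

  # total-CD convention: the generator slope k11*s0 = 0.1 maps to ~1111.1
  gen <- noiseless_phase(1e-4, k11 = 1000, cd_grid = seq(0, 0.1, by = 0.02))
  fit2 <- suppressWarnings(fit_al_k11(gen))
  expect_equal(fit2$k11, 0.1 / (1e-4 * 0.9), tolerance = 1e-6)

  # data generated under the free-CD mass balance return the true constant
  cd <- seq(0, 0.1, by = 0.02)
  free <- tibble::tibble(
    cd_total_M = cd,
    s_total_M = predict_total_solubility(1e-4, 1000, 0, cd,
                                         free_cd_correction = TRUE)
  )
  fit3 <- suppressWarnings(fit_al_k11(free, s0 = 1e-4))
  expect_equal(fit3$k11, 1000, tolerance = 1e-6)

  steep <- tibble::tibble(cd_total_M = cd, s_total_M = 1e-3 + 1.2 * cd)
  expect_error(suppressWarnings(fit_al_k11(steep, s0 = 1e-3)),
               "inadmissible")
  flat <- tibble::tibble(cd_total_M = cd, s_total_M = 1e-3 - 0.001 * cd)
  expect_error(suppressWarnings(fit_al_k11(flat, s0 = 1e-3)), "<= 0")
})

test_that("linearized A_p fit is exact on noiseless model data", {
  d <- noiseless_phase(1e-5, k11 = 100, k12 = 50)
  fit <- suppressWarnings(fit_ap_linearized(d))
  expect_equal(fit$k11, 100, tolerance = 1e-9)
  expect_equal(fit$k12, 50, tolerance = 1e-9)
  expect_true(all(diag(fit$covariance) >= 0))

  pure <- noiseless_phase(1e-5, k11 = 100)
  fp <- suppressWarnings(fit_ap_linearized(pure))
  expect_equal(fp$k12, 0)

  # a diagram implying negative K1:1 is an error, not a clamped estimate
  cd <- seq(0.01, 0.1, by = 0.01)
  bad <- tibble::tibble(cd_total_M = cd, s_total_M = 1 - cd + 5 * cd^2)
  expect_error(fit_ap_linearized(bad, s0 = 1), "negative K1:1")
})

test_that("nonlinear A_p fit matches truth, boundaries and the linearized fit", {
  d <- noiseless_phase(1e-5, k11 = 100, k12 = 50)
  fit <- suppressWarnings(fit_ap_nonlinear(d))
  expect_lt(abs(fit$k11 - 100) / 100, 1e-6)
  expect_lt(abs(fit$k12 - 50) / 50, 1e-6)

  pure <- noiseless_phase(1e-5, k11 = 100)
  fp <- suppressWarnings(fit_ap_nonlinear(pure))
  expect_lt(fp$k12, 1e-6)

  noisy <- sim_phase_solubility(1e-5, 100, 50, noise_cv = 0.02,
                                cd_grid = seq(0.4 / 21, 0.4, length.out = 21),
                                replicates = 1, seed = 31)
  lin <- fit_ap_linearized(noisy, s0 = 1e-5)
  nl <- fit_ap_nonlinear(noisy, s0 = 1e-5)
  se <- sqrt(pmax(diag(lin$covariance), 0))
  expect_lt(abs(nl$k11 - lin$k11), 3 * se["k11"])
  expect_lt(abs(nl$k12 - lin$k12), 3 * se["k12"])
})

test_that("noiseless round trip recovers random admissible parameter sets", {
  withr::with_seed(17, {
    for (i in 1:8) {
      s0 <- 10^stats::runif(1, -6, -3)
      k11 <- 10^stats::runif(1, 0.5, 3)
      k12 <- 10^stats::runif(1, 0, 2.5)
      d <- noiseless_phase(s0, k11, k12)
      lin <- suppressWarnings(fit_ap_linearized(d))
      nl <- suppressWarnings(fit_ap_nonlinear(d))
      expect_lt(abs(lin$k11 - k11) / k11, 1e-6)
      expect_lt(abs(lin$k12 - k12) / k12, 1e-6)
      expect_lt(abs(nl$k11 - k11) / k11, 1e-6)
      expect_lt(abs(nl$k12 - k12) / k12, 1e-6)
    }
  })
})

test_that("solubility prediction handles zero CD, monotonicity and the free-CD root", {
  expect_equal(predict_total_solubility(1e-4, 1000, 0, 0), 1e-4)
  expect_equal(predict_total_solubility(1e-4, 1000, 0, 0.01), 1.1e-3)

  withr::with_seed(23, {
    for (i in 1:6) {
      s0 <- 10^stats::runif(1, -6, -3)
      k11 <- 10^stats::runif(1, 0, 3)
      k12 <- 10^stats::runif(1, 0, 3)
      cd <- sort(stats::runif(12, 0, 0.5))
      for (corr in c(FALSE, TRUE)) {
        s <- predict_total_solubility(s0, k11, k12, cd,
                                      free_cd_correction = corr)
        expect_true(all(diff(s) >= -1e-12))
      }
    }
  })

  # frozen values from an independent bisection oracle on the mass balance
  s_off <- predict_total_solubility(1e-5, 6.5, 12370, 0.4)
  s_on <- predict_total_solubility(1e-5, 6.5, 12370, 0.4,
                                   free_cd_correction = TRUE)
  expect_equal(s_off, 0.128684, tolerance = 1e-12)
  expect_equal(s_on, 0.06162634460902768, tolerance = 1e-6)
  expect_lt(s_on, s_off)
})

test_that("tidy and glance expose estimates in broom form", {
  d <- noiseless_phase(1e-5, k11 = 100, k12 = 50)
  lin <- suppressWarnings(fit_ap_linearized(d))
  td <- tidy(lin)
  expect_identical(td$term, c("k11", "k12"))
  expect_equal(td$estimate, c(100, 50), tolerance = 1e-8)
  expect_identical(glance(lin)$fit_method, "ap_linearized")

  st <- suppressWarnings(fit_loglog_stoichiometry(noiseless_phase(1e-4, 750)))
  expect_equal(suppressWarnings(tidy(st))$estimate[1], 1, tolerance = 1e-10)
  expect_equal(glance(st)$r.squared, 1, tolerance = 1e-10)
})
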