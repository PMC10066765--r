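test_that("random-effect draws are reproducible and match the requested spread", {
  pop <- population_params(omega_cl32 = 0.495, sigma_prop = 0.375)
  expect_identical(draw_etas(pop, 50, seed = 9), draw_etas(pop, 50, seed = 9))
  expect_false(identical(draw_etas(pop, 50, seed = 9),
                         draw_etas(pop, 50, seed = 10)))
  pop0 <- population_params(omega_cl32 = 0, sigma_prop = 0.375)
  expect_identical(draw_etas(pop0, 20, seed = 1), rep(0, 20))
  # law of large numbers
  e <- draw_etas(pop, 1e5, seed = 4)
  expect_equal(stats::sd(e), 0.495, tolerance = 0.01)
  expect_equal(mean(e), 0, tolerance = 0.01)
})

test_that("log-normal CV conversion round-trips and matches the closed form", {
  expect_equal(cv_from_omega(0), 0)
  expect_equal(omega_from_cv(52.7), sqrt(log(1 + 0.527^2)), tolerance = 1e-12)
  expect_equal(cv_from_omega(omega_from_cv(52.7)), 52.7, tolerance = 1e-12)
  om <- c(0.1, 0.3, 0.495, 1.2)
  expect_equal(omega_from_cv(cv_from_omega(om)), om, tolerance = 1e-12)
})

test_that("individual parameters apply the CL32 random effect only", {
  pk <- TRUTH$pk
  ind0 <- individual("a", 0.025, eta_cl32 = 0)
  expect_equal(individual_params(pk, ind0), allometric_scale(pk, 0.025))
  ind2 <- individual("b", 0.025, eta_cl32 = log(2))
  r0 <- allometric_scale(pk, 0.025)
  r2 <- individual_params(pk, ind2)
  expect_equal(r2$CL32, 2 * r0$CL32, tolerance = 1e-12)
  expect_equal(r2$k32, 2 * r0$k32, tolerance = 1e-12)
  for (nm in c("CL12", "CL23", "CL20", "V", "V2", "k12", "k23", "k20")) {
    expect_identical(r2[[nm]], r0[[nm]])
  }
})

test_that("median of simulated CL32 matches the typical value (log-normal median)", {
  pk <- TRUTH$pk
  pop <- population_params(omega_cl32 = 0.495, sigma_prop = 0.375)
  etas <- draw_etas(pop, 2e4, seed = 5)
  cl32 <- allometric_scale(pk, 0.025)$CL32 * exp(etas)
  expect_equal(stats::median(cl32), allometric_scale(pk, 0.025)$CL32,
               tolerance = 0.02)
  # empirical CV matches the reporting convention
  expect_equal(100 * stats::sd(cl32) / mean(cl32), cv_from_omega(0.495),
               tolerance = 0.03)
})

test_that("proportional residual error has the right spread and a logged floor", {
  f <- rep(100, 1e5)
  y <- apply_residual_error(f, 0.375, seed = 2)
  expect_equal(stats::sd(y), 37.5, tolerance = 0.01 * 37.5)
  expect_identical(attr(apply_residual_error(f[1:10], 0, seed = 1), "n_floored"), 0L)
  expect_equal(as.numeric(apply_residual_error(f[1:10], 0, seed = 1)), f[1:10])
  expect_equal(as.numeric(apply_residual_error(rep(0, 5), 0.375, seed = 3)),
               rep(0, 5))
  expect_gte(attr(y, "n_floored"), 0)
})

test_that("noise-free population simulation reduces to the structural model", {
  pop0 <- population_params(omega_cl32 = 0, sigma_prop = 1e-300)
  pop0$sigma_obs[] <- 0
  pop0$sigma_prop <- 0
  cohort <- list(individual("s1", 0.025))
  times <- c(1, 4, 24, 48)
  d <- simulate_population(TRUTH$pk, TRUTH$pd, TRUTH$biomarkers, pop0, cohort,
                           dose_per_kg = 1, n_doses = 1,
                           sampling = list(mrna = times, pcc = times),
                           seed = 11)
  sim <- simulate_pkpd(TRUTH$pk, TRUTH$pd, 0.025, dose_event(0, 0.025), times)
  obs <- d[d$evid == 0, ]
  expect_equal(obs$dv[obs$dvid == "mrna"], sim$conc, tolerance = 1e-8)
  expect_equal(obs$dv[obs$dvid == "pcc"], sim$p_total, tolerance = 1e-8)
})

test_that("population dataset has the expected record layout and determinism", {
  pop <- TRUTH$pop
  cohort <- make_cohort(4, "mouse", seed = 3)
  d1 <- simulate_population(TRUTH$pk, TRUTH$pd, TRUTH$biomarkers, pop, cohort,
                            dose_per_kg = c(1, 1, 2, 2), interval = 504,
                            n_doses = 2,
                            sampling = list(mrna = c(1, 24), `2mc` = c(24, 600)),
                            seed = 7)
  expect_s3_class(d1, "pkpd_dataset")
  expect_identical(sum(d1$evid == 1), 4L * 2L)
  expect_identical(sum(d1$evid == 0), 4L * (2L + 2L))
  d2 <- simulate_population(TRUTH$pk, TRUTH$pd, TRUTH$biomarkers, pop, cohort,
                            dose_per_kg = c(1, 1, 2, 2), interval = 504,
                            n_doses = 2,
                            sampling = list(mrna = c(1, 24), `2mc` = c(24, 600)),
                            seed = 7)
  expect_identical(d1, d2)
  d3 <- simulate_population(TRUTH$pk, TRUTH$pd, TRUTH$biomarkers, pop, cohort,
                            dose_per_kg = c(1, 1, 2, 2), interval = 504,
                            n_doses = 2,
                            sampling = list(mrna = c(1, 24), `2mc` = c(24, 600)),
                            seed = 8)
  expect_false(identical(d1$dv, d3$dv))
  expect_true(validate_dataset(d1)$id[1] == d1$id[1])
})

test_that("dose amounts are body weight times the mg/kg dose level", {
  cohort <- make_cohort(3, "rat", seed = 2)
  d <- simulate_population(TRUTH$pk, NULL, NULL, TRUTH$pop, cohort,
                           dose_per_kg = 3, n_doses = 1,
                           sampling = list(mrna = c(1, 24)), seed = 5)
  doses <- d[d$evid == 1, ]
  expect_equal(doses$amt, 3 * doses$wt, tolerance = 1e-12)
})
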