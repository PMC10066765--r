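test_that("allometric scaling reduces to typical values at the reference weight", {
  pk <- TRUTH$pk
  r <- allometric_scale(pk, pk$wt_ref)
  expect_identical(r$CL12, pk$tvCL12)
  expect_identical(r$CL23, pk$tvCL23)
  expect_identical(r$CL32, pk$tvCL32)
  expect_identical(r$CL20, pk$tvCL20)
  expect_identical(r$V, pk$tvV)
  expect_identical(r$V2, pk$tvV2)
})

test_that("allometric scaling matches direct power-law arithmetic at 70 kg", {
  r <- allometric_scale(TRUTH$pk, 70)
  expect_equal(r$CL12, 19.7 * 70^0.631, tolerance = 1e-12)
  expect_equal(r$CL32, 2.96 * 70^0.631, tolerance = 1e-12)
  expect_equal(r$CL23, 0.215 * 70^1.10, tolerance = 1e-12)
  expect_equal(r$CL20, 0.136 * 70^1.10, tolerance = 1e-12)
  expect_equal(r$V, 2.67 * 70, tolerance = 1e-12)
  expect_equal(r$k12, r$CL12 / r$V, tolerance = 1e-12)
  expect_equal(r$k23, r$CL23 / r$V2, tolerance = 1e-12)
})

test_that("zero exponents make scaling weight-independent", {
  pk <- pk_params(19.7, 0.215, 2.96, 0.136, 2.67, 0.961,
                  cl_alpha = 0, cl_beta = 0, v_exponent = 0)
  for (wt in c(0.02, 1, 70)) {
    r <- allometric_scale(pk, wt)
    expect_equal(r$CL12, 19.7)
    expect_equal(r$CL20, 0.136)
    expect_equal(r$V, 2.67)
  }
})

test_that("non-positive body weight is rejected with the subject named", {
  expect_error(allometric_scale(TRUTH$pk, -1, id = "m-7"), "m-7")
  expect_error(allometric_scale(TRUTH$pk, 0), "non-positive")
})

test_that("pk_derivatives equals the independently assembled system matrix", {
  set.seed(42)
  for (rep in 1:20) {
    k <- stats::runif(4, 0.01, 5)
    rates <- rate_list(k[1], k[2], k[3], k[4])
    a <- stats::runif(3, 0, 10)
    A <- rbind(c(-k[1], 0, 0),
               c(k[1], -(k[2] + k[4]), k[3]),
               c(0, k[2], -k[3]))
    expect_equal(pk_derivatives(a, 0, rates), drop(A %*% a),
                 tolerance = 1e-12)
  }
  rates <- rate_list(1, 2, 3, 4)
  expect_equal(pk_derivatives(c(0, 0, 0), 0, rates), c(0, 0, 0))
  # mass conservation when the tissue sink is closed
  rates0 <- rate_list(0.7, 1.3, 0.4, 0)
  d <- pk_derivatives(c(2, 5, 1), 0, rates0, infusion_rate = 3)
  expect_equal(sum(d), 3, tolerance = 1e-12)
})

test_that("simulated PK profile matches the matrix-exponential closed form", {
  pk <- TRUTH$pk
  wt <- 0.025
  doses <- list(dose_event(0, 0.05), dose_event(504, 0.05))
  times <- c(0.25, 1, 4, 24, 48, 168, 504.5, 506, 600)
  rates <- allometric_scale(pk, wt)
  A <- rbind(c(-rates$k12, 0, 0),
             c(rates$k12, -(rates$k23 + rates$k20), rates$k32),
             c(0, rates$k23, -rates$k32))
  ref <- expm_reference(A, numeric(3), data.frame(
    time = c(0, 504), amount = c(0.05, 0.05), duration = c(0, 0)), times)
  for (m in c("ode", "linear")) {
    sim <- simulate_pk(pk, wt, doses, times, method = m)
    expect_equal(sim$conc, ref[, 3] / rates$V * 1e6, tolerance = 1e-6)
  }
})

test_that("infusions match the matrix-exponential closed form", {
  pk <- toy_pk()
  rates <- allometric_scale(pk, 2)
  doses <- list(dose_event(0, 1, duration = 2), dose_event(10, 0.5, duration = 1))
  times <- c(0.5, 1.5, 2, 3, 9, 10.5, 11, 20)
  A <- rbind(c(-rates$k12, 0, 0),
             c(rates$k12, -(rates$k23 + rates$k20), rates$k32),
             c(0, rates$k23, -rates$k32))
  ref <- expm_reference(A, numeric(3), data.frame(
    time = c(0, 10), amount = c(1, 0.5), duration = c(2, 1)), times)
  for (m in c("ode", "linear")) {
    sim <- simulate_pk(pk, 2, doses, times, method = m)
    expect_equal(sim$conc, ref[, 3] / rates$V * 1e6, tolerance = 1e-6)
  }
})

test_that("a bolus gives zero observed concentration at t = 0 and delayed Cmax", {
  times <- sort(c(0, 10^seq(-2, log10(48), length.out = 120)))
  sim <- simulate_pk(TRUTH$pk, 0.025, dose_event(0, 0.05), times)
  expect_equal(sim$conc[1], 0)
  expect_gt(which.max(sim$conc), 1)
  expect_gt(max(sim$conc), 0)
})

test_that("PK is linear in dose", {
  times <- c(0.5, 2, 8, 24, 48)
  s1 <- simulate_pk(TRUTH$pk, 0.025, dose_event(0, 0.025), times,
                    method = "linear")
  s2 <- simulate_pk(TRUTH$pk, 0.025, dose_event(0, 0.050), times,
                    method = "linear")
  expect_equal(s2$conc, 2 * s1$conc, tolerance = 1e-10)
})

test_that("mass balance holds when the elimination clearance is zero", {
  rates <- rate_list(5, 0.5, 2, 0)  # closed system
  A <- rbind(c(-rates$k12, 0, 0),
             c(rates$k12, -(rates$k23 + rates$k20), rates$k32),
             c(0, rates$k23, -rates$k32))
  df <- data.frame(time = c(0, 5), amount = c(1, 2), duration = c(0, 3))
  times <- c(1, 4, 5.5, 8, 12, 50)
  st <- mrnapkpd:::integrate_piecewise(A, numeric(3), df, times)
  dosed <- c(1, 1, 1 + 2 * 0.5 / 3, 1 + 2, 1 + 2, 1 + 2)
  expect_equal(rowSums(st), dosed, tolerance = 1e-7)
})

test_that("protein is absent without synthesis and scales with the gain", {
  pk <- TRUTH$pk
  times <- c(12, 48, 168, 504)
  pd0 <- pd_params(ke0 = 0.1, ksyn_slope = 0, kdeg = 0.03, kq = 0.005)
  s0 <- simulate_pkpd(pk, pd0, 0.025, dose_event(0, 0.05), times)
  expect_equal(s0$p_total, rep(0, 4))
  pd1 <- toy_pd()
  pd2 <- pd_params(pd1$ke0, 2 * pd1$ksyn_slope, pd1$kdeg, pd1$kq)
  s1 <- simulate_pkpd(pk, pd1, 0.025, dose_event(0, 0.05), times,
                      method = "linear")
  s2 <- simulate_pkpd(pk, pd2, 0.025, dose_event(0, 0.05), times,
                      method = "linear")
  expect_equal(s2$p_total, 2 * s1$p_total, tolerance = 1e-10)
})

test_that("terminal protein decline matches the slow eigenvalue of the subsystem", {
  pd <- TRUTH$pd
  M <- rbind(c(-(pd$kdeg + pd$kq), pd$kq), c(pd$kq, -pd$kq))
  lam_slow <- max(eigen(M, only.values = TRUE)$values)
  # long after mRNA elimination the log of total protein declines linearly
  times <- seq(3000, 6000, by = 100)
  sim <- simulate_pkpd(TRUTH$pk, pd, 0.025, dose_event(0, 0.05), times,
                       method = "linear")
  slope <- stats::coef(stats::lm(log(sim$p_total) ~ times))[2]
  expect_equal(unname(slope), lam_slow, tolerance = 1e-3)
})

test_that("protein terminal half-life: closed form, calibration and simulation", {
  expect_equal(protein_terminal_halflife(pd_params(1, 0, kdeg = 0.02, kq = 0)),
               log(2) / 0.02, tolerance = 1e-12)
  expect_equal(protein_terminal_halflife(TRUTH$pd), 168, tolerance = 1e-9)
  # arbitrary rates: read the half-life off a simulated decay tail
  pd <- pd_params(0.2, 0.1, kdeg = 0.011, kq = 0.003)
  times <- seq(4000, 9000, by = 100)
  sim <- simulate_pkpd(TRUTH$pk, pd, 0.025, dose_event(0, 0.05), times,
                       method = "linear")
  slope <- stats::coef(stats::lm(log(sim$p_total) ~ times))[2]
  expect_equal(protein_terminal_halflife(pd), -log(2) / unname(slope),
               tolerance = 1e-3)
  expect_error(protein_terminal_halflife(structure(
    list(kdeg = 0, kq = 1), class = "pd_params")), "kdeg")
})

test_that("biomarker Imax relation: baseline, half-maximal point, asymptote", {
  bp <- biomarker_params("2mc", e0 = 7.26, base = 12.74, ic50 = 21,
                         imax = 0.999, gamma = 1)
  expect_equal(biomarker_level(0, bp), 7.26 + 12.74)
  expect_equal(biomarker_level(21, bp), 7.26 + 12.74 * (1 - 0.999 / 2),
               tolerance = 1e-12)
  expect_equal(biomarker_level(1e9, bp), 7.26 + 12.74 * (1 - 0.999),
               tolerance = 1e-4)
})

test_that("biomarker level is non-increasing in protein for random parameter sets", {
  set.seed(7)
  p <- sort(c(0, 10^seq(-2, 4, length.out = 50)))
  for (rep in 1:25) {
    bp <- biomarker_params(
      sample(c("2mc", "3hp", "c3c2"), 1),
      e0 = stats::runif(1, 0, 10), base = stats::runif(1, 0.1, 100),
      ic50 = stats::runif(1, 0.5, 100), imax = stats::runif(1, 0.5, 1),
      gamma = stats::runif(1, 0.3, 4))
    lev <- biomarker_level(p, bp)
    expect_true(all(diff(lev) <= 1e-12))
  }
})

test_that("amenable fraction follows from the baseline split", {
  expect_equal(amenable_fraction(biomarker_params("2mc", 0, 5, 10)), 1)
  expect_equal(amenable_fraction(biomarker_params("2mc", 5, 5, 10)), 0.5)
  expect_equal(amenable_fraction(TRUTH$biomarkers[["2mc"]]), 0.637,
               tolerance = 1e-12)
})

test_that("parameter constructors reject invalid values", {
  expect_error(pk_params(-1, 1, 1, 1, 1, 1, 0.6, 1.1), "tvCL12")
  expect_error(pd_params(0, 1, 1, 1), "ke0")
  expect_error(biomarker_params("2mc", 1, 1, 1, imax = 1.5), "imax")
  expect_error(biomarker_params("xyz", 1, 1, 1), "name")
  expect_error(dose_event(0, -1), "amount")
})
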