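# conditional log-likelihood computed entirely from test-side primitives
# (matrix-exponential reference solution + manual normal densities)
ref_cond_loglik <- function(obs, dose_df, rates, sigma, eta) {
  k32 <- rates$k32 * exp(eta)
  A <- rbind(c(-rates$k12, 0, 0),
             c(rates$k12, -(rates$k23 + rates$k20), k32),
             c(0, rates$k23, -k32))
  st <- expm_reference(A, numeric(3), dose_df, obs$time)
  f <- st[, 3] / rates$V * 1e6
  s <- sqrt((sigma * f)^2 + 1e-10)
  sum(ifelse(obs$blq == 1,
             stats::pnorm(obs$lloq, f, s, log.p = TRUE),
             stats::dnorm(obs$dv, f, s, log = TRUE)))
}

make_pk_subject <- function(seed = 31, n = 1) {
  des <- default_designs(n_mouse_pk = 4)$mouse_pk
  d <- generate_study(des, TRUTH, seed = seed)
  d[d$id %in% unique(d$id)[seq_len(n)], , drop = FALSE]
}

pk_ctx <- function(sigma = 0.375) {
  list(pk = TRUTH$pk, pd = NULL, biomarkers = NULL,
       sigmas = c(mrna = sigma), observed = "a3", conc_scale = 1e6)
}

test_that("marginal likelihood degenerates to the conditional at omega = 0", {
  sub <- make_pk_subject()
  ctx <- pk_ctx()
  got <- subject_marginal_loglik(sub, ctx, omega = 0)
  obs <- sub[sub$evid == 0, ]
  dose_df <- data.frame(time = 0, amount = sub$amt[sub$evid == 1],
                        duration = 0)
  rates <- allometric_scale(TRUTH$pk, obs$wt[1])
  want <- ref_cond_loglik(obs, dose_df, rates, 0.375, 0)
  expect_equal(as.numeric(got), want, tolerance = 1e-8)
})

test_that("adaptive quadrature agrees with brute-force Monte-Carlo integration", {
  sub <- make_pk_subject()
  obs <- sub[sub$evid == 0, ]
  dose_df <- data.frame(time = 0, amount = sub$amt[sub$evid == 1],
                        duration = 0)
  rates <- allometric_scale(TRUTH$pk, obs$wt[1])
  omega <- 0.495
  # dense grid of the conditional likelihood from the independent reference,
  # interpolated for 1e5 Monte-Carlo draws of eta
  grid <- seq(-6 * omega, 6 * omega, length.out = 801)
  cl <- vapply(grid, function(e) ref_cond_loglik(obs, dose_df, rates, 0.375, e),
               numeric(1))
  clf <- stats::splinefun(grid, cl)
  set.seed(99)
  etas <- stats::rnorm(1e5, 0, omega)
  w <- exp(clf(etas) - max(cl))
  mc <- log(mean(w)) + max(cl)
  mc_se <- stats::sd(w) / (sqrt(length(w)) * mean(w))
  got <- subject_marginal_loglik(sub, pk_ctx(), omega = omega,
                                 method = "agq", n_nodes = 21)
  expect_lt(abs(as.numeric(got) - mc), 3 * mc_se)
  # Laplace and AGQ agree closely on this well-behaved subject
  lap <- subject_marginal_loglik(sub, pk_ctx(), omega = omega,
                                 method = "laplace")
  expect_lt(abs(as.numeric(got) - as.numeric(lap)), 0.05)
})

test_that("fully censored records saturate to a vanishing penalty", {
  sub <- make_pk_subject()
  i <- which(sub$evid == 0)
  sub$blq[i] <- 1L
  sub$lloq[i] <- 1e12       # far above any prediction
  sub$dv[i] <- 1e12
  got <- subject_marginal_loglik(sub, pk_ctx(), omega = 0.495)
  expect_gt(as.numeric(got), -1e-4)
  expect_lt(as.numeric(got), 1e-12)
})

test_that("fitting noise-free data started at the truth returns the truth", {
  des <- default_designs(n_mouse_pk = 6)
  d0 <- rbind(generate_study(des$mouse_pk, TRUTH, seed = 41,
                             omega_override = 0, sigma_override = 0),
              generate_study(des$monkey_pk, TRUTH, seed = 42,
                             omega_override = 0, sigma_override = 0))
  class(d0) <- c("pkpd_dataset", "data.frame")
  truth <- c(tvCL12 = 19.7, tvCL23 = 0.215, tvCL32 = 2.96, tvCL20 = 0.136)
  spec <- fit_spec("pk", free = truth,
                   fixed = list(tvV = 2.67, tvV2 = 0.961, wt_ref = 1,
                                v_exponent = 1, cl_alpha = 0.631,
                                cl_beta = 1.10, omega_cl32 = 0,
                                sigma_mrna = 0.05),
                   n_starts = 1)
  f <- fit(d0, spec)
  expect_true(f$convergence)
  expect_equal(unname(f$estimates), unname(truth), tolerance = 5e-3)
  # the truth is not a better optimum than the one found
  expect_gte(evaluate_fit(d0, spec, at = truth)$m2ll, f$m2ll - 1e-6)
})

test_that("the optimum is a local minimum along every free parameter", {
  des <- default_designs(n_mouse_pk = 8)
  d <- generate_study(des$mouse_pk, TRUTH, seed = 43)
  truth <- c(tvCL12 = 19.7, tvCL32 = 2.96, omega_cl32 = 0.495,
             sigma_mrna = 0.375)
  spec <- fit_spec("pk", free = truth,
                   fixed = list(tvV = 2.67, tvV2 = 0.961, wt_ref = 1,
                                v_exponent = 1, tvCL23 = 0.215,
                                tvCL20 = 0.136, cl_alpha = 0.631,
                                cl_beta = 1.10),
                   n_starts = 1)
  f <- fit(d, spec)
  expect_true(f$convergence)
  for (nm in names(f$estimates)) {
    for (fac in c(0.8, 1.2)) {
      at <- f$estimates
      at[nm] <- at[nm] * fac
      expect_gt(evaluate_fit(d, spec, at = at)$m2ll, f$m2ll)
    }
  }
})

test_that("a common unit factor shifts the objective by the analytic constant", {
  d <- make_pk_subject(seed = 44, n = 4)
  truth <- c(tvCL12 = 19.7, tvCL32 = 2.96)
  fixed <- list(tvV = 2.67, tvV2 = 0.961, wt_ref = 1, v_exponent = 1,
                tvCL23 = 0.215, tvCL20 = 0.136, cl_alpha = 0.631,
                cl_beta = 1.10, omega_cl32 = 0.495, sigma_mrna = 0.375)
  spec1 <- fit_spec("pk", free = truth, fixed = fixed, n_starts = 1)
  m1 <- evaluate_fit(d, spec1)$m2ll
  cfac <- 1000
  d2 <- d
  i <- d2$evid == 0
  d2$dv[i] <- d2$dv[i] * cfac
  spec2 <- fit_spec("pk", free = truth, fixed = fixed, n_starts = 1,
                    conc_scale = 1e6 * cfac)
  m2 <- evaluate_fit(d2, spec2)$m2ll
  n <- sum(i)
  expect_equal(m2, m1 + 2 * n * log(cfac), tolerance = 1e-6)
})

test_that("diagnostics vanish on noise-free data at the true parameters", {
  des <- default_designs(n_mouse_pk = 4)
  d0 <- generate_study(des$mouse_pk, TRUTH, seed = 45,
                       omega_override = 0, sigma_override = 0)
  spec <- fit_spec("pk", free = c(tvCL12 = 19.7),
                   fixed = list(tvV = 2.67, tvV2 = 0.961, wt_ref = 1,
                                v_exponent = 1, tvCL23 = 0.215,
                                tvCL32 = 2.96, tvCL20 = 0.136,
                                cl_alpha = 0.631, cl_beta = 1.10,
                                omega_cl32 = 0, sigma_mrna = 0.1))
  f <- evaluate_fit(d0, spec)
  dg <- compute_diagnostics(d0, f)
  expect_equal(dg$pred, dg$ipred, tolerance = 1e-10)  # eta = 0 throughout
  expect_lt(max(abs(dg$cwres)), 1e-4)
  expect_equal(dg$dv, dg$pred, tolerance = 1e-6)
})

test_that("conditional weighted residuals are calibrated on a correct model", {
  des <- default_designs(n_mouse_pk = 40)
  d <- generate_study(des$mouse_pk, TRUTH, seed = 46)
  spec <- fit_spec("pk", free = c(tvCL12 = 19.7),
                   fixed = list(tvV = 2.67, tvV2 = 0.961, wt_ref = 1,
                                v_exponent = 1, tvCL23 = 0.215,
                                tvCL32 = 2.96, tvCL20 = 0.136,
                                cl_alpha = 0.631, cl_beta = 1.10,
                                omega_cl32 = 0.495, sigma_mrna = 0.375))
  f <- evaluate_fit(d, spec)
  dg <- compute_diagnostics(d, f)
  expect_gt(nrow(dg), 300)
  expect_lt(abs(mean(dg$cwres)), 0.1)
  expect_gt(stats::sd(dg$cwres), 0.85)
  expect_lt(stats::sd(dg$cwres), 1.15)
})

test_that("fit refuses a dataset lacking the required observables", {
  d <- make_pk_subject(seed = 47, n = 2)
  spec <- fit_spec("protein",
                   free = c(ke0 = 0.1, ksyn_slope = 0.05, kdeg = 0.03,
                            kq = 0.005, sigma_pcc = 0.2),
                   fixed = list(pk = TRUTH$pk, omega_cl32 = 0.495))
  expect_error(fit(d, spec), "pcc")
})

test_that("standard errors use the delta method so %RSE is scale-free", {
  des <- default_designs(n_mouse_pk = 10)
  d <- generate_study(des$mouse_pk, TRUTH, seed = 48)
  spec <- fit_spec("pk", free = c(tvCL12 = 15, sigma_mrna = 0.3),
                   fixed = list(tvV = 2.67, tvV2 = 0.961, wt_ref = 1,
                                v_exponent = 1, tvCL23 = 0.215,
                                tvCL32 = 2.96, tvCL20 = 0.136,
                                cl_alpha = 0.631, cl_beta = 1.10,
                                omega_cl32 = 0.495),
                   n_starts = 1)
  f <- fit(d, spec)
  expect_true(f$se_available)
  expect_equal(unname(f$rse_pct), unname(100 * f$se / f$estimates),
               tolerance = 1e-10)
  expect_true(all(f$rse_pct > 0))
})
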