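#' Synthetic interspecies PK study and fit
#'
#' Generates the mouse, rat and monkey PK studies from [default_designs()]
#' at the [default_truth()] parameters and fits the interspecies disposition
#' model (four clearances, two allometric exponents, IIV on `CL32`,
#' proportional error) by AGQ marginal maximum likelihood with volumes fixed,
#' starting from generic initial values (round-number clearances and the
#' conventional 0.75 allometric exponent).
#'
#' @param seed integer root seed for study generation.
#' @param n_mouse_pk mouse PK cohort size (default 20; with the rat and
#'   monkey cohorts this gives the 55-subject interspecies study).
#' @param n_starts optimiser multi-starts (default 3).
#' @param method marginalisation method (default `"agq"`).
#' @return List with `dataset`, `fit`, and `truth`.
#' @export
interspecies_pk_fit <- function(seed, n_mouse_pk = 20, n_starts = 3,
                                method = "agq") {
  truth <- default_truth()
  des <- default_designs(n_mouse_pk = n_mouse_pk)
  d <- rbind(generate_study(des$mouse_pk, truth, seed = seed),
             generate_study(des$rat_pk, truth, seed = seed),
             generate_study(des$monkey_pk, truth, seed = seed))
  class(d) <- c("pkpd_dataset", "data.frame")
  spec <- fit_spec(
    "pk",
    free = c(tvCL12 = 10, tvCL23 = 0.1, tvCL32 = 1, tvCL20 = 0.1,
             cl_alpha = 0.75, cl_beta = 0.75, omega_cl32 = 0.3,
             sigma_mrna = 0.3),
    fixed = list(tvV = truth$pk$tvV, tvV2 = truth$pk$tvV2,
                 wt_ref = truth$pk$wt_ref, v_exponent = 1),
    method = method, n_starts = n_starts)
  list(dataset = d, fit = fit(d, spec), truth = truth)
}

#' Synthetic mouse PD study and sequential PD fit
#'
#' Generates the single-dose and three-weekly multiple-dose mouse PD studies
#' at the [default_truth()] parameters and runs the stepwise estimation
#' scheme: with the PK model fixed (typically at the interspecies fit), the
#' protein turnover parameters are estimated from the hepatic protein data;
#' the per-subject model-predicted protein trajectories at the
#' empirical-Bayes random effects then serve as the covariate for the static
#' sigmoidal Imax fits of each biomarker (Imax fixed at 0.999).  The 3-HP
#' model uses the Laplacian method and the M3 censored likelihood for its
#' below-quantification records.
#'
#' Initial values for the biomarker baselines are taken from the pre-dose
#' observations; the IC50 start is the median predicted protein exposure.
#'
#' @param seed integer root seed for study generation.
#' @param pk fixed PK parameters ([pk_params()]), e.g. from the
#'   interspecies fit.
#' @param omega_cl32 fixed IIV standard deviation, from the same fit.
#' @param n_starts optimiser multi-starts (default 3).
#' @return List with `dataset`, `protein_fit`, `pd` (fitted [pd_params()])
#'   and `biomarker_fits` (named list over `2mc`, `3hp`, `c3c2`).
#' @export
mouse_pd_sequential_fit <- function(seed, pk, omega_cl32, n_starts = 3) {
  truth <- default_truth()
  des <- default_designs()
  d <- rbind(generate_study(des$mouse_pd_single, truth, seed = seed),
             generate_study(des$mouse_pd_q3w, truth, seed = seed))
  class(d) <- c("pkpd_dataset", "data.frame")
  spec_p <- fit_spec(
    "protein",
    free = c(ke0 = 0.05, ksyn_slope = 0.02, kdeg = 0.01, kq = 0.01,
             sigma_pcc = 0.3),
    fixed = list(pk = pk, omega_cl32 = omega_cl32),
    n_starts = n_starts)
  fp <- fit(d, spec_p)
  pd_hat <- pd_params(ke0 = fp$estimates[["ke0"]],
                      ksyn_slope = fp$estimates[["ksyn_slope"]],
                      kdeg = fp$estimates[["kdeg"]],
                      kq = fp$estimates[["kq"]])
  d2 <- add_protein_predictions(d, pk, pd_hat, etas = fp$etas)
  bio_fits <- list()
  for (b in c("2mc", "3hp", "c3c2")) {
    obs <- d2[d2$evid == 0 & d2$dvid == b, ]
    predose <- mean(obs$dv[obs$time == 0])
    if (!is.finite(predose) || predose <= 0) predose <- mean(obs$dv)
    ic50_init <- stats::median(obs$p_pred[obs$p_pred > 0])
    spec_b <- fit_spec(
      "biomarker",
      free = c(e0 = 0.2 * predose, base = 0.8 * predose,
               ic50 = ic50_init, sigma_b = 0.2),
      fixed = list(name = b, imax = 0.999, gamma = 1),
      method = if (b == "3hp") "laplace" else "agq",
      n_starts = n_starts)
    bio_fits[[b]] <- fit(d2, spec_b)
  }
  list(dataset = d2, protein_fit = fp, pd = pd_hat, biomarker_fits = bio_fits)
}
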