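#' Individual subject descriptor
#'
#' @param id subject identifier.
#' @param wt body weight, kg (> 0).
#' @param eta_cl32 log-scale random effect on `CL32`.
#' @param species species label.
#' @return An object of class `individual`.
#' @export
individual <- function(id, wt, eta_cl32 = 0, species = "mouse") {
  if (!is.finite(wt) || wt <= 0) {
    stop(sprintf("individual: non-positive weight for subject '%s'", id))
  }
  structure(list(id = id, wt = wt, eta_cl32 = eta_cl32, species = species),
            class = "individual")
}

# Named substreams derived from one root seed, so e.g. adding residual-error
# draws never perturbs the eta draws.  Plain integer arithmetic kept below
# 2^31.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

#' Draw interindividual random effects
#'
#' @param pop a [population_params()] object.
#' @param n number of subjects (>= 1).
#' @param seed integer seed; draws are reproducible given the seed.
#' @return Numeric vector of `n` i.i.d. Normal(0, omega^2) draws.
#' @export
draw_etas <- function(pop, n, seed) {
  stopifnot(inherits(pop, "population_params"), n >= 1)
  if (pop$omega_cl32 == 0) return(numeric(n))
  withr::with_seed(substream_seed(seed, "eta"),
                   stats::rnorm(n, 0, pop$omega_cl32))
}

#' Individual PK parameters: allometry plus the CL32 random effect
#'
#' @param pk a [pk_params()] object.
#' @param ind an [individual()] object.
#' @return Rate list as from [allometric_scale()] with `CL32` (and `k32`)
#'   multiplied by `exp(eta_cl32)`.
#' @export
individual_params <- function(pk, ind) {
  stopifnot(inherits(ind, "individual"))
  r <- allometric_scale(pk, ind$wt, id = ind$id)
  f <- exp(ind$eta_cl32)
  r$CL32 <- r$CL32 * f
  r$k32 <- r$k32 * f
  r
}

#' Apply proportional residual error to noise-free predictions
#'
#' `y = f * (1 + eps)`, `eps ~ Normal(0, sigma^2)`; any negative results are
#' floored at zero and the number of floored values is attached as the
#' `"n_floored"` attribute.
#'
#' @param predictions non-negative noise-free predictions.
#' @param sigma_prop proportional residual SD (fraction).
#' @param seed integer seed.
#' @return Perturbed observations, same length as `predictions`.
#' @export
apply_residual_error <- function(predictions, sigma_prop, seed) {
  stopifnot(all(predictions >= 0), sigma_prop >= 0)
  if (sigma_prop == 0) {
    y <- predictions
    attr(y, "n_floored") <- 0L
    return(y)
  }
  eps <- withr::with_seed(substream_seed(seed, "residual"),
                          stats::rnorm(length(predictions), 0, sigma_prop))
  y <- predictions * (1 + eps)
  nfl <- sum(y < 0)
  y[y < 0] <- 0
  attr(y, "n_floored") <- nfl
  y
}

observable_predict <- function(rates, pd, biomarkers, doses, times, dvids,
                               observed = "a3", conc_scale = 1e6,
                               method = "linear") {
  need_pd <- any(dvids != "mrna")
  if (need_pd) {
    if (is.null(pd)) stop("PD parameters required for non-mRNA observables")
    sim <- simulate_pkpd(rates, pd, wt = NA, doses = doses, times = times,
                         observed = observed, conc_scale = conc_scale,
                         method = method)
  } else {
    sim <- simulate_pk(rates, wt = NA, doses = doses, times = times,
                       observed = observed, conc_scale = conc_scale,
                       method = method)
  }
  vapply(seq_along(times), function(i) {
    dv <- dvids[i]
    if (dv == "mrna") {
      sim$conc[i]
    } else if (dv == "pcc") {
      sim$p_total[i]
    } else {
      bp <- biomarkers[[dv]]
      if (is.null(bp)) stop(sprintf("no biomarker parameters for '%s'", dv))
      biomarker_level(sim$p_total[i], bp)
    }
  }, numeric(1))
}

#' Simulate a study population into a long-format dataset
#'
#' One record per subject, observation time and observable, in NONMEM
#' convention (dose records `evid = 1`, observations `evid = 0`), plus dose
#' records with amounts computed as mg/kg times body weight.  Observables
#' with an LLOQ have below-limit values flagged `blq = 1` with `dv` set to
#' the LLOQ.
#'
#' @param pk a [pk_params()] object.
#' @param pd a [pd_params()] object or `NULL` when only mRNA is observed.
#' @param biomarkers named list of [biomarker_params()] (may be empty).
#' @param pop a [population_params()] object.
#' @param cohort list of [individual()] objects (etas are redrawn from
#'   `pop` unless `use_cohort_etas = TRUE`).
#' @param dose_per_kg per-subject dose level, mg/kg (scalar or one per
#'   subject).
#' @param interval,n_doses,infusion_duration regimen, as [regimen_doses()].
#' @param sampling named list: observable -> observation time grid (h).
#' @param lloq named vector of LLOQs per observable (optional).
#' @param seed integer root seed; eta and residual substreams are derived
#'   from it.
#' @param use_cohort_etas keep the etas already present in `cohort`.
#' @param observed,conc_scale observation mapping, as [simulate_pk()].
#' @return A `data.frame` of class `pkpd_dataset` with columns `id`, `time`,
#'   `evid`, `amt`, `rate`, `dv`, `dvid`, `mdv`, `blq`, `lloq`, `wt`,
#'   `species`.
#' @export
simulate_population <- function(pk, pd, biomarkers, pop, cohort, dose_per_kg,
                                interval = 504, n_doses = 1,
                                infusion_duration = 0, sampling, lloq = NULL,
                                seed = 1, use_cohort_etas = FALSE,
                                observed = "a3", conc_scale = 1e6) {
  stopifnot(length(cohort) >= 1)
  n <- length(cohort)
  dose_per_kg <- rep(dose_per_kg, length.out = n)
  etas <- if (use_cohort_etas) {
    vapply(cohort, `[[`, 0, "eta_cl32")
  } else {
    draw_etas(pop, n, seed)
  }
  dvids_all <- names(sampling)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    ind <- cohort[[i]]
    ind$eta_cl32 <- etas[i]
    rates <- individual_params(pk, ind)
    doses <- if (dose_per_kg[i] > 0) {
      regimen_doses(dose_per_kg[i], ind$wt, interval, n_doses,
                    infusion_duration)
    } else list()
    obs_long <- data.frame(
      time = unlist(lapply(dvids_all, function(d) sampling[[d]])),
      dvid = rep(dvids_all, vapply(sampling, length, 0L))
    )
    obs_long <- obs_long[order(obs_long$time, obs_long$dvid), , drop = FALSE]
    f <- observable_predict(rates, pd, biomarkers, doses, obs_long$time,
                            dvids = obs_long$dvid, observed, conc_scale)
    sig <- vapply(obs_long$dvid, function(d) sigma_for(pop, d), numeric(1))
    eps <- withr::with_seed(
      substream_seed(seed, paste0("residual-", ind$id)),
      stats::rnorm(nrow(obs_long))
    )
    y <- pmax(f * (1 + sig * eps), 0)
    ll <- if (is.null(lloq)) rep(NA_real_, nrow(obs_long)) else {
      unname(lloq[obs_long$dvid])
    }
    is_blq <- !is.na(ll) & y < ll
    dose_df <- doses_frame(doses)
    dose_rec <- if (nrow(dose_df)) {
      data.frame(id = ind$id, time = dose_df$time, evid = 1L,
                 amt = dose_df$amount,
                 rate = ifelse(dose_df$duration > 0,
                               dose_df$amount / dose_df$duration, 0),
                 dv = NA_real_, dvid = "mrna", mdv = 1L, blq = 0L,
                 lloq = NA_real_, wt = ind$wt, species = ind$species)
    } else NULL
    obs_rec <- data.frame(id = ind$id, time = obs_long$time, evid = 0L,
                          amt = NA_real_, rate = NA_real_,
                          dv = ifelse(is_blq, ll, y),
                          dvid = obs_long$dvid, mdv = 0L,
                          blq = as.integer(is_blq), lloq = ll,
                          wt = ind$wt, species = ind$species)
    recs[[i]] <- rbind(dose_rec, obs_rec)
  }
  out <- do.call(rbind, recs)
  out <- out[order(match(out$id, vapply(cohort, `[[`, "", "id")),
                   out$time, -out$evid), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "etas") <- stats::setNames(etas, vapply(cohort, `[[`, "", "id"))
  class(out) <- c("pkpd_dataset", "data.frame")
  out
}

#' Build a cohort of individuals with jittered species weights
#'
#' @param n number of subjects.
#' @param species species label.
#' @param wt_center central body weight, kg; defaults per species (mouse
#'   0.025, rat 0.08, monkey 3, human 70, pediatric 10).
#' @param wt_jitter half-width of the uniform weight jitter as a fraction of
#'   `wt_center` (default 0.10).
#' @param seed integer seed.
#' @param id_prefix prefix for subject identifiers.
#' @return List of [individual()] objects.
#' @export
make_cohort <- function(n, species = "mouse", wt_center = NULL,
                        wt_jitter = 0.10, seed = 1, id_prefix = species) {
  defaults <- c(mouse = 0.025, rat = 0.08, monkey = 3, human = 70,
                pediatric = 10)
  if (is.null(wt_center)) {
    wt_center <- unname(defaults[species])
    if (is.na(wt_center)) stop(sprintf("no default weight for '%s'", species))
  }
  wts <- withr::with_seed(
    substream_seed(seed, paste0("wt-", species)),
    stats::runif(n, wt_center * (1 - wt_jitter), wt_center * (1 + wt_jitter))
  )
  lapply(seq_len(n), function(i) {
    individual(sprintf("%s-%03d", id_prefix, i), wts[i], 0, species)
  })
}
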