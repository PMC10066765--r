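# Marginal likelihood for one subject with a scalar log-normal random effect
# on CL32, marginalised by Laplace approximation or adaptive Gauss-Hermite
# quadrature.  Residual model: proportional error per observable, with the M3
# censored-likelihood contribution Phi((LLOQ - f) / (sigma f)) for records
# flagged below the limit of quantification.
#
# The conditional likelihood is evaluated through the compiled exact
# propagator on pre-extracted per-subject vectors; this is the hot path of
# every fit.

VAR_FLOOR <- 1e-10

gh_cache <- new.env(parent = emptyenv())

gh_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(gh_cache[[key]])) gh_cache[[key]] <- pracma::gaussHermite(n)
  gh_cache[[key]]
}

subject_doses <- function(sub) {
  dose <- sub[sub$evid == 1, , drop = FALSE]
  data.frame(
    time = dose$time,
    amount = dose$amt,
    duration = ifelse(!is.na(dose$rate) & dose$rate > 0,
                      dose$amt / dose$rate, 0)
  )
}

# fixed observable coding shared with the compiled likelihood:
# 0 = mrna, 1 = pcc, 2/3/4 = biomarker rows (2mc, 3hp, c3c2)
BIO_ORDER <- c("2mc", "3hp", "c3c2")

# flatten one subject's records into plain vectors for the fast path
prep_subject <- function(sub) {
  obs <- sub[sub$evid == 0 & sub$mdv == 0, , drop = FALSE]
  doses <- subject_doses(sub)
  blq <- obs$blq == 1
  list(
    id = sub$id[1],
    wt = sub$wt[1],
    dose_time = doses$time,
    dose_amt = doses$amount,
    dose_dur = doses$duration,
    time = obs$time,
    dvid = obs$dvid,
    code = match(obs$dvid, c("mrna", "pcc", BIO_ORDER)) - 1L,
    i_mrna = which(obs$dvid == "mrna"),
    i_pcc = which(obs$dvid == "pcc"),
    i_bio = which(!obs$dvid %in% c("mrna", "pcc")),
    dv = ifelse(is.na(obs$dv), 0, obs$dv),
    blq = blq,
    lloq = ifelse(blq, obs$lloq, 0),
    p_pred = obs$p_pred %||% NULL
  )
}

# assemble the biomarker parameter matrix in the fixed row order
bio_matrix <- function(biomarkers) {
  m <- matrix(0, nrow = length(BIO_ORDER), ncol = 5)
  for (k in seq_along(BIO_ORDER)) {
    bp <- biomarkers[[BIO_ORDER[k]]]
    if (!is.null(bp)) m[k, ] <- c(bp$e0, bp$base, bp$ic50, bp$imax, bp$gamma)
  }
  m
}

# evaluate the structural predictions for all of one subject's records
subject_predict <- function(sd, ctx, eta) {
  if (isTRUE(ctx$static_biomarker)) {
    bp <- ctx$biomarkers[[sd$dvid[1]]]
    return(biomarker_level(sd$p_pred, bp))
  }
  r <- sd$wt / ctx$pk$wt_ref
  ra <- r^ctx$pk$cl_alpha
  rb <- r^ctx$pk$cl_beta
  V <- ctx$pk$tvV * r^ctx$pk$v_exponent
  V2 <- ctx$pk$tvV2 * r^ctx$pk$v_exponent
  k12 <- ctx$pk$tvCL12 * ra / V
  k23 <- ctx$pk$tvCL23 * rb / V2
  k32 <- ctx$pk$tvCL32 * ra * exp(eta) / V
  k20 <- ctx$pk$tvCL20 * rb / V2
  cs <- ctx$conc_scale
  crow <- if (identical(ctx$observed, "a1+a3")) c(cs / V, 0, cs / V)
          else c(0, 0, cs / V)
  need_pd <- length(sd$i_pcc) + length(sd$i_bio) > 0
  if (need_pd) {
    pd <- ctx$pd
    A <- matrix(0, 6, 6)
    A[1, 1] <- -k12
    A[2, 1] <- k12; A[2, 2] <- -(k23 + k20); A[2, 3] <- k32
    A[3, 2] <- k23; A[3, 3] <- -k32
    A[4, 1:3] <- pd$ke0 * crow; A[4, 4] <- -pd$ke0
    A[5, 4] <- pd$ksyn_slope; A[5, 5] <- -(pd$kdeg + pd$kq); A[5, 6] <- pd$kq
    A[6, 5] <- pd$kq; A[6, 6] <- -pd$kq
    init <- c(0, 0, 0, 0, pd$p_baseline / 2, pd$p_baseline / 2)
  } else {
    A <- matrix(c(-k12, k12, 0, 0, -(k23 + k20), k23, 0, k32, -k32), 3, 3)
    init <- numeric(3)
  }
  st <- .linode_solve(A, init, sd$dose_time, sd$dose_amt, sd$dose_dur,
                      rep(1L, length(sd$dose_time)), sd$time)
  f <- numeric(length(sd$time))
  if (length(sd$i_mrna)) {
    f[sd$i_mrna] <- crow[1] * st[1, sd$i_mrna] + crow[3] * st[3, sd$i_mrna]
  }
  if (need_pd) {
    p_tot <- st[5, ] + st[6, ]
    if (length(sd$i_pcc)) f[sd$i_pcc] <- p_tot[sd$i_pcc]
    for (i in sd$i_bio) {
      f[i] <- biomarker_level(p_tot[i], ctx$biomarkers[[sd$dvid[i]]])
    }
  }
  f
}

subject_cond_loglik <- function(sd, ctx, eta) {
  f <- subject_predict(sd, ctx, eta)
  sig <- ctx$sigmas[sd$dvid]
  s <- sqrt((sig * f)^2 + VAR_FLOOR)
  blq <- sd$blq
  ll <- numeric(length(f))
  if (!all(blq)) {
    ll[!blq] <- stats::dnorm(sd$dv[!blq], f[!blq], s[!blq], log = TRUE)
  }
  if (any(blq)) {
    ll[blq] <- stats::pnorm(sd$lloq[blq], f[blq], s[blq], log.p = TRUE)
  }
  tot <- sum(ll)
  if (!is.finite(tot)) tot <- -1e10
  tot
}

# marginal log-likelihood for one prepared subject via the compiled
# propagator + quadrature; eta_start warm-starts the mode search
marginal_loglik_prep <- function(sd, ctx, omega, method = "agq", n_nodes = 9,
                                 eta_start = 0) {
  if (isTRUE(ctx$static_biomarker)) {
    out <- subject_cond_loglik(sd, ctx, 0)
    attr(out, "eta_mode") <- 0
    return(out)
  }
  r <- sd$wt / ctx$pk$wt_ref
  ra <- r^ctx$pk$cl_alpha
  rb <- r^ctx$pk$cl_beta
  V <- ctx$pk$tvV * r^ctx$pk$v_exponent
  V2 <- ctx$pk$tvV2 * r^ctx$pk$v_exponent
  cs <- ctx$conc_scale
  crow <- if (identical(ctx$observed, "a1+a3")) c(cs / V, 0, cs / V)
          else c(0, 0, cs / V)
  need_pd <- length(sd$i_pcc) + length(sd$i_bio) > 0
  pd <- ctx$pd
  gh <- gh_nodes(n_nodes)
  res <- .marginal_loglik_cpp(
    k12 = ctx$pk$tvCL12 * ra / V,
    k23 = ctx$pk$tvCL23 * rb / V2,
    k32_base = ctx$pk$tvCL32 * ra / V,
    k20 = ctx$pk$tvCL20 * rb / V2,
    need_pd = need_pd,
    ke0 = if (need_pd) pd$ke0 else 0,
    ksyn = if (need_pd) pd$ksyn_slope else 0,
    kdeg = if (need_pd) pd$kdeg else 1,
    kq = if (need_pd) pd$kq else 0,
    p_baseline = if (need_pd) pd$p_baseline else 0,
    crow = crow,
    dose_time = sd$dose_time, dose_amt = sd$dose_amt, dose_dur = sd$dose_dur,
    obs_time = sd$time, pred_code = sd$code,
    bio = bio_matrix(ctx$biomarkers),
    dv = sd$dv, lloq = sd$lloq,
    sigma = unname(ctx$sigmas[sd$dvid]),
    blq = as.integer(sd$blq),
    omega = omega,
    method = if (method == "laplace") 0L else 1L,
    gh_x = gh$x, gh_w = gh$w,
    eta_start = eta_start
  )
  out <- res$loglik
  attr(out, "eta_mode") <- res$eta_mode
  out
}

#' Marginal log-likelihood of one subject
#'
#' Evaluates `log integral p(y | eta) phi(eta; 0, omega^2) d eta` for the
#' scalar random effect on `CL32`, by Laplace approximation or adaptive
#' Gauss-Hermite quadrature centred and scaled at the empirical-Bayes mode.
#' With `omega = 0` the marginal degenerates to the `eta = 0` conditional
#' log-likelihood.  Records flagged `blq = 1` contribute the M3 censored
#' term `Phi((LLOQ - f) / sd)`.
#'
#' @param sub records of a single subject (dose and observation rows).
#' @param ctx model context: a list with `pk` ([pk_params()]), optional `pd`
#'   and `biomarkers`, `sigmas` (named proportional error SDs per
#'   observable), `observed`, and `conc_scale`.
#' @param omega SD of the random effect.
#' @param method `"agq"` (default) or `"laplace"`.
#' @param n_nodes quadrature nodes for AGQ (default 9).
#' @return Scalar log-likelihood with attribute `"eta_mode"` (the
#'   empirical-Bayes mode).
#' @export
subject_marginal_loglik <- function(sub, ctx, omega, method = c("agq", "laplace"),
                                    n_nodes = 9) {
  method <- match.arg(method)
  if (!any(sub$evid == 0 & sub$mdv == 0)) stop("subject has no observations")
  sd <- prep_subject(sub)
  marginal_loglik_prep(sd, ctx, omega, method, n_nodes)
}

split_subjects <- function(dataset) {
  split(dataset, factor(dataset$id, levels = unique(dataset$id)))
}
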