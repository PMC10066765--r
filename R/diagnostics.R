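#' Goodness-of-fit quantities per observation record
#'
#' Computes population predictions (`PRED`, at `eta = 0`), individual
#' predictions (`IPRED`, at the empirical-Bayes mode) and conditional
#' weighted residuals (`CWRES`) via first-order conditional linearisation of
#' the subject residual covariance: with `G = df/deta` at the mode,
#' `Cov = G omega^2 G' + diag((sigma f)^2)` and
#' `CWRES = Cov^{-1/2} (y - f(eta_hat) + G eta_hat)`.
#' Records flagged BLQ are excluded (counted in the `"n_blq_excluded"`
#' attribute).
#'
#' @param dataset the dataset the model was fitted to.
#' @param fit a [fit()] result (PK or protein model).
#' @return A data.frame with `id`, `time`, `dvid`, `dv`, `pred`, `ipred`,
#'   `cwres` for non-BLQ observation records.
#' @export
compute_diagnostics <- function(dataset, fit) {
  stopifnot(inherits(fit, "fit_result"))
  ctx <- fit$context
  spec <- fit$spec
  d <- dataset[dataset$evid == 1 |
                 (dataset$evid == 0 & dataset$dvid %in% spec$observables), ,
               drop = FALSE]
  subjects <- split_subjects(d)
  out <- list()
  n_blq <- 0L
  omega <- if (is.null(ctx$omega)) 0 else ctx$omega
  for (sub in subjects) {
    obs <- sub[sub$evid == 0 & sub$mdv == 0, , drop = FALSE]
    if (!nrow(obs)) next
    id <- obs$id[1]
    doses <- subject_doses(sub)
    eta_hat <- if (!is.na(fit$etas[id])) fit$etas[[id]] else 0
    predict_at <- function(eta) {
      if (isTRUE(ctx$static_biomarker)) {
        bp <- ctx$biomarkers[[obs$dvid[1]]]
        biomarker_level(obs$p_pred, bp)
      } else {
        rates <- allometric_scale(ctx$pk, obs$wt[1], id = id)
        g <- exp(eta)
        rates$CL32 <- rates$CL32 * g
        rates$k32 <- rates$k32 * g
        observable_predict(rates, ctx$pd, ctx$biomarkers, doses, obs$time,
                           obs$dvid, ctx$observed, ctx$conc_scale)
      }
    }
    pred <- predict_at(0)
    ipred <- if (eta_hat == 0) pred else predict_at(eta_hat)
    keep <- obs$blq == 0
    n_blq <- n_blq + sum(!keep)
    cwres <- rep(NA_real_, nrow(obs))
    if (any(keep)) {
      if (omega > 0 && !isTRUE(ctx$static_biomarker)) {
        step <- max(1e-4, 0.01 * omega)
        G <- (predict_at(eta_hat + step) - predict_at(eta_hat - step)) /
          (2 * step)
      } else {
        G <- numeric(nrow(obs))
      }
      f <- ipred[keep]
      Gk <- G[keep]
      sig <- ctx$sigmas[obs$dvid[keep]]
      Cov <- outer(Gk, Gk) * omega^2 + diag((sig * f)^2 + VAR_FLOOR,
                                            nrow = length(f))
      ee <- eigen(Cov, symmetric = TRUE)
      Cinv_half <- ee$vectors %*% diag(1 / sqrt(pmax(ee$values, 1e-300)),
                                       nrow = length(f)) %*% t(ee$vectors)
      resid <- obs$dv[keep] - f + Gk * eta_hat
      cwres[keep] <- drop(Cinv_half %*% resid)
    }
    out[[length(out) + 1L]] <- data.frame(
      id = id, time = obs$time, dvid = obs$dvid, dv = obs$dv,
      pred = pred, ipred = ipred, cwres = cwres, blq = obs$blq
    )
  }
  res <- do.call(rbind, out)
  res <- res[res$blq == 0, setdiff(names(res), "blq"), drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_blq_excluded") <- n_blq
  res
}

#' Visual predictive check
#'
#' Re-simulates the dataset's own design `n_sim` times at the supplied
#' parameters (new random effects and residual errors each replicate),
#' censors simulated values at the LLOQ where the original record carries
#' one, and summarises each time/observable bin: observed percentiles and
#' the across-replicate band of each simulated percentile.
#'
#' @param dataset the observed dataset providing the design and observations.
#' @param pk,pd,biomarkers model parameters to simulate from (`pd`,
#'   `biomarkers` optional if only mRNA is observed).
#' @param pop a [population_params()] with the omega and sigmas to simulate.
#' @param n_sim number of replicates (>= 100).
#' @param seed integer seed.
#' @param percentiles percentiles summarised (default 5, 50, 95).
#' @param band_level coverage of the across-replicate band (default 0.90).
#' @param observed,conc_scale observation mapping.
#' @return A data.frame with one row per (dvid, time, percentile):
#'   `observed`, `sim_lo`, `sim_med`, `sim_hi`, `n`, `all_blq`.
#' @export
vpc <- function(dataset, pk, pd = NULL, biomarkers = NULL, pop,
                n_sim = 200, seed = 1, percentiles = c(5, 50, 95),
                band_level = 0.90, observed = "a3", conc_scale = 1e6) {
  if (n_sim < 100) stop("vpc: 'n_sim' must be >= 100")
  dataset <- validate_dataset(dataset)
  subjects <- split_subjects(dataset)
  obs_tab <- dataset[dataset$evid == 0 & dataset$mdv == 0, , drop = FALSE]
  bins <- unique(obs_tab[, c("dvid", "time")])
  bins <- bins[order(bins$dvid, bins$time), , drop = FALSE]
  bin_key <- paste(obs_tab$dvid, obs_tab$time)
  keys <- paste(bins$dvid, bins$time)
  # structural predictions are recomputed per replicate eta draw; residual
  # noise rides on top
  sim_mat <- matrix(NA_real_, nrow = nrow(obs_tab), ncol = n_sim)
  row_of <- split(seq_len(nrow(obs_tab)), obs_tab$id)
  set.seed(substream_seed(seed, "vpc"))
  for (r in seq_len(n_sim)) {
    for (sub in subjects) {
      obs <- sub[sub$evid == 0 & sub$mdv == 0, , drop = FALSE]
      if (!nrow(obs)) next
      id <- obs$id[1]
      eta <- stats::rnorm(1, 0, pop$omega_cl32)
      rates <- allometric_scale(pk, obs$wt[1], id = id)
      g <- exp(eta)
      rates$CL32 <- rates$CL32 * g
      rates$k32 <- rates$k32 * g
      f <- observable_predict(rates, pd, biomarkers,
                              df_to_doses(subject_doses(sub)), obs$time,
                              obs$dvid, observed, conc_scale)
      sig <- vapply(obs$dvid, function(dv) sigma_for(pop, dv), numeric(1))
      y <- pmax(f * (1 + stats::rnorm(length(f), 0, sig)), 0)
      cens <- !is.na(obs$lloq) & y < obs$lloq
      y[cens] <- obs$lloq[cens]
      sim_mat[row_of[[id]], r] <- y
    }
  }
  alpha <- (1 - band_level) / 2
  out <- list()
  for (k in seq_along(keys)) {
    rows <- which(bin_key == keys[k])
    yobs <- obs_tab$dv[rows]
    all_blq <- all(obs_tab$blq[rows] == 1)
    for (p in percentiles) {
      obs_q <- stats::quantile(yobs, p / 100, names = FALSE, type = 7)
      sim_q <- apply(sim_mat[rows, , drop = FALSE], 2, stats::quantile,
                     probs = p / 100, names = FALSE, type = 7)
      out[[length(out) + 1L]] <- data.frame(
        dvid = bins$dvid[k], time = bins$time[k], percentile = p,
        observed = obs_q,
        sim_lo = stats::quantile(sim_q, alpha, names = FALSE),
        sim_med = stats::median(sim_q),
        sim_hi = stats::quantile(sim_q, 1 - alpha, names = FALSE),
        n = length(rows), all_blq = all_blq
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
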