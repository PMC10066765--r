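# Maximum-likelihood estimation on log-transformed parameters, minimising
# -2 * sum of subject marginal log-likelihoods with deterministic multi-start
# and inverse-Hessian standard errors.

PK_FREE <- c("tvCL12", "tvCL23", "tvCL32", "tvCL20", "cl_alpha", "cl_beta",
             "omega_cl32", "sigma_mrna")
PROTEIN_FREE <- c("ke0", "ksyn_slope", "kdeg", "kq", "sigma_pcc")
BIOMARKER_FREE <- c("e0", "base", "ic50", "gamma", "sigma_b")

#' Specify an estimation run
#'
#' @param model one of `"pk"` (interspecies mRNA disposition with allometric
#'   exponents, IIV on `CL32` and proportional error), `"protein"`
#'   (effect-compartment / protein-turnover parameters with the PK model
#'   fixed) or `"biomarker"` (static Imax model on a precomputed protein
#'   covariate).
#' @param free named numeric vector of initial values for the parameters to
#'   estimate.  Allowed names per model: PK `tvCL12, tvCL23, tvCL32, tvCL20,
#'   cl_alpha, cl_beta, omega_cl32, sigma_mrna`; protein `ke0, ksyn_slope,
#'   kdeg, kq, sigma_pcc`; biomarker `e0, base, ic50, gamma, sigma_b`.
#' @param fixed named list of fixed quantities.  PK model: `tvV`, `tvV2`,
#'   `wt_ref`, `v_exponent` (volumes are fixed in the second estimation step,
#'   following the two-step convention that permits \%RSE computation).
#'   Protein model: `pk` ([pk_params()]), `omega_cl32`, plus any free
#'   parameter held fixed.  Biomarker model: `name`, `imax`, `gamma`.
#' @param method marginalisation method, `"agq"` or `"laplace"`.
#' @param n_nodes AGQ nodes (default 9).
#' @param observables observation types entering the likelihood.
#' @param n_starts deterministic multi-start count (default 3).
#' @param observed,conc_scale observation mapping, as [simulate_pk()].
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(model = c("pk", "protein", "biomarker"), free, fixed = list(),
                     method = c("agq", "laplace"), n_nodes = 9,
                     observables = NULL, n_starts = 3,
                     observed = "a3", conc_scale = 1e6) {
  model <- match.arg(model)
  method <- match.arg(method)
  allowed <- switch(model, pk = PK_FREE, protein = PROTEIN_FREE,
                    biomarker = BIOMARKER_FREE)
  if (!length(free)) stop("fit_spec: at least one free parameter required")
  bad <- setdiff(names(free), allowed)
  if (length(bad)) {
    stop("fit_spec: unknown free parameters for model '", model, "': ",
         paste(bad, collapse = ", "))
  }
  if (any(free <= 0)) stop("fit_spec: initial values must be positive")
  if (is.null(observables)) {
    observables <- switch(model, pk = "mrna", protein = "pcc",
                          biomarker = fixed$name)
  }
  structure(list(model = model, free = free, fixed = fixed, method = method,
                 n_nodes = n_nodes, observables = observables,
                 n_starts = n_starts, observed = observed,
                 conc_scale = conc_scale),
            class = "fit_spec")
}

# natural parameters -> model context used by the likelihood
build_context <- function(spec, nat) {
  fx <- spec$fixed
  val <- function(nm, default = NULL) {
    if (!is.null(nat[[nm]])) nat[[nm]]
    else if (!is.null(fx[[nm]])) fx[[nm]]
    else default
  }
  if (spec$model == "pk") {
    pk <- pk_params(
      tvCL12 = val("tvCL12"), tvCL23 = val("tvCL23"),
      tvCL32 = val("tvCL32"), tvCL20 = val("tvCL20"),
      tvV = val("tvV"), tvV2 = val("tvV2"),
      cl_alpha = val("cl_alpha"), cl_beta = val("cl_beta"),
      v_exponent = val("v_exponent", 1), wt_ref = val("wt_ref", 1)
    )
    list(pk = pk, pd = NULL, biomarkers = NULL,
         sigmas = c(mrna = val("sigma_mrna")),
         omega = val("omega_cl32"),
         observed = spec$observed, conc_scale = spec$conc_scale)
  } else if (spec$model == "protein") {
    pd <- pd_params(ke0 = val("ke0"), ksyn_slope = val("ksyn_slope"),
                    kdeg = val("kdeg"), kq = val("kq"),
                    p_baseline = val("p_baseline", 0))
    list(pk = fx$pk, pd = pd, biomarkers = NULL,
         sigmas = c(pcc = val("sigma_pcc"), mrna = val("sigma_mrna", 1)),
         omega = val("omega_cl32"),
         observed = spec$observed, conc_scale = spec$conc_scale)
  } else {
    bp <- biomarker_params(name = fx$name, e0 = val("e0"), base = val("base"),
                           ic50 = val("ic50"), imax = val("imax", 0.999),
                           gamma = val("gamma", 1))
    bl <- list(bp)
    names(bl) <- fx$name
    sig <- c(val("sigma_b"))
    names(sig) <- fx$name
    list(pk = NULL, pd = NULL, biomarkers = bl, sigmas = sig, omega = 0,
         static_biomarker = TRUE,
         observed = spec$observed, conc_scale = spec$conc_scale)
  }
}

# e0 in the biomarker model may legitimately be tiny; everything estimated
# here is strictly positive, so all free parameters live on the log scale
theta_to_nat <- function(theta, spec) as.list(exp(theta))

nat_to_theta <- function(free) log(free)

fit_objective <- function(spec, preps) {
  mode_cache <- rep(0, length(preps))
  function(theta) {
    nat <- theta_to_nat(theta, spec)
    names(nat) <- names(spec$free)
    ctx <- tryCatch(build_context(spec, nat), error = function(e) NULL)
    if (is.null(ctx)) return(1e10)
    ll <- 0
    for (i in seq_along(preps)) {
      l <- tryCatch(
        marginal_loglik_prep(preps[[i]], ctx, ctx$omega, spec$method,
                             spec$n_nodes, eta_start = mode_cache[i]),
        error = function(e) NA_real_)
      if (!is.finite(l)) return(1e10)
      mode_cache[i] <<- attr(l, "eta_mode")
      ll <- ll + as.numeric(l)
    }
    -2 * ll
  }
}

#' Fit a model to a dataset by marginal maximum likelihood
#'
#' Minimises `-2 *` the sum of [subject_marginal_loglik()] over the free
#' parameters on the log scale, with a deterministic set of jittered starting
#' points, and reports standard errors from the inverse of the numerically
#' differentiated Hessian at the optimum.
#'
#' @param dataset a validated `pkpd_dataset`.
#' @param spec a [fit_spec()].
#' @return An object of class `fit_result` with elements `estimates`
#'   (natural scale), `se`, `rse_pct`, `m2ll`, `convergence`, `message`,
#'   `etas` (empirical-Bayes modes per subject), `spec`, and `fixed`.
#' @export
fit <- function(dataset, spec) {
  stopifnot(inherits(spec, "fit_spec"))
  dataset <- validate_dataset(dataset)
  have <- unique(dataset$dvid[dataset$evid == 0])
  missing_obs <- setdiff(spec$observables, have)
  if (length(missing_obs)) {
    stop("dataset lacks required observables: ",
         paste(missing_obs, collapse = ", "))
  }
  keep <- dataset$evid == 1 |
    (dataset$evid == 0 & dataset$dvid %in% spec$observables)
  d <- dataset[keep, , drop = FALSE]
  subjects <- split_subjects(d)
  subjects <- Filter(function(s) any(s$evid == 0 & s$mdv == 0), subjects)
  preps <- lapply(subjects, prep_subject)
  obj <- fit_objective(spec, preps)
  theta0 <- nat_to_theta(spec$free)
  p <- length(theta0)
  # deterministic multi-start: alternating +/- 0.35 log-unit perturbations
  starts <- list(theta0)
  if (spec$n_starts > 1) {
    for (k in seq_len(spec$n_starts - 1)) {
      starts[[k + 1]] <- theta0 + 0.35 * (-1)^(k + seq_len(p))
    }
  }
  best <- NULL
  for (st in starts) {
    o <- tryCatch(
      stats::nlminb(st, obj, control = list(iter.max = 500, eval.max = 1200,
                                            rel.tol = 1e-9)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  if (is.null(best)) stop("fit: optimisation failed from every start")
  theta_hat <- best$par
  nat_hat <- exp(theta_hat)
  names(nat_hat) <- names(spec$free)
  converged <- best$convergence == 0
  # standard errors: delta method on the log scale gives %RSE = 100 * SE_log
  se <- rep(NA_real_, p)
  H <- tryCatch(stats::optimHess(theta_hat, obj), error = function(e) NULL)
  se_ok <- FALSE
  if (!is.null(H)) {
    ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) NA)
    if (all(is.finite(ev)) && all(ev > 0)) {
      se_log <- sqrt(diag(2 * solve(H)))
      se <- se_log * nat_hat
      se_ok <- TRUE
    }
  }
  names(se) <- names(spec$free)
  # empirical-Bayes modes at the optimum
  nat_list <- as.list(nat_hat)
  ctx <- build_context(spec, nat_list)
  etas <- vapply(preps, function(sd) {
    attr(marginal_loglik_prep(sd, ctx, ctx$omega, spec$method, spec$n_nodes),
         "eta_mode")
  }, numeric(1))
  names(etas) <- vapply(preps, `[[`, "", "id")
  structure(list(
    estimates = nat_hat,
    se = se,
    rse_pct = 100 * se / nat_hat,
    m2ll = best$objective,
    convergence = converged,
    message = if (se_ok) best$message
              else paste(best$message, "| Hessian not positive definite;",
                         "standard errors unavailable"),
    se_available = se_ok,
    etas = etas,
    n_subjects = length(subjects),
    n_obs = sum(d$evid == 0 & d$mdv == 0),
    n_blq = sum(d$evid == 0 & d$blq == 1),
    spec = spec,
    context = ctx
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Model fit (%s, %s): -2LL = %.3f, %s\n", x$spec$model,
              x$spec$method, x$m2ll,
              if (x$convergence) "converged" else "NOT converged"))
  cat(sprintf("  %d subjects, %d observations (%d BLQ)\n",
              x$n_subjects, x$n_obs, x$n_blq))
  tab <- data.frame(estimate = signif(x$estimates, 4),
                    rse_pct = signif(x$rse_pct, 3))
  print(tab)
  invisible(x)
}

#' Evaluate a model at fixed parameter values without optimisation
#'
#' Computes the objective (-2 log-likelihood) and the empirical-Bayes modes
#' at the supplied parameter values, returning a `fit_result` whose
#' estimates are the supplied values.  Useful for diagnostics at known
#' (e.g. simulation-truth) parameters and for likelihood profiling.
#'
#' @param dataset a `pkpd_dataset`.
#' @param spec a [fit_spec()]; `spec$free` names the parameters supplied.
#' @param at named numeric vector of parameter values (defaults to
#'   `spec$free`).
#' @return A `fit_result` (no standard errors).
#' @export
evaluate_fit <- function(dataset, spec, at = NULL) {
  stopifnot(inherits(spec, "fit_spec"))
  if (is.null(at)) at <- spec$free
  stopifnot(setequal(names(at), names(spec$free)))
  at <- at[names(spec$free)]
  dataset <- validate_dataset(dataset)
  keep <- dataset$evid == 1 |
    (dataset$evid == 0 & dataset$dvid %in% spec$observables)
  d <- dataset[keep, , drop = FALSE]
  subjects <- split_subjects(d)
  subjects <- Filter(function(s) any(s$evid == 0 & s$mdv == 0), subjects)
  preps <- lapply(subjects, prep_subject)
  obj <- fit_objective(spec, preps)
  m2ll <- obj(log(at))
  ctx <- build_context(spec, as.list(at))
  etas <- vapply(preps, function(sd) {
    attr(marginal_loglik_prep(sd, ctx, ctx$omega, spec$method, spec$n_nodes),
         "eta_mode")
  }, numeric(1))
  names(etas) <- vapply(preps, `[[`, "", "id")
  structure(list(
    estimates = at, se = rep(NA_real_, length(at)),
    rse_pct = rep(NA_real_, length(at)), m2ll = m2ll, convergence = TRUE,
    message = "evaluation only", se_available = FALSE, etas = etas,
    n_subjects = length(subjects), n_obs = sum(d$evid == 0 & d$mdv == 0),
    n_blq = sum(d$evid == 0 & d$blq == 1), spec = spec, context = ctx
  ), class = "fit_result")
}

#' Attach model-predicted protein concentrations to a dataset
#'
#' Computes the total hepatic protein prediction at each observation record's
#' time, using fixed PK/PD parameters and per-subject random-effect values
#' (typically the empirical-Bayes modes from the protein-model fit), and
#' stores it in a `p_pred` column.  This is the covariate the static
#' biomarker Imax models are fitted against in the sequential scheme.
#'
#' @param dataset a `pkpd_dataset`.
#' @param pk,pd fitted parameter objects.
#' @param etas named vector of per-subject random effects (default all 0).
#' @param observed,conc_scale observation mapping.
#' @return The dataset with a `p_pred` column on observation rows.
#' @export
add_protein_predictions <- function(dataset, pk, pd, etas = NULL,
                                    observed = "a3", conc_scale = 1e6) {
  dataset <- validate_dataset(dataset)
  dataset$p_pred <- NA_real_
  for (sub in split(seq_len(nrow(dataset)), dataset$id)) {
    s <- dataset[sub, , drop = FALSE]
    id <- s$id[1]
    eta <- if (!is.null(etas) && !is.na(etas[id])) etas[[id]] else 0
    rates <- allometric_scale(pk, s$wt[1], id = id)
    g <- exp(eta)
    rates$CL32 <- rates$CL32 * g
    rates$k32 <- rates$k32 * g
    obs <- s$evid == 0
    if (!any(obs)) next
    sim <- simulate_pkpd(rates, pd, wt = NA, doses = df_to_doses(subject_doses(s)),
                         times = s$time[obs], observed = observed,
                         conc_scale = conc_scale, method = "linear")
    dataset$p_pred[sub[obs]] <- sim$p_total
  }
  dataset
}

df_to_doses <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    dose_event(df$time[i], df$amount[i], df$duration[i])
  })
}
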