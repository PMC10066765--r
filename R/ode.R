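#' IV dose event
#'
#' @param time dose start time, h (>= 0).
#' @param amount absolute dose, mg (mg/kg doses are converted upstream by
#'   multiplying with body weight).
#' @param duration infusion duration, h; 0 means bolus.
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(time, amount, duration = 0) {
  if (time < 0) stop("dose_event: 'time' must be >= 0")
  if (amount <= 0) stop("dose_event: 'amount' must be > 0")
  if (duration < 0) stop("dose_event: 'duration' must be >= 0")
  structure(list(time = time, amount = amount, duration = duration),
            class = "dose_event")
}

doses_frame <- function(doses) {
  if (is.data.frame(doses)) {
    stopifnot(all(c("time", "amount", "duration") %in% names(doses)))
    return(doses[, c("time", "amount", "duration"), drop = FALSE])
  }
  if (inherits(doses, "dose_event")) doses <- list(doses)
  stopifnot(length(doses) >= 0, all(vapply(doses, inherits, TRUE, "dose_event")))
  data.frame(
    time = vapply(doses, `[[`, 0, "time"),
    amount = vapply(doses, `[[`, 0, "amount"),
    duration = vapply(doses, `[[`, 0, "duration")
  )
}

#' Time derivatives of the mRNA disposition system
#'
#' The dose compartment (1) drains into tissue (2), which exchanges with the
#' observation compartment (3) and carries the only elimination pathway
#' (`k20`), so total mass is conserved when `k20 = 0`.
#'
#' @param state numeric vector `c(a1, a2, a3)`, amounts in mg.
#' @param t time, h (unused; the system is autonomous).
#' @param rates rate list as returned by [allometric_scale()] (uses `k12`,
#'   `k23`, `k32`, `k20`).
#' @param infusion_rate zero-order input into compartment 1, mg/h.
#' @return Vector of derivatives `c(da1, da2, da3)`.
#' @export
pk_derivatives <- function(state, t, rates, infusion_rate = 0) {
  a1 <- state[[1]]; a2 <- state[[2]]; a3 <- state[[3]]
  c(-rates$k12 * a1 + infusion_rate,
    rates$k12 * a1 + rates$k32 * a3 - (rates$k23 + rates$k20) * a2,
    rates$k23 * a2 - rates$k32 * a3)
}

# system matrix of the 3-state mRNA model
pk_matrix <- function(rates) {
  matrix(c(-rates$k12, 0, 0,
           rates$k12, -(rates$k23 + rates$k20), rates$k32,
           0, rates$k23, -rates$k32),
         nrow = 3, byrow = TRUE)
}

# 6-state matrix: mRNA (a1, a2, a3), effect compartment ce (in observed
# concentration units) and protein pools p1, p2.  conc_row gives the linear
# map from amounts to the observed concentration driving ce.
pkpd_matrix <- function(rates, pd, conc_scale, observed = "a3") {
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- pk_matrix(rates)
  cr <- conc_row(rates, conc_scale, observed)
  A[4, 1:3] <- pd$ke0 * cr
  A[4, 4] <- -pd$ke0
  A[5, 4] <- pd$ksyn_slope
  A[5, 5] <- -(pd$kdeg + pd$kq)
  A[5, 6] <- pd$kq
  A[6, 5] <- pd$kq
  A[6, 6] <- -pd$kq
  A
}

conc_row <- function(rates, conc_scale, observed = c("a3", "a1+a3")) {
  observed <- match.arg(observed)
  if (observed == "a3") c(0, 0, conc_scale / rates$V)
  else c(conc_scale / rates$V, 0, conc_scale / rates$V)
}

# piecewise lsoda integration with dose times, infusion ends and observation
# times as hard breakpoints; bolus = jump in the state between segments
integrate_piecewise <- function(A, init, doses, times,
                                rtol = 1e-10, atol = 1e-12) {
  n <- length(init)
  brk <- sort(unique(c(0, doses$time, doses$time + doses$duration, times)))
  brk <- brk[brk >= 0]
  deriv <- function(t, y, parms) list(parms$A %*% y + parms$u)
  x <- init
  bolus0 <- doses$duration == 0 & doses$time < 1e-12
  if (any(bolus0)) x[1] <- x[1] + sum(doses$amount[bolus0])
  out <- matrix(NA_real_, nrow = length(times), ncol = n)
  record <- function(t, x) {
    hit <- which(abs(times - t) < 1e-12)
    if (length(hit)) out[hit, ] <<- rep(x, each = length(hit))
  }
  record(brk[1], x)
  for (i in seq_len(length(brk) - 1)) {
    t0 <- brk[i]; t1 <- brk[i + 1]
    u <- numeric(n)
    act <- doses$duration > 0 & doses$time <= t0 + 1e-12 &
      (doses$time + doses$duration) >= t1 - 1e-12
    if (any(act)) u[1] <- sum(doses$amount[act] / doses$duration[act])
    sol <- deSolve::lsoda(y = x, times = c(t0, t1), func = deriv,
                          parms = list(A = A, u = u),
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop(sprintf("ODE solver failed on [%g, %g] h (istate %d)",
                   t0, t1, attr(sol, "istate")[1]))
    }
    x <- sol[nrow(sol), -1]
    bol <- doses$duration == 0 & abs(doses$time - t1) < 1e-12
    if (any(bol)) x[1] <- x[1] + sum(doses$amount[bol])
    record(t1, x)
  }
  neg <- out < 0
  if (any(neg)) {
    worst <- min(out[neg])
    if (worst < -1e-6 * max(abs(out), 1e-12)) {
      stop(sprintf("negative state beyond solver tolerance (min %g)", worst))
    }
    out[neg] <- 0
  }
  out
}

# exact linear propagation via the compiled eigendecomposition path;
# same contract as integrate_piecewise (rows = times)
propagate_linear <- function(A, init, doses, times) {
  t(.linode_solve(A, init, doses$time, doses$amount, doses$duration,
                  rep(1L, nrow(doses)), times))
}

check_times <- function(times) {
  if (is.unsorted(times)) stop("observation times must be sorted")
  if (any(times < 0)) stop("observation times must be non-negative")
}

#' Simulate plasma mRNA concentrations for one subject
#'
#' Integrates the disposition system for a dosing schedule and returns the
#' observed plasma concentration, by default `a3 / V` scaled by `conc_scale`
#' (mg/mL to ng/mL with the default `1e6`).  The default `"ode"` method uses
#' a stiff-capable integrator with dose and observation times as hard
#' breakpoints; `"linear"` uses the exact matrix-exponential propagator that
#' also backs the estimation routines.
#'
#' @param params a [pk_params()] object (or a pre-scaled rate list from
#'   [allometric_scale()]).
#' @param wt body weight, kg.
#' @param doses a `dose_event` or list of them.
#' @param times sorted, non-negative observation grid, h.
#' @param observed which amounts constitute the observed concentration.
#' @param conc_scale unit factor applied to amount/volume (default mg/mL ->
#'   ng/mL).
#' @param method `"ode"` (numerical integration) or `"linear"` (exact).
#' @param rtol,atol solver tolerances for the `"ode"` method.
#' @return A data.frame with columns `time` and `conc`.
#' @export
simulate_pk <- function(params, wt, doses, times,
                        observed = c("a3", "a1+a3"), conc_scale = 1e6,
                        method = c("ode", "linear"),
                        rtol = 1e-10, atol = 1e-12) {
  observed <- match.arg(observed)
  method <- match.arg(method)
  check_times(times)
  rates <- if (inherits(params, "pk_params")) allometric_scale(params, wt) else params
  A <- pk_matrix(rates)
  df <- doses_frame(doses)
  states <- if (method == "ode") {
    integrate_piecewise(A, numeric(3), df, times, rtol, atol)
  } else {
    propagate_linear(A, numeric(3), df, times)
  }
  conc <- drop(states %*% conc_row(rates, conc_scale, observed))
  data.frame(time = times, conc = conc)
}

#' Simulate the coupled mRNA/protein system for one subject
#'
#' Augments the disposition model with the effect compartment and the
#' two-pool protein subsystem.  The endogenous protein baseline starts
#' equally partitioned between the two pools (their exchange equilibrium).
#'
#' @inheritParams simulate_pk
#' @param pd a [pd_params()] object.
#' @return A data.frame with columns `time`, `conc` (observed plasma mRNA),
#'   `ce` (effect compartment) and `p_total` (`p1 + p2`, ug/g).
#' @export
simulate_pkpd <- function(params, pd, wt, doses, times,
                          observed = c("a3", "a1+a3"), conc_scale = 1e6,
                          method = c("ode", "linear"),
                          rtol = 1e-10, atol = 1e-12) {
  observed <- match.arg(observed)
  method <- match.arg(method)
  stopifnot(inherits(pd, "pd_params"))
  check_times(times)
  rates <- if (inherits(params, "pk_params")) allometric_scale(params, wt) else params
  A <- pkpd_matrix(rates, pd, conc_scale, observed)
  init <- c(0, 0, 0, 0, pd$p_baseline / 2, pd$p_baseline / 2)
  df <- doses_frame(doses)
  states <- if (method == "ode") {
    integrate_piecewise(A, init, df, times, rtol, atol)
  } else {
    propagate_linear(A, init, df, times)
  }
  conc <- drop(states[, 1:3, drop = FALSE] %*%
                 conc_row(rates, conc_scale, observed))
  data.frame(time = times, conc = conc, ce = states[, 4],
             p_total = states[, 5] + states[, 6])
}

#' Build the dose schedule of a repeated regimen
#'
#' @param dose_per_kg dose level, mg/kg.
#' @param wt body weight, kg.
#' @param interval dosing interval, h (`q2W` = 336, `q3W` = 504).
#' @param n_doses number of doses (>= 1).
#' @param infusion_duration infusion duration, h (0 = bolus).
#' @return List of [dose_event()] objects.
#' @export
regimen_doses <- function(dose_per_kg, wt, interval = 504, n_doses = 1,
                          infusion_duration = 0) {
  if (n_doses < 1) stop("regimen_doses: 'n_doses' must be >= 1")
  if (interval <= 0) stop("regimen_doses: 'interval' must be > 0")
  lapply(seq_len(n_doses) - 1L, function(k) {
    dose_event(k * interval, dose_per_kg * wt, infusion_duration)
  })
}
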