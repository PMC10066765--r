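#' Typical-value PK parameters for the mRNA disposition model
#'
#' Container for the typical (population) parameters of the linear
#' three-compartment mRNA disposition model: an IV dose compartment (1) and an
#' observation compartment (3), both plasma and sharing the distribution
#' volume `tvV`, exchanging with a tissue compartment (2, volume `tvV2`) from
#' which elimination occurs.  Clearances scale allometrically with body
#' weight: the plasma-to-tissue clearances `CL12` and `CL32` share the
#' exponent `cl_alpha`, the tissue-side clearances `CL23` and `CL20` share
#' `cl_beta`, and volumes scale with `v_exponent` (conventionally 1).
#'
#' @param tvCL12 typical clearance compartment 1 -> 2, mL/h at `wt_ref`.
#' @param tvCL23 typical clearance compartment 2 -> 3, mL/h.
#' @param tvCL32 typical clearance compartment 3 -> 2, mL/h.
#' @param tvCL20 typical tissue elimination clearance, mL/h.
#' @param tvV typical distribution volume of plasma compartments 1 and 3, mL.
#' @param tvV2 typical distribution volume of the tissue compartment, mL.
#' @param cl_alpha allometric exponent for `CL12` and `CL32` (dimensionless).
#' @param cl_beta allometric exponent for `CL23` and `CL20` (dimensionless).
#' @param v_exponent allometric exponent for volumes; default 1.
#' @param wt_ref reference body weight, kg, at which the typical values apply.
#' @return An object of class `pk_params`.
#' @export
pk_params <- function(tvCL12, tvCL23, tvCL32, tvCL20, tvV, tvV2,
                      cl_alpha, cl_beta, v_exponent = 1, wt_ref = 1) {
  p <- list(tvCL12 = tvCL12, tvCL23 = tvCL23, tvCL32 = tvCL32,
            tvCL20 = tvCL20, tvV = tvV, tvV2 = tvV2,
            cl_alpha = cl_alpha, cl_beta = cl_beta,
            v_exponent = v_exponent, wt_ref = wt_ref)
  for (nm in c("tvCL12", "tvCL23", "tvCL32", "tvCL20", "tvV", "tvV2")) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stop(sprintf("pk_params: '%s' must be strictly positive", nm))
    }
  }
  if (!all(is.finite(c(cl_alpha, cl_beta, v_exponent)))) {
    stop("pk_params: allometric exponents must be finite")
  }
  if (!is.finite(wt_ref) || wt_ref <= 0) stop("pk_params: 'wt_ref' must be > 0")
  structure(p, class = "pk_params")
}

#' Effect-compartment and protein-turnover PD parameters
#'
#' Parameters of the hepatic protein subsystem: an empirical effect
#' compartment equilibrating with the observed plasma mRNA concentration at
#' rate `ke0` drives protein synthesis linearly (gain `ksyn_slope`), and the
#' expressed protein distributes between a central and a peripheral pool
#' (rate `kq`) with first-order degradation `kdeg` acting on the central
#' pool.  The two-pool structure produces the biexponential terminal decline
#' seen for long-lived enzymes.
#'
#' @param ke0 effect-compartment equilibration rate, 1/h.
#' @param ksyn_slope synthesis gain, (ug/g liver)/h per unit plasma mRNA
#'   concentration.
#' @param kdeg protein degradation rate, 1/h.
#' @param kq protein intercompartmental rate, 1/h.
#' @param p_baseline endogenous protein baseline, ug/g; 0 for knockout
#'   animals with no functional endogenous enzyme.
#' @return An object of class `pd_params`.
#' @export
pd_params <- function(ke0, ksyn_slope, kdeg, kq, p_baseline = 0) {
  if (!is.finite(ke0) || ke0 <= 0) stop("pd_params: 'ke0' must be > 0")
  if (!is.finite(kdeg) || kdeg <= 0) stop("pd_params: 'kdeg' must be > 0")
  if (ksyn_slope < 0 || kq < 0 || p_baseline < 0) {
    stop("pd_params: rates and baseline must be non-negative")
  }
  structure(list(ke0 = ke0, ksyn_slope = ksyn_slope, kdeg = kdeg, kq = kq,
                 p_baseline = p_baseline), class = "pd_params")
}

#' Sigmoidal Imax biomarker parameters
#'
#' Direct inhibitory relation between total hepatic protein `p` and a plasma
#' biomarker: `level = e0 + base * (1 - imax * p^gamma / (ic50^gamma +
#' p^gamma))`.  `e0` is the biomarker pool not suppressible by treatment,
#' `base` the suppressible baseline, and `base / (e0 + base)` the amenable
#' fraction.
#'
#' @param name biomarker label, one of `"2mc"`, `"3hp"`, `"c3c2"`.
#' @param e0 non-suppressible level, biomarker units.
#' @param base suppressible baseline, biomarker units.
#' @param ic50 total hepatic protein at half-maximal inhibition, ug/g.
#' @param imax maximum inhibition fraction; conventionally fixed at 0.999.
#' @param gamma Hill exponent; default 1.
#' @return An object of class `biomarker_params`.
#' @export
biomarker_params <- function(name, e0, base, ic50, imax = 0.999, gamma = 1) {
  if (!name %in% c("2mc", "3hp", "c3c2")) {
    stop("biomarker_params: 'name' must be one of '2mc', '3hp', 'c3c2'")
  }
  if (e0 < 0) stop("biomarker_params: 'e0' must be >= 0")
  if (base <= 0) stop("biomarker_params: 'base' must be > 0")
  if (ic50 <= 0) stop("biomarker_params: 'ic50' must be > 0")
  if (imax <= 0 || imax > 1) stop("biomarker_params: 'imax' must be in (0, 1]")
  if (gamma <= 0) stop("biomarker_params: 'gamma' must be > 0")
  structure(list(name = name, e0 = e0, base = base, ic50 = ic50,
                 imax = imax, gamma = gamma), class = "biomarker_params")
}

#' Between-subject variability and residual error
#'
#' A single log-normal random effect acts on `CL32` (the only parameter with
#' estimated interindividual variability); proportional residual error is
#' carried per observable, with `sigma_prop` the plasma mRNA value.
#'
#' @param omega_cl32 SD of the log-scale random effect on `CL32`.
#' @param sigma_prop proportional residual error SD (fraction) for plasma
#'   mRNA concentrations.
#' @param sigma_obs optional named vector of proportional residual SDs per
#'   observable (`mrna`, `pcc`, `2mc`, `3hp`, `c3c2`); unnamed observables
#'   fall back to `sigma_prop`.
#' @return An object of class `population_params`.
#' @export
population_params <- function(omega_cl32, sigma_prop, sigma_obs = NULL) {
  if (omega_cl32 < 0) stop("population_params: 'omega_cl32' must be >= 0")
  if (sigma_prop < 0) stop("population_params: 'sigma_prop' must be >= 0")
  sig <- c(mrna = unname(sigma_prop))
  if (!is.null(sigma_obs)) {
    stopifnot(!is.null(names(sigma_obs)), all(sigma_obs >= 0))
    sig[names(sigma_obs)] <- sigma_obs
  }
  structure(list(omega_cl32 = omega_cl32, sigma_prop = sigma_prop,
                 sigma_obs = sig), class = "population_params")
}

sigma_for <- function(pop, dvid) {
  s <- unname(pop$sigma_obs[dvid])
  if (length(s) != 1 || is.na(s)) s <- pop$sigma_prop
  s
}

#' Allometric scaling of PK parameters to an individual body weight
#'
#' Scales clearances and volumes by power laws of body weight relative to the
#' reference weight: `CL12` and `CL32` by `(wt/wt_ref)^cl_alpha`, `CL23` and
#' `CL20` by `(wt/wt_ref)^cl_beta`, volumes by `(wt/wt_ref)^v_exponent`, and
#' derives the first-order micro rates `k12 = CL12/V`, `k23 = CL23/V2`,
#' `k32 = CL32/V`, `k20 = CL20/V2`.
#'
#' @param params a [pk_params()] object.
#' @param wt body weight, kg.
#' @param id optional subject label used in error messages.
#' @return A list with scaled `CL12`, `CL23`, `CL32`, `CL20`, `V`, `V2` and
#'   the derived rates `k12`, `k23`, `k32`, `k20`.
#' @export
allometric_scale <- function(params, wt, id = NULL) {
  stopifnot(inherits(params, "pk_params"))
  if (!is.finite(wt) || wt <= 0) {
    stop(sprintf("allometric_scale: non-positive body weight%s",
                 if (is.null(id)) "" else sprintf(" for subject '%s'", id)))
  }
  r <- wt / params$wt_ref
  CL12 <- params$tvCL12 * r^params$cl_alpha
  CL32 <- params$tvCL32 * r^params$cl_alpha
  CL23 <- params$tvCL23 * r^params$cl_beta
  CL20 <- params$tvCL20 * r^params$cl_beta
  V <- params$tvV * r^params$v_exponent
  V2 <- params$tvV2 * r^params$v_exponent
  list(CL12 = CL12, CL23 = CL23, CL32 = CL32, CL20 = CL20, V = V, V2 = V2,
       k12 = CL12 / V, k23 = CL23 / V2, k32 = CL32 / V, k20 = CL20 / V2)
}

#' Terminal half-life of the two-pool protein subsystem
#'
#' The protein pools decay (once synthesis has ceased) according to the
#' linear system with matrix `[[-(kdeg+kq), kq], [kq, -kq]]`; the terminal
#' half-life is `ln(2)` over the magnitude of its slowest eigenvalue.
#'
#' @param pd a [pd_params()] object.
#' @return Terminal half-life in hours.
#' @export
protein_terminal_halflife <- function(pd) {
  stopifnot(inherits(pd, "pd_params"))
  if (pd$kdeg <= 0) stop("protein_terminal_halflife: 'kdeg' must be > 0")
  ev <- protein_eigenvalues(pd$kdeg, pd$kq)
  # kq = 0 decouples the second pool (zero eigenvalue, never populated);
  # the decaying mode is then kdeg alone
  dec <- ev[ev < 0]
  unname(log(2) / abs(max(dec)))
}

# eigenvalues of [[-(kdeg+kq), kq], [kq, -kq]]; real because the matrix is
# sign-symmetrizable (off-diagonal product kq^2 >= 0)
protein_eigenvalues <- function(kdeg, kq) {
  tr <- -(kdeg + 2 * kq)
  det <- kdeg * kq
  disc <- sqrt(tr^2 - 4 * det)
  c(slow = (tr + disc) / 2, fast = (tr - disc) / 2)
}

#' Biomarker level at a given total hepatic protein concentration
#'
#' Direct sigmoidal Imax model: `e0 + base * (1 - imax * p^gamma /
#' (ic50^gamma + p^gamma))`.  Non-increasing in `p_total`.
#'
#' @param p_total total hepatic protein, ug/g (vectorised).
#' @param bp a [biomarker_params()] object.
#' @return Biomarker level(s) in the biomarker's units.
#' @export
biomarker_level <- function(p_total, bp) {
  stopifnot(inherits(bp, "biomarker_params"), all(p_total >= 0))
  pg <- p_total^bp$gamma
  bp$e0 + bp$base * (1 - bp$imax * pg / (bp$ic50^bp$gamma + pg))
}

#' Fraction of the total biomarker baseline amenable to suppression
#'
#' @param bp a [biomarker_params()] object.
#' @return `base / (e0 + base)`, in `[0, 1]`.
#' @export
amenable_fraction <- function(bp) {
  stopifnot(inherits(bp, "biomarker_params"))
  tot <- bp$e0 + bp$base
  if (tot <= 0) stop("amenable_fraction: total baseline e0 + base must be > 0")
  bp$base / tot
}

#' Convert a log-normal SD to a coefficient of variation (and back)
#'
#' For a log-normal random effect with log-scale SD `omega`, the exact
#' coefficient of variation is `100 * sqrt(exp(omega^2) - 1)` percent.
#'
#' @param omega log-scale SD (>= 0).
#' @return CV in percent.
#' @export
cv_from_omega <- function(omega) {
  stopifnot(all(omega >= 0))
  100 * sqrt(exp(omega^2) - 1)
}

#' @rdname cv_from_omega
#' @param cv coefficient of variation in percent (>= 0).
#' @return `omega_from_cv`: the log-scale SD.
#' @export
omega_from_cv <- function(cv) {
  stopifnot(all(cv >= 0))
  sqrt(log(1 + (cv / 100)^2))
}

#' @export
print.pk_params <- function(x, ...) {
  cat("mRNA disposition parameters (typical values at",
      format(x$wt_ref), "kg):\n")
  cat(sprintf("  CL12 %.4g  CL23 %.4g  CL32 %.4g  CL20 %.4g mL/h\n",
              x$tvCL12, x$tvCL23, x$tvCL32, x$tvCL20))
  cat(sprintf("  V %.4g  V2 %.4g mL;  exponents: CL alpha %.3g, CL beta %.3g, V %.3g\n",
              x$tvV, x$tvV2, x$cl_alpha, x$cl_beta, x$v_exponent))
  invisible(x)
}

#' @export
print.biomarker_params <- function(x, ...) {
  cat(sprintf("Imax biomarker model '%s': E0 %.4g, base %.4g, IC50 %.4g ug/g, Imax %.4g, gamma %.3g\n",
              x$name, x$e0, x$base, x$ic50, x$imax, x$gamma))
  cat(sprintf("  amenable fraction %.3f\n", amenable_fraction(x)))
  invisible(x)
}
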