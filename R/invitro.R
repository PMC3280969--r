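#' Assembly and disassembly efficiency from particle concentrations
#'
#' Assembly efficiency is the fraction of double-layered particles (DLP)
#' converted to triple-layered particles at equilibrium,
#' `([DLP]0 - [DLP]e) / [DLP]0`; disassembly efficiency is the symmetric
#' fraction of RLP stripped back to DLP.
#'
#' @param p0 initial particle concentration, M (> 0).
#' @param pe particle concentration at equilibrium, M (0 <= pe <= p0).
#' @return fraction in `[0, 1]`.
#' @examples
#' assembly_efficiency(10e-12, 5.2e-12)  # 0.48
#' @export
assembly_efficiency <- function(p0, pe) {
  if (any(p0 <= 0)) stop("initial concentration must be > 0", call. = FALSE)
  if (any(pe < 0) || any(pe > p0)) {
    stop("equilibrium concentration must lie in [0, p0]", call. = FALSE)
  }
  (p0 - pe) / p0
}

#' @rdname assembly_efficiency
#' @export
disassembly_efficiency <- assembly_efficiency

#' One in vitro assembly/disassembly observation
#'
#' @param label short condition label.
#' @param kind `"assembly"`, `"disassembly"` or `"reassembly"`.
#' @param temperature K.
#' @param efficiency measured assembly (or disassembly) efficiency,
#'   strictly inside (0, 1) for energy estimation; printed detection
#'   bounds (e.g. "<0.10") enter at their boundary value.
#' @param dlp0 initial DLP concentration, M (assembly/reassembly).
#' @param rlp0 initial RLP concentration, M (disassembly).
#' @param vp7_0 total initial vp7 protein concentration, M.
#' @param condition free-text physicochemical descriptor.
#' @return an object of class `"invitro_obs"`.
#' @export
invitro_obs <- function(label, kind = c("assembly", "disassembly",
                                        "reassembly"),
                        temperature, efficiency,
                        dlp0 = NA_real_, rlp0 = NA_real_,
                        vp7_0 = NA_real_, condition = "") {
  kind <- match.arg(kind)
  if (temperature <= 0) stop("temperature must be > 0 K", call. = FALSE)
  if (!is.finite(efficiency) || efficiency <= 0 || efficiency >= 1) {
    stop("efficiency must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(label = label, kind = kind, temperature = temperature,
                 efficiency = efficiency, dlp0 = dlp0, rlp0 = rlp0,
                 vp7_0 = vp7_0, condition = condition),
            class = "invitro_obs")
}

#' Estimate vp7 association energies from an assembly observation
#'
#' Treats the vp7 layer as one lumped equilibrium reaction,
#' `DLP + 20 subunits <-> RLP`, and reconstructs its equilibrium constant
#' from a measured assembly efficiency: `[RLP]e = eff * [DLP]0`,
#' `[DLP]e = (1 - eff) * [DLP]0`, free vp7 protein
#' `[vp7]0 - 780 * [RLP]e` expressed as trimers, and
#' `Keq = [RLP]e / ([DLP]e * [trimer]e^20)`. The layer free energy is
#' `-RT ln Keq` and the per-subunit free energy divides out the 50
#' contacts of the docked layer after removing the layer statistical
#' factor of 2: `dG_subunit = -RT (ln Keq - ln 2) / 50`.
#'
#' @param obs an [invitro_obs()] of kind `"assembly"` or `"reassembly"`.
#' @return an object of class `"thermo_estimate"`: list with `ln_keq`,
#'   `dg_layer_kcal` (kcal/mol), `dg_subunit_cal` (cal/mol),
#'   `temperature`, `label`. (`Keq` itself overflows double precision at
#'   these magnitudes, so it is carried in log form.)
#' @examples
#' obs <- invitro_obs("standard", "assembly", 298.15, 0.48,
#'                    dlp0 = 10e-12, vp7_0 = 7.8e-9)
#' dg_from_assembly(obs)  # ~ -4830 cal/mol per subunit
#' @export
dg_from_assembly <- function(obs) {
  stopifnot(inherits(obs, "invitro_obs"))
  if (obs$kind == "disassembly") {
    stop("dg_from_assembly expects an assembly/reassembly observation",
         call. = FALSE)
  }
  eff <- obs$efficiency
  rlp_e <- eff * obs$dlp0
  dlp_e <- (1 - eff) * obs$dlp0
  free_vp7 <- obs$vp7_0 - STOICH_VP7 * rlp_e
  if (free_vp7 <= 0) {
    stop("infeasible observation: all vp7 consumed", call. = FALSE)
  }
  trimer_e <- free_vp7 / 3
  ln_keq <- log(rlp_e) - log(dlp_e) - 20 * log(trimer_e)
  rt <- R_CAL * obs$temperature
  structure(list(
    ln_keq = ln_keq,
    dg_layer_kcal = -rt * ln_keq / 1000,
    dg_subunit_cal = -rt * (ln_keq - log(2)) / 50,
    temperature = obs$temperature,
    label = obs$label
  ), class = "thermo_estimate")
}

#' @export
print.thermo_estimate <- function(x, ...) {
  cat(sprintf(
    "<thermo_estimate> %s at %.2f K: ln Keq = %.2f, dG_layer = %.1f kcal/mol, dG_subunit = %.1f cal/mol\n",
    x$label, x$temperature, x$ln_keq, x$dg_layer_kcal, x$dg_subunit_cal))
  invisible(x)
}

#' @export
coef.thermo_estimate <- function(object, ...) {
  c(ln_keq = object$ln_keq,
    dg_layer_kcal = object$dg_layer_kcal,
    dg_subunit_cal = object$dg_subunit_cal)
}

#' Predicted assembly efficiency from a per-subunit association energy
#'
#' Inverse of [dg_from_assembly()]: solves the lumped-layer equilibrium
#' for the efficiency at which the implied per-subunit free energy equals
#' `dg_subunit_cal`. The estimator is strictly decreasing in efficiency
#' (more assembly implies more negative energy), so a bracketed root is
#' unique; it round-trips with [dg_from_assembly()] to better than 1e-6
#' relative.
#'
#' @param dg_subunit_cal per-subunit association energy, cal/mol.
#' @param dlp0 initial DLP concentration, M.
#' @param vp7_0 total initial vp7 protein, M.
#' @param temperature K.
#' @return predicted efficiency in (0, 1). If the root lies outside the
#'   feasible open interval the nearest boundary is returned with
#'   attribute `boundary = TRUE`.
#' @export
efficiency_from_dg <- function(dg_subunit_cal, dlp0 = 10e-12,
                               vp7_0 = 7.8e-9, temperature = 298.15) {
  eps <- 1e-12
  upper_eff <- min(1 - eps, vp7_0 / (STOICH_VP7 * dlp0) - eps)
  g <- function(eff) {
    obs <- invitro_obs("probe", "assembly", temperature, eff,
                       dlp0 = dlp0, vp7_0 = vp7_0)
    dg_from_assembly(obs)$dg_subunit_cal - dg_subunit_cal
  }
  g_lo <- g(eps)          # decreasing: large positive at eff -> 0
  g_hi <- g(upper_eff)
  if (g_lo <= 0) return(structure(eps, boundary = TRUE))
  if (g_hi >= 0) return(structure(upper_eff, boundary = TRUE))
  stats::uniroot(g, lower = eps, upper = upper_eff, tol = 1e-14)$root
}

#' Van't Hoff decomposition of an equilibrium-constant series
#'
#' Ordinary least squares of `ln Keq` against `1/T`: the slope is
#' `-dH0/R` and the intercept `dS0/R`, giving the standard enthalpy and
#' entropy of the lumped layer-assembly reaction under the usual
#' assumption that both are constant over the temperature range.
#'
#' @param temperature numeric vector of temperatures, K (>= 2 distinct).
#' @param ln_keq log equilibrium constants at those temperatures.
#' @return an object of class `"vant_hoff"` wrapping the underlying
#'   [stats::lm()] fit, with `dh0` (cal/mol), `ds0` (cal/mol/K) and
#'   their standard errors.
#' @examples
#' tt <- c(288.15, 298.15, 308.15)
#' lnk <- (30000 / R_CAL) / tt + (-85 / R_CAL)  # dH0 = -30 kcal, dS0 = -85
#' vant_hoff(tt, lnk)
#' @export
vant_hoff <- function(temperature, ln_keq) {
  stopifnot(length(temperature) == length(ln_keq),
            all(is.finite(temperature)), all(is.finite(ln_keq)))
  if (length(unique(temperature)) < 2L) {
    stop("van't Hoff fit needs at least two distinct temperatures",
         call. = FALSE)
  }
  inv_t <- 1 / temperature
  fit <- stats::lm(ln_keq ~ inv_t)
  cf <- stats::coef(fit)
  se <- if (length(temperature) > 2L) {
    # suppress the "essentially perfect fit" note on noiseless series
    suppressWarnings(sqrt(diag(stats::vcov(fit))))
  } else c(NA_real_, NA_real_)
  structure(list(
    dh0 = -unname(cf[2]) * R_CAL,
    ds0 = unname(cf[1]) * R_CAL,
    dh0_se = unname(se[2]) * R_CAL,
    ds0_se = unname(se[1]) * R_CAL,
    fit = fit,
    n = length(temperature)
  ), class = "vant_hoff")
}

#' @export
print.vant_hoff <- function(x, ...) {
  cat(sprintf(
    "<vant_hoff> n = %d: dH0 = %.1f cal/mol, dS0 = %.3f cal/mol/K\n",
    x$n, x$dh0, x$ds0))
  invisible(x)
}

#' @export
coef.vant_hoff <- function(object, ...) {
  c(dh0 = object$dh0, ds0 = object$ds0)
}

#' @export
summary.vant_hoff <- function(object, ...) {
  out <- list(dh0 = object$dh0, ds0 = object$ds0,
              dh0_se = object$dh0_se, ds0_se = object$ds0_se,
              lm_summary = suppressWarnings(summary(object$fit)))
  class(out) <- "summary.vant_hoff"
  out
}

#' @export
print.summary.vant_hoff <- function(x, ...) {
  cat(sprintf("dH0 = %.1f +/- %.1f cal/mol\n", x$dh0, x$dh0_se))
  cat(sprintf("dS0 = %.3f +/- %.3f cal/mol/K\n", x$ds0, x$ds0_se))
  invisible(x)
}

#' Estimate energies for every assembly row of an observation table
#'
#' @param obs data frame as returned by [read_observations()].
#' @return data frame with one row per assembly/reassembly observation:
#'   label, temperature_K, efficiency, ln_keq, dg_subunit_cal,
#'   dg_layer_kcal.
#' @export
estimate_observations <- function(obs) {
  keep <- obs$kind %in% c("assembly", "reassembly") &
    is.finite(obs$efficiency)
  rows <- which(keep)
  est <- lapply(rows, function(i) {
    o <- invitro_obs(obs$label[i], obs$kind[i], obs$temperature_K[i],
                     obs$efficiency[i], dlp0 = obs$dlp0_M[i],
                     vp7_0 = obs$vp7_0_M[i], condition = obs$condition[i])
    dg_from_assembly(o)
  })
  data.frame(
    label = obs$label[rows],
    temperature_K = obs$temperature_K[rows],
    efficiency = obs$efficiency[rows],
    ln_keq = vapply(est, `[[`, numeric(1), "ln_keq"),
    dg_subunit_cal = vapply(est, `[[`, numeric(1), "dg_subunit_cal"),
    dg_layer_kcal = vapply(est, `[[`, numeric(1), "dg_layer_kcal"),
    stringsAsFactors = FALSE
  )
}
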