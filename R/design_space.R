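#' Irreversible-assembly reference efficiency
#'
#' Upper bound on the mass assembly efficiency obtained by assuming every
#' possible complete particle forms: the particle count is limited by the
#' scarcest protein relative to the 120:780:780 stoichiometry and nothing
#' is lost to intermediates,
#' `particles = min(vp2_0/120, vp6_0/780, vp7_0/780)`.
#'
#' @param vp2_0,vp6_0,vp7_0 initial protein concentrations, M.
#' @return mass efficiency in `[0, 1]`.
#' @examples
#' irreversible_efficiency(1.2, 7.8, 7.8)  # exact stoichiometry -> 1
#' @export
irreversible_efficiency <- function(vp2_0, vp6_0, vp7_0) {
  stopifnot(all(vp2_0 >= 0), all(vp6_0 >= 0), all(vp7_0 >= 0))
  mass0 <- vp2_0 * MASS_VP2 + vp6_0 * MASS_VP6 + vp7_0 * MASS_VP7
  if (any(mass0 == 0)) {
    stop("efficiency undefined: no initial protein", call. = FALSE)
  }
  particles <- pmin(vp2_0 / STOICH_VP2, vp6_0 / STOICH_VP6,
                    vp7_0 / STOICH_VP7)
  mass_particle <- STOICH_VP2 * MASS_VP2 + STOICH_VP6 * MASS_VP6 +
    STOICH_VP7 * MASS_VP7
  particles * mass_particle / mass0
}

#' Assembly efficiency as a function of the vp7 association energy
#'
#' Re-solves the full equilibrium over a grid of outer-layer association
#' energies, holding everything else fixed. Efficiency is monotone
#' non-increasing in the energy and saturates once the outer layer is no
#' longer limiting (around -4 kcal/mol for the default model).
#'
#' @param model a three-layer [vlp_model()] (default: stoichiometric
#'   scenario, [rlp_model()]).
#' @param dg_grid vp7 subunit association energies, kcal/mol.
#' @return data frame with columns `dg_vp7_kcal` and `efficiency`.
#' @export
dg_vp7_sweep <- function(model = rlp_model(), dg_grid) {
  stopifnot(inherits(model, "vlp_model"), length(model$layers) == 3L)
  eff <- numeric(length(dg_grid))
  st <- NULL  # warm-start each point from its neighbour
  for (k in seq_along(dg_grid)) {
    m <- model
    m$layers[[3]]$dg <- dg_grid[k] * 1000
    st <- solve_equilibrium(m, init = st)
    eff[k] <- st$efficiency_mass
  }
  data.frame(dg_vp7_kcal = dg_grid, efficiency = eff)
}

#' Species distribution under the three study scenarios
#'
#' Solves the full model for one of the named initial-concentration
#' scenarios: `"stoichiometric"` ([vp2]0 = 1.2 M, [vp6]0 = [vp7]0 =
#' 7.8 M), `"vp7-limited"` ([vp7]0 cut tenfold to 0.78 M) and
#' `"vp2-excess"` ([vp2]0 raised tenfold to 12 M).
#'
#' @param model a three-layer [vlp_model()]; its `conc0` is replaced by
#'   the scenario values.
#' @param scenario scenario name.
#' @return the solved `"vlp_equilibrium"` state.
#' @export
scenario_distribution <- function(model = rlp_model(),
                                  scenario = c("stoichiometric",
                                               "vp7-limited",
                                               "vp2-excess")) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(model, "vlp_model"), length(model$layers) == 3L)
  model$conc0 <- switch(scenario,
    "stoichiometric" = c(vp2 = 1.2, vp6 = 7.8, vp7 = 7.8),
    "vp7-limited"    = c(vp2 = 1.2, vp6 = 7.8, vp7 = 0.78),
    "vp2-excess"     = c(vp2 = 12,  vp6 = 7.8, vp7 = 7.8))
  solve_equilibrium(model)
}

#' Efficiency landscape over vp6/vp7 concentration ratios
#'
#' Maps the mass assembly efficiency over a grid of initial-concentration
#' ratios `[vp6]0/[vp2]0` and `[vp7]0/[vp2]0` at fixed `[vp2]0`, for
#' either the equilibrium model or the irreversible reference. The
#' irreversible landscape dominates the equilibrium landscape pointwise
#' and both peak at the stoichiometric ratios (6.5, 6.5) for
#' sufficiently negative association energies.
#'
#' @param dg common subunit association energy for all layers, kcal/mol
#'   (ignored for `kind = "irreversible"`).
#' @param vp2_0 fixed initial vp2 protein concentration, M.
#' @param vp6_ratio,vp7_ratio ratio grids; defaults are log-spaced over
#'   0.1..1000 with the stoichiometric ratio 6.5 inserted so the
#'   published optimum is on the grid.
#' @param kind `"equilibrium"` or `"irreversible"`.
#' @param temperature K.
#' @return an object of class `"vlp_landscape"`: list with the grids, an
#'   `efficiency` matrix (vp6 ratios in rows), `argmax` (the maximising
#'   ratio pair) and the settings.
#' @export
assembly_landscape <- function(dg = -4.08, vp2_0 = 1,
                               vp6_ratio = landscape_ratio_grid(),
                               vp7_ratio = landscape_ratio_grid(),
                               kind = c("equilibrium", "irreversible"),
                               temperature = 298.15) {
  kind <- match.arg(kind)
  stopifnot(all(vp6_ratio > 0), all(vp7_ratio > 0), vp2_0 > 0)
  eff <- matrix(NA_real_, length(vp6_ratio), length(vp7_ratio))
  row_start <- NULL  # warm-start each solve from its grid neighbour
  for (i in seq_along(vp6_ratio)) {
    st <- row_start
    for (j in seq_along(vp7_ratio)) {
      c6 <- vp6_ratio[i] * vp2_0
      c7 <- vp7_ratio[j] * vp2_0
      if (kind == "irreversible") {
        eff[i, j] <- irreversible_efficiency(vp2_0, c6, c7)
      } else {
        st <- solve_equilibrium(rlp_model(
          dg_vp2 = dg, dg_vp6 = dg, dg_vp7 = dg,
          conc0 = c(vp2 = vp2_0, vp6 = c6, vp7 = c7),
          temperature = temperature), init = st)
        eff[i, j] <- st$efficiency_mass
        if (j == 1L) row_start <- st
      }
    }
  }
  amax <- arrayInd(which.max(eff), dim(eff))
  structure(list(
    vp6_ratio = vp6_ratio, vp7_ratio = vp7_ratio, efficiency = eff,
    argmax = c(vp6_ratio = vp6_ratio[amax[1]],
               vp7_ratio = vp7_ratio[amax[2]]),
    dg = dg, vp2_0 = vp2_0, kind = kind, temperature = temperature
  ), class = "vlp_landscape")
}

#' Default ratio grid for [assembly_landscape()]
#'
#' Log-spaced points over 0.1..1000 with the stoichiometric ratio 6.5
#' inserted.
#'
#' @param n number of log-spaced points.
#' @return sorted numeric vector.
#' @export
landscape_ratio_grid <- function(n = 15) {
  sort(unique(c(10^seq(-1, 3, length.out = n), 6.5)))
}

#' @export
print.vlp_landscape <- function(x, ...) {
  cat(sprintf(
    "<vlp_landscape> %s, dG = %.3g kcal/mol, %d x %d grid, [vp2]0 = %g M\n",
    x$kind, x$dg, length(x$vp6_ratio), length(x$vp7_ratio), x$vp2_0))
  cat(sprintf("  max efficiency %.4g at vp6/vp2 = %.3g, vp7/vp2 = %.3g\n",
              max(x$efficiency), x$argmax[1], x$argmax[2]))
  invisible(x)
}

#' Plot an efficiency landscape
#'
#' Filled-contour view of the efficiency surface on log ratio axes.
#'
#' @param x a `"vlp_landscape"`.
#' @param ... passed to [graphics::filled.contour()].
#' @return the landscape, invisibly.
#' @export
plot.vlp_landscape <- function(x, ...) {
  graphics::filled.contour(
    log10(x$vp6_ratio), log10(x$vp7_ratio), x$efficiency,
    xlab = "log10 [vp6]0/[vp2]0", ylab = "log10 [vp7]0/[vp2]0", ...)
  invisible(x)
}
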