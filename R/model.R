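#' Define one icosahedral capsid layer
#'
#' A layer is a shell of 20 structural subunits. For the rotavirus-like
#' particle the inner vp2 layer is built from subunits of 3 dimers (6
#' proteins, degeneracy `s2 = 3`, `z = 2` proteins per asymmetric unit)
#' and assembles free-standing; the vp6 and vp7 layers are built from
#' subunits of 13 trimers (39 proteins, `s2 = 13`, `z = 3`) and dock only
#' onto a completed template layer. Sub-subunit oligomerisation (dimer and
#' trimer formation, and the stepwise growth of a 13-trimer subunit) is
#' lumped: the free pool of a docked layer is its trimer, related to the
#' free-subunit activity through `[free subunit] = [trimer]^13`
#' (`free_pool_exponent = 13`), while the free pool of a free-standing
#' layer is the structural subunit itself (`free_pool_exponent = 1`).
#'
#' @param name layer label, e.g. `"vp2"`.
#' @param protein_mass molar mass of one protein, kDa.
#' @param dg standard Gibbs free energy of subunit association credited
#'   per inter-subunit contact, in `dg_unit` per mol (negative favours
#'   assembly).
#' @param s2 degeneracy of the incoming subunit (3 for the vp2 layer, 13
#'   for vp6/vp7 layers).
#' @param z proteins per asymmetric unit (2 for vp2, 3 for vp6/vp7).
#' @param docked logical; `TRUE` for a layer that assembles on a completed
#'   template particle.
#' @param free_pool_exponent exponent relating the free building-block
#'   (pool) concentration to the subunit activity: 1 when the pool is the
#'   subunit, 13 when the pool is the trimer of a 13-trimer subunit.
#' @param ln_stat_total total natural-log statistical factor of the layer
#'   (the log-product of all build-up/build-down and degeneracy factors
#'   over the layer's additions). Defaults: the calibrated vp2-layer value
#'   [vlp_ln_stat_vp2()] for a free-standing layer, `log(2)` (the lumped
#'   layer factor consistent with the in vitro estimator) for a docked
#'   layer. Spread uniformly over the layer's additions; only the total
#'   affects the completed-shell species.
#' @param n_subunits structural subunits per layer; only 20 supported.
#' @param dg_unit `"cal"` (default) or `"kcal"` per mol.
#' @return an object of class `"layer_spec"`.
#' @seealso [vlp_model()], [rlp_model()]
#' @export
layer_spec <- function(name, protein_mass, dg,
                       s2 = 13L, z = 3L, docked = TRUE,
                       free_pool_exponent = if (docked) 13L else 1L,
                       ln_stat_total = NULL,
                       n_subunits = 20L,
                       dg_unit = c("cal", "kcal")) {
  dg <- .dg_to_cal(dg, match.arg(dg_unit))
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(protein_mass), protein_mass > 0,
            is.numeric(dg), is.finite(dg),
            s2 >= 1, z >= 1, n_subunits >= 2)
  if (n_subunits != 20L) {
    stop("only 20-subunit icosahedral layers are implemented", call. = FALSE)
  }
  if (is.null(ln_stat_total)) {
    ln_stat_total <- if (docked) log(2) else vlp_ln_stat_vp2()
  }
  proteins_per_subunit <- s2 * z
  if (proteins_per_subunit %% free_pool_exponent != 0) {
    stop("free_pool_exponent must divide s2 * z", call. = FALSE)
  }
  structure(list(
    name = name,
    n_subunits = as.integer(n_subunits),
    s2 = as.integer(s2),
    z = as.integer(z),
    proteins_per_subunit = proteins_per_subunit,
    pool_proteins = proteins_per_subunit / free_pool_exponent,
    protein_mass = protein_mass,
    dg = dg,
    docked = isTRUE(docked),
    free_pool_exponent = as.integer(free_pool_exponent),
    ln_stat_total = ln_stat_total
  ), class = "layer_spec")
}

#' @export
print.layer_spec <- function(x, ...) {
  cat(sprintf(
    "<layer_spec> %s: 20 x (%d x %d)-protein subunits, %s, dG = %.1f cal/mol\n",
    x$name, x$s2, x$z, if (x$docked) "template-docked" else "free-standing",
    x$dg))
  invisible(x)
}

#' Assemble a multi-layer equilibrium model
#'
#' Combines ordered layer definitions (innermost first; the first layer
#' must be free-standing, all others docked), total initial protein
#' concentrations per layer and a temperature into the model object
#' consumed by [solve_equilibrium()] and the design-space functions.
#'
#' @param layers list of [layer_spec()] objects, innermost first.
#' @param conc0 numeric vector of total initial protein concentration per
#'   layer, M (protein molar units), in the same order as `layers`.
#' @param temperature temperature in K.
#' @return an object of class `"vlp_model"` with elements `layers`,
#'   `conc0`, `temperature`.
#' @examples
#' m <- rlp_model()
#' m
#' @export
vlp_model <- function(layers, conc0, temperature = 298.15) {
  stopifnot(is.list(layers), length(layers) >= 1L,
            all(vapply(layers, inherits, logical(1), "layer_spec")),
            is.numeric(conc0), length(conc0) == length(layers),
            all(conc0 >= 0), is.numeric(temperature))
  if (temperature <= 0) stop("temperature must be > 0 K", call. = FALSE)
  if (layers[[1]]$docked) {
    stop("the innermost layer must be free-standing", call. = FALSE)
  }
  if (length(layers) > 1L &&
      !all(vapply(layers[-1], `[[`, logical(1), "docked"))) {
    stop("all layers above the innermost must be template-docked",
         call. = FALSE)
  }
  names(conc0) <- vapply(layers, `[[`, character(1), "name")
  structure(list(layers = layers, conc0 = conc0, temperature = temperature),
            class = "vlp_model")
}

#' @export
print.vlp_model <- function(x, ...) {
  cat(sprintf("<vlp_model> %d layer(s), T = %.2f K\n",
              length(x$layers), x$temperature))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  %-4s %s  dG = %8.1f cal/mol  [%s]0 = %g M\n",
                l$name, if (l$docked) "docked " else "free   ",
                l$dg, l$name, x$conc0[i]))
  }
  invisible(x)
}

#' Default triple-layered rotavirus-like particle model
#'
#' The packaged default: vp2 (102.7 kDa, inner, free-standing), vp6
#' (44.9 kDa, docked) and vp7 (37.2 kDa, docked) with particle
#' stoichiometry 120:780:780 proteins. Default initial concentrations are
#' the stoichiometric simulation scenario ([vp2]0 = 1.2 M,
#' [vp6]0 = [vp7]0 = 7.8 M) and default association energies are
#' -4.08 kcal/mol per layer.
#'
#' @param dg_vp2,dg_vp6,dg_vp7 subunit association energies, kcal/mol.
#' @param conc0 initial protein concentrations (vp2, vp6, vp7), M.
#' @param temperature K.
#' @return a `"vlp_model"`.
#' @export
rlp_model <- function(dg_vp2 = -4.08, dg_vp6 = -4.08, dg_vp7 = -4.08,
                      conc0 = c(vp2 = 1.2, vp6 = 7.8, vp7 = 7.8),
                      temperature = 298.15) {
  vlp_model(
    layers = list(
      layer_spec("vp2", MASS_VP2, dg_vp2, s2 = 3, z = 2, docked = FALSE,
                 dg_unit = "kcal"),
      layer_spec("vp6", MASS_VP6, dg_vp6, s2 = 13, z = 3, docked = TRUE,
                 dg_unit = "kcal"),
      layer_spec("vp7", MASS_VP7, dg_vp7, s2 = 13, z = 3, docked = TRUE,
                 dg_unit = "kcal")
    ),
    conc0 = conc0,
    temperature = temperature
  )
}

#' Single-layer (vp2-only) model
#'
#' @param dg vp2 subunit association energy, kcal/mol.
#' @param conc0 initial vp2 protein concentration, M.
#' @param temperature K.
#' @return a `"vlp_model"` with one layer.
#' @export
slp_model <- function(dg = -4.08, conc0 = 1.2, temperature = 298.15) {
  vlp_model(
    layers = list(layer_spec("vp2", MASS_VP2, dg, s2 = 3, z = 2,
                             docked = FALSE, dg_unit = "kcal")),
    conc0 = c(vp2 = conc0),
    temperature = temperature
  )
}
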