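#' Log-concentrations of all species given free-pool values
#'
#' Evaluates the law-of-mass-action expression for every species on the
#' assembly ladder: `ln[n] = cum_ln_k(n) + sum_l e_l(n) * ln(pool_l)`,
#' where `e_l(n)` is the free-pool exponent of layer `l` in species `n`
#' (the number of that layer's subunits present times the layer's
#' `free_pool_exponent`; for vp6/vp7 the incoming-subunit activity is
#' `[trimer]^13`). Carried entirely in log space because cumulative
#' association constants reach e^400 and beyond.
#'
#' @param table a [species_table()].
#' @param ln_free numeric vector of log free-pool concentrations, one per
#'   layer (`-Inf` for an absent pool), ln(M).
#' @return numeric vector `ln[n]`, one entry per species.
#' @export
species_ln_conc <- function(table, ln_free) {
  stopifnot(inherits(table, "species_table"))
  expo <- attr(table, "pool_exponents")
  if (length(ln_free) != ncol(expo)) {
    stop("ln_free must have one entry per layer", call. = FALSE)
  }
  contrib <- sweep(expo, 2, ln_free, `*`)
  contrib[expo == 0] <- 0  # 0 * -Inf: species without that layer
  table$cum_ln_k + rowSums(contrib)
}

## log total protein of layer l implied by the pools:
## free building blocks plus proteins_per_subunit per subunit in species
.ln_total_protein <- function(table, ln_free, l) {
  model <- attr(table, "model")
  lay <- model$layers[[l]]
  m_l <- attr(table, "m_layer")[, l]
  ln_sp <- species_ln_conc(table, ln_free)
  keep <- m_l > 0L
  terms <- log(lay$proteins_per_subunit * m_l[keep]) + ln_sp[keep]
  if (lay$docked) {
    # free trimers are not a ladder species; count them explicitly
    terms <- c(terms, log(lay$pool_proteins) + ln_free[l])
  }
  logsumexp(terms)
}

#' Mass-balance residuals of a state
#'
#' Relative conservation error per layer protein:
#' `|total_implied - conc0| / max(conc0, eps)` where the implied total
#' counts free building blocks (6 proteins per free vp2 subunit, 3 per
#' free trimer) plus `z * s2` proteins per subunit over all species.
#'
#' @param model a [vlp_model()].
#' @param state a [solve_equilibrium()] result (or any list with
#'   `ln_free` and `table`).
#' @return named numeric vector of relative residuals, one per layer.
#' @export
mass_balance_residual <- function(model, state) {
  stopifnot(inherits(model, "vlp_model"))
  if (any(model$conc0 < 0)) {
    stop("initial concentrations must be >= 0", call. = FALSE)
  }
  table <- state$table
  vapply(seq_along(model$layers), function(l) {
    t0 <- model$conc0[l]
    lnT <- .ln_total_protein(table, state$ln_free, l)
    tot <- if (is.finite(lnT)) exp(lnT) else 0
    abs(tot - t0) / max(t0, 1e-300)
  }, numeric(1)) |>
    stats::setNames(names(model$conc0))
}

## gap_l = ln(total implied) - ln(conc0_l); monotone increasing in ln_free[l]
.balance_gap <- function(table, ln_free, l, ln_t0) {
  g <- .ln_total_protein(table, ln_free, l) - ln_t0
  # clamp so uniroot always sees finite values
  max(min(g, 1e15), -1e15)
}

#' Solve the coupled protein mass balances for the equilibrium state
#'
#' Finds the unique free-pool concentrations (free vp2 subunit; free vp6
#' and vp7 trimers) at which the law-of-mass-action species ladder
#' reproduces the total initial protein of every layer, then returns all
#' species concentrations and the mass-based assembly efficiency.
#'
#' The balances are solved by nested monotone root bracketing in log
#' space: the outer level adjusts the innermost layer's pool and each
#' inner level re-solves the balances of the layers above it. Each
#' balance is strictly monotone in its own pool along the inner-solved
#' manifold (the species totals are the gradient of a convex
#' log-partition function), so the bracketing is guaranteed. A layer with
#' zero total protein short-circuits: its pool and all species containing
#' it are zero, and any layer docking above it keeps all of its protein
#' in the free pool.
#'
#' @param model a [vlp_model()].
#' @param table optionally a precomputed [species_table()] for `model`.
#' @param tol relative mass-balance tolerance (default 1e-10, reported
#'   residuals are checked against 1e-8).
#' @param maxiter iteration cap per root bracketing level.
#' @param init optional warm start: a previously solved
#'   `"vlp_equilibrium"` for a nearby model, or a numeric vector of log
#'   free-pool concentrations. Only a starting guess; the result is
#'   identical either way.
#' @return an object of class `"vlp_equilibrium"`: list with `ln_free`
#'   (log pool concentrations), `ln_species`, `conc` (molar, may
#'   underflow to 0), `efficiency_mass`, `residuals`, `table`, `model`.
#' @examples
#' st <- solve_equilibrium(rlp_model(dg_vp7 = -1))
#' st$efficiency_mass
#' @export
solve_equilibrium <- function(model, table = NULL, tol = 1e-10,
                              maxiter = 1000L, init = NULL) {
  stopifnot(inherits(model, "vlp_model"))
  if (any(!is.finite(model$conc0)) || any(model$conc0 < 0)) {
    stop("initial concentrations must be finite and >= 0", call. = FALSE)
  }
  if (is.null(table)) table <- species_table(model)
  L <- length(model$layers)
  pool_p <- vapply(model$layers, `[[`, numeric(1), "pool_proteins")

  # layers at and above the first zero-concentration layer cannot dock
  first_zero <- which(model$conc0 == 0)[1]
  n_active <- if (is.na(first_zero)) L else first_zero - 1L

  ln_free <- numeric(L)
  for (l in seq_len(L)) {
    if (l > n_active) {
      # cannot assemble: zero layer itself -> -Inf, layers above keep
      # all protein free (their species all contain the zero layer)
      ln_free[l] <- if (model$conc0[l] == 0) -Inf else
        log(model$conc0[l] / pool_p[l])
    }
  }

  if (n_active > 0L) {
    ln_t0 <- log(model$conc0[seq_len(n_active)])
    last_root <- rep(NA_real_, n_active)  # warm starts per nesting level
    if (!is.null(init)) {
      guess <- if (inherits(init, "vlp_equilibrium")) init$ln_free
               else as.numeric(init)
      k <- min(n_active, length(guess))
      last_root[seq_len(k)] <- ifelse(is.finite(guess[seq_len(k)]),
                                      guess[seq_len(k)], NA_real_)
    }

    solve_level <- function(l, mu) {
      # roots balance l given mu[1..l-1]; inner layers re-solved per trial
      upper <- log(model$conc0[l] / pool_p[l]) + 1e-6
      h <- function(x) {
        mu[l] <- x
        if (l < n_active) mu <- solve_level(l + 1L, mu)
        .balance_gap(table, mu, l, ln_t0[l])
      }
      # bracket: start tight around the previous root at this level and
      # expand until the monotone gap changes sign
      if (is.finite(last_root[l])) {
        hi <- min(last_root[l] + 0.5, upper)
        lo <- last_root[l] - 0.5
      } else {
        hi <- upper
        lo <- upper - 25
      }
      step <- 2
      while (h(hi) < 0 && hi < upper) {
        hi <- min(hi + step, upper)
        step <- step * 2
      }
      step <- 2
      while (h(lo) > 0 && lo > LN_ZERO) {
        lo <- max(lo - step, LN_ZERO)
        step <- step * 2
      }
      root <- stats::uniroot(h, lower = lo, upper = hi,
                             tol = 1e-13, maxiter = maxiter)$root
      last_root[l] <<- root
      mu[l] <- root
      if (l < n_active) mu <- solve_level(l + 1L, mu)
      mu
    }
    ln_free <- solve_level(1L, ln_free)
  }

  ln_species <- species_ln_conc(table, ln_free)
  state <- structure(list(
    ln_free = stats::setNames(ln_free, names(model$conc0)),
    ln_species = ln_species,
    conc = exp(ln_species),
    table = table,
    model = model
  ), class = "vlp_equilibrium")
  state$residuals <- mass_balance_residual(model, state)
  active_res <- state$residuals[seq_len(n_active)]
  if (n_active > 0L && any(active_res > 1e-8)) {
    stop(sprintf(
      "equilibrium solver did not converge: worst relative residual %.3g",
      max(active_res)), call. = FALSE)
  }
  state$efficiency_mass <- if (sum(model$conc0) == 0) NA_real_ else
    efficiency_mass(model, state)
  state
}

#' Mass-based assembly efficiency of a solved state
#'
#' Mass of the intact outermost species (the complete particle: species
#' 60 for the three-layer model, 20 for a single layer) divided by the
#' total initial protein mass.
#'
#' @param model a [vlp_model()].
#' @param state a solved [solve_equilibrium()] state.
#' @return fraction in `[0, 1]`.
#' @export
efficiency_mass <- function(model, state) {
  masses <- vapply(model$layers, `[[`, numeric(1), "protein_mass")
  pps <- vapply(model$layers, `[[`, numeric(1), "proteins_per_subunit")
  mass_particle <- sum(20 * pps * masses)
  mass_initial <- sum(model$conc0 * masses)
  if (mass_initial == 0) {
    stop("efficiency undefined: no initial protein", call. = FALSE)
  }
  n_species <- 20L * length(model$layers)
  conc_final <- exp(state$ln_species[n_species])
  conc_final * mass_particle / mass_initial
}

#' @export
print.vlp_equilibrium <- function(x, ...) {
  cat(sprintf("<vlp_equilibrium> %d species, T = %.2f K\n",
              length(x$ln_species), x$model$temperature))
  cat(sprintf("  mass assembly efficiency: %.4g%%\n",
              100 * x$efficiency_mass))
  cat("  free pools (M):",
      paste(sprintf("%s = %.4g", names(x$ln_free), exp(x$ln_free)),
            collapse = ", "), "\n")
  cat(sprintf("  worst mass-balance residual: %.2g\n", max(x$residuals)))
  invisible(x)
}

#' @export
summary.vlp_equilibrium <- function(object, n_top = 6L, ...) {
  ord <- order(object$ln_species, decreasing = TRUE)
  top <- data.frame(
    species = ord[seq_len(min(n_top, length(ord)))],
    layer = object$table$layer[ord[seq_len(min(n_top, length(ord)))]],
    conc_M = exp(object$ln_species[ord[seq_len(min(n_top, length(ord)))]])
  )
  out <- list(efficiency_mass = object$efficiency_mass,
              free_pools = exp(object$ln_free),
              residuals = object$residuals,
              dominant_species = top)
  class(out) <- "summary.vlp_equilibrium"
  out
}

#' @export
print.summary.vlp_equilibrium <- function(x, ...) {
  cat(sprintf("Mass assembly efficiency: %.4g%%\n",
              100 * x$efficiency_mass))
  cat("Dominant species at equilibrium:\n")
  print(x$dominant_species, row.names = FALSE)
  invisible(x)
}

#' Plot the species distribution of a solved state
#'
#' Log-scale bar plot of species concentration against species index,
#' the standard way of looking at which assembly intermediates matter.
#'
#' @param x a `"vlp_equilibrium"`.
#' @param floor lowest log10 concentration shown.
#' @param ... passed to [graphics::barplot()].
#' @return the state, invisibly.
#' @export
plot.vlp_equilibrium <- function(x, floor = -30, ...) {
  l10 <- x$ln_species / log(10)
  l10 <- pmax(l10, floor)
  graphics::barplot(l10 - floor, names.arg = x$table$index,
                    offset = floor,
                    xlab = "species n", ylab = "log10 concentration (M)",
                    ...)
  invisible(x)
}

#' @export
residuals.vlp_equilibrium <- function(object, ...) object$residuals
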