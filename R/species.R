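#' Non-statistical log association constant of one assembly step
#'
#' The association constant of an addition that forms `n_contacts` new
#' inter-subunit contacts, each credited the per-contact Gibbs free energy
#' `dg`: `ln K' = -n_contacts * dg / (R * T)` with R = 1.987
#' cal mol^-1 K^-1 and a 1 M reference state. With `n_contacts = 1` this
#' is the log of the single-contact association constant K_contact.
#'
#' @param dg Gibbs free energy per contact, cal/mol.
#' @param n_contacts number of new contacts formed (>= 0).
#' @param temperature K (> 0).
#' @return dimensionless `ln K'`.
#' @examples
#' ln_k_contact(-4080, 1, 298.15)   # single-contact constant, ~6.89
#' @export
ln_k_contact <- function(dg, n_contacts, temperature) {
  if (any(temperature <= 0)) {
    stop("temperature must be > 0 K", call. = FALSE)
  }
  stopifnot(all(n_contacts >= 0))
  -n_contacts * dg / (R_CAL * temperature)
}

#' Build the full species table of a model
#'
#' Enumerates the assembly ladder of a model (20 species per layer; for
#' the three-layer rotavirus model species 1..60 with species 1 the free
#' vp2 structural subunit, 20 = SLP, 40 = DLP, 60 = RLP) and computes per
#' addition the contact count, the per-step log statistical factor and
#' the cumulative log association constant
#' `cum_ln_k(n) = cum_ln_k(n-1) + ln(S1*S2) + ln K'_n` referenced to
#' species 1 and 1 M.
#'
#' Per-step statistical factors default to the layer total
#' (`ln_stat_total`) spread uniformly over the layer's additions (19 for
#' the free-standing layer, whose first species carries no factor; 20 for
#' a docked layer). A transcribed per-step table can be supplied via
#' `ln_stat_overrides`.
#'
#' @param model a [vlp_model()].
#' @param ln_stat_overrides optional numeric vector, one entry per
#'   species, of per-step `ln(S1*S2)` values replacing the uniform
#'   default (the species-1 entry must be 0).
#' @return a data frame of class `"species_table"` with columns `index`,
#'   `layer`, `m_subunits`, `n_contacts`, `ln_stat`, `cum_ln_k`, plus
#'   attributes used by the solver (`pool_exponents`, `m_layer` matrices).
#' @examples
#' tab <- species_table(rlp_model())
#' tab[c(1, 20, 40, 60), ]
#' @export
species_table <- function(model, ln_stat_overrides = NULL) {
  stopifnot(inherits(model, "vlp_model"))
  L <- length(model$layers)
  n_species <- 20L * L
  idx <- seq_len(n_species)
  layer_id <- rep(seq_len(L), each = 20L)
  m_in_layer <- rep(1:20, times = L)

  n_contacts <- numeric(n_species)
  ln_stat <- numeric(n_species)
  for (l in seq_len(L)) {
    lay <- model$layers[[l]]
    sched <- contact_schedule(docked = lay$docked)
    rows <- which(layer_id == l)
    n_contacts[rows] <- sched
    n_add <- if (lay$docked) 20L else 19L
    per_step <- lay$ln_stat_total / n_add
    ln_stat[rows] <- per_step
    if (!lay$docked) ln_stat[rows[1]] <- 0  # species 1 carries no factor
  }

  if (!is.null(ln_stat_overrides)) {
    if (length(ln_stat_overrides) != n_species) {
      stop(sprintf("ln_stat_overrides must have length %d", n_species),
           call. = FALSE)
    }
    if (ln_stat_overrides[1] != 0) {
      stop("the species-1 entry of ln_stat_overrides must be 0",
           call. = FALSE)
    }
    ln_stat <- as.numeric(ln_stat_overrides)
  }

  dg_step <- vapply(model$layers, `[[`, numeric(1), "dg")[layer_id]
  ln_kprime <- ln_k_contact(dg_step, n_contacts, model$temperature)
  ln_kprime[1] <- 0  # species 1 is the reference building block
  cum_ln_k <- cumsum(ln_stat + ln_kprime)
  cum_ln_k <- cum_ln_k - cum_ln_k[1]  # reference: species 1

  # exponent of each layer's free pool in the concentration of species n:
  # free_pool_exponent * (subunits of that layer present)
  m_layer <- matrix(0L, n_species, L)
  expo <- matrix(0, n_species, L)
  for (l in seq_len(L)) {
    m_layer[, l] <- pmin(pmax(idx - 20L * (l - 1L), 0L), 20L)
    expo[, l] <- model$layers[[l]]$free_pool_exponent * m_layer[, l]
  }
  colnames(m_layer) <- colnames(expo) <-
    vapply(model$layers, `[[`, character(1), "name")

  out <- data.frame(
    index = idx,
    layer = vapply(model$layers, `[[`, character(1), "name")[layer_id],
    m_subunits = m_in_layer,
    n_contacts = n_contacts,
    ln_stat = ln_stat,
    cum_ln_k = cum_ln_k,
    stringsAsFactors = FALSE
  )
  attr(out, "m_layer") <- m_layer
  attr(out, "pool_exponents") <- expo
  attr(out, "model") <- model
  class(out) <- c("species_table", "data.frame")
  out
}

#' Write a species table to CSV
#'
#' @param table a [species_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_species_csv <- function(table, path) {
  stopifnot(inherits(table, "species_table"))
  utils::write.csv(as.data.frame(table)[, c("index", "layer", "m_subunits",
                                            "n_contacts", "ln_stat",
                                            "cum_ln_k")],
                   path, row.names = FALSE)
  invisible(path)
}
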