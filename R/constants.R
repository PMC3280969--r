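#' Physical constants and default rotavirus layer parameters
#'
#' @description
#' The package works throughout in cal, mol, K and molar units with the
#' ideal gas constant `R_CAL = 1.987` cal mol^-1 K^-1 and a 1 M
#' concentration reference state. Energies supplied in kcal/mol must be
#' multiplied by 1000 before being passed to low-level functions; the
#' model constructors accept either unit via an explicit `dg_unit`
#' argument.
#'
#' @name vlpthermo-constants
NULL

## ideal gas constant, cal mol^-1 K^-1
R_CAL <- 1.987

## protein molar masses, kDa
MASS_VP2 <- 102.7
MASS_VP6 <- 44.9
MASS_VP7 <- 37.2

## molecules per complete rotavirus-like particle
STOICH_VP2 <- 120
STOICH_VP6 <- 780
STOICH_VP7 <- 780

## log-concentration used as "zero" lower bracket (ln of ~1e-300 M)
LN_ZERO <- -690

.dg_to_cal <- function(dg, dg_unit = c("cal", "kcal")) {
  dg_unit <- match.arg(dg_unit)
  if (dg_unit == "kcal") dg * 1000 else dg
}

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log-scale values (`-Inf` allowed).
#' @return `log(sum(exp(x)))` computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
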