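#' Load a model specification from a JSON config file
#'
#' The config mirrors the model constructors: a `temperature_K` scalar
#' and a `layers` array whose entries carry `name`, `protein_mass_kDa`,
#' either `dg_cal` or `dg_kcal`, `s2`, `z`, `docked`, `conc0_M` and
#' optionally `free_pool_exponent` and `ln_stat_total`. The packaged
#' default config (`system.file("extdata", "rlp_model.json", package =
#' "vlpthermo")`) reproduces the triple-layered rotavirus model.
#'
#' @param path config file path.
#' @return a [vlp_model()].
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("cannot parse config ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.null(cfg$layers) || length(cfg$layers) == 0L) {
    stop("config error at 'layers': at least one layer required",
         call. = FALSE)
  }
  need <- function(block, field, i) {
    if (is.null(block[[field]])) {
      stop(sprintf("config error at layers[%d].%s: missing", i, field),
           call. = FALSE)
    }
    block[[field]]
  }
  layers <- vector("list", length(cfg$layers))
  conc0 <- numeric(length(cfg$layers))
  for (i in seq_along(cfg$layers)) {
    b <- cfg$layers[[i]]
    dg <- if (!is.null(b$dg_cal)) b$dg_cal
          else if (!is.null(b$dg_kcal)) b$dg_kcal * 1000
          else stop(sprintf("config error at layers[%d]: need dg_cal or dg_kcal", i),
                    call. = FALSE)
    docked <- isTRUE(need(b, "docked", i))
    args <- list(name = need(b, "name", i),
                 protein_mass = need(b, "protein_mass_kDa", i),
                 dg = dg, s2 = need(b, "s2", i), z = need(b, "z", i),
                 docked = docked)
    if (!is.null(b$free_pool_exponent)) {
      args$free_pool_exponent <- b$free_pool_exponent
    }
    if (!is.null(b$ln_stat_total)) args$ln_stat_total <- b$ln_stat_total
    layers[[i]] <- do.call(layer_spec, args)
    conc0[i] <- need(b, "conc0_M", i)
  }
  temperature <- if (is.null(cfg$temperature_K)) 298.15 else cfg$temperature_K
  vlp_model(layers, conc0, temperature)
}

#' Read an in vitro observation table
#'
#' Delimited text with header columns `label, kind, temperature_K,
#' dlp0_M, rlp0_M, vp7_0_M, efficiency, condition`. Efficiency cells may
#' carry detection bounds written as `<0.10` or `>0.90`; they are parsed
#' at their boundary value and flagged in the `bound` column. Empty
#' efficiency cells give `NA` rows (conditions reported without a
#' numeric estimate).
#'
#' The packaged fixture (`system.file("extdata", "invitro_assembly.csv",
#' package = "vlpthermo")`) transcribes the published in vitro
#' assembly/disassembly table.
#'
#' @param path CSV file path.
#' @return data frame with the columns above plus `bound`
#'   (`""`, `"<"` or `">"`).
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("observation file not found: ", path,
                               call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("label", "kind", "temperature_K", "dlp0_M", "rlp0_M",
            "vp7_0_M", "efficiency", "condition")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("observation table lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  eff_raw <- trimws(raw$efficiency)
  bound <- ifelse(grepl("^<", eff_raw), "<",
                  ifelse(grepl("^>", eff_raw), ">", ""))
  eff <- suppressWarnings(as.numeric(sub("^[<>]", "", eff_raw)))
  data.frame(
    label = raw$label,
    kind = raw$kind,
    temperature_K = as.numeric(raw$temperature_K),
    dlp0_M = suppressWarnings(as.numeric(raw$dlp0_M)),
    rlp0_M = suppressWarnings(as.numeric(raw$rlp0_M)),
    vp7_0_M = suppressWarnings(as.numeric(raw$vp7_0_M)),
    efficiency = eff,
    bound = bound,
    condition = raw$condition,
    stringsAsFactors = FALSE
  )
}

#' Write a solved state or estimate table to CSV or JSON
#'
#' Output is bit-stable for fixed inputs: keys are emitted in a fixed
#' order and floats at full double precision. `-Inf` log concentrations
#' serialize as the string sentinel `"-Inf"` in JSON and round-trip.
#'
#' @param x a `"vlp_equilibrium"` state or a data frame of estimates.
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(x, "vlp_equilibrium")) {
    tab <- data.frame(
      species = x$table$index,
      layer = x$table$layer,
      m_subunits = x$table$m_subunits,
      ln_conc = x$ln_species,
      conc_molar = exp(x$ln_species)
    )
    if (format == "csv") {
      utils::write.csv(tab, path, row.names = FALSE)
    } else {
      rep <- list(
        pools_ln_M = as.list(x$ln_free),
        efficiency_mass = x$efficiency_mass,
        residuals = as.list(x$residuals),
        species = tab
      )
      rep <- rapply(rep, function(v) {
        if (is.numeric(v)) ifelse(is.infinite(v) & v < 0, "-Inf", v) else v
      }, how = "replace")
      jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
  } else if (is.data.frame(x)) {
    if (format == "csv") {
      utils::write.csv(x, path, row.names = FALSE)
    } else {
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
  } else {
    stop("write_report handles vlp_equilibrium states and data frames",
         call. = FALSE)
  }
  invisible(path)
}
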