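## run code under a temporary RNG state so callers' streams are untouched
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration for synthetic in vitro observations
#'
#' Describes a simulated measurement campaign mirroring the in vitro
#' design (DLP at 10 pM, vp7 at 7.8 nM, stoichiometric): either a fixed
#' true per-subunit energy `dg_true`, or an enthalpy/entropy pair
#' (`dh_true`, `ds_true`) from which the true energy at each temperature
#' is `dH0 - T dS0`. Measured efficiencies get additive Gaussian noise
#' and are clipped into (1e-6, 1 - 1e-6); clipping is reported via an
#' attribute on the simulated table.
#'
#' @param seed integer seed; identical seeds give identical output.
#' @param n_replicates replicate measurements per temperature.
#' @param noise_sd standard deviation of the efficiency noise (fraction).
#' @param dg_true true per-subunit association energy, cal/mol (used
#'   when `dh_true`/`ds_true` are `NULL`).
#' @param dh_true,ds_true true standard enthalpy (cal/mol) and entropy
#'   (cal/mol/K) of the lumped layer reaction per subunit; both or
#'   neither.
#' @param temperatures K.
#' @param dlp0,vp7_0 initial concentrations, M.
#' @return an object of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1L, n_replicates = 1L, noise_sd = 0,
                         dg_true = -4830, dh_true = NULL, ds_true = NULL,
                         temperatures = 298.15,
                         dlp0 = 10e-12, vp7_0 = 7.8e-9) {
  stopifnot(noise_sd >= 0, n_replicates >= 1, length(temperatures) >= 1,
            all(temperatures > 0), dlp0 > 0, vp7_0 > 0)
  if (xor(is.null(dh_true), is.null(ds_true))) {
    stop("supply both dh_true and ds_true, or neither", call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, dg_true = dg_true,
                 dh_true = dh_true, ds_true = ds_true,
                 temperatures = temperatures, dlp0 = dlp0, vp7_0 = vp7_0),
            class = "synth_config")
}

.true_dg <- function(cfg, temperature) {
  if (!is.null(cfg$dh_true)) cfg$dh_true - temperature * cfg$ds_true
  else cfg$dg_true
}

#' Simulate noisy in vitro assembly observations
#'
#' For each configured temperature and replicate, computes the true
#' equilibrium assembly efficiency from the true energy via
#' [efficiency_from_dg()], adds Gaussian measurement noise and clips to
#' the open unit interval. Ground truth is carried in dedicated columns
#' for recovery scoring and is never consulted by the estimators.
#'
#' @param cfg a [synth_config()].
#' @return data frame with columns `label`, `kind`, `temperature_K`,
#'   `dlp0_M`, `rlp0_M`, `vp7_0_M`, `efficiency`, `condition`,
#'   `replicate`, `dg_true_cal`; attribute `n_clipped` counts clipped
#'   efficiencies.
#' @export
simulate_assembly_observations <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      temperature = cfg$temperatures)
  .with_seed(cfg$seed, {
    eff_true <- vapply(grid$temperature, function(tt) {
      as.numeric(efficiency_from_dg(.true_dg(cfg, tt), dlp0 = cfg$dlp0,
                                    vp7_0 = cfg$vp7_0, temperature = tt))
    }, numeric(1))
    eff <- eff_true + stats::rnorm(nrow(grid), sd = cfg$noise_sd)
    clipped <- eff <= 1e-6 | eff >= 1 - 1e-6
    eff <- pmin(pmax(eff, 1e-6), 1 - 1e-6)
    out <- data.frame(
      label = sprintf("sim_T%.2f_r%d", grid$temperature, grid$replicate),
      kind = "assembly",
      temperature_K = grid$temperature,
      dlp0_M = cfg$dlp0,
      rlp0_M = NA_real_,
      vp7_0_M = cfg$vp7_0,
      efficiency = eff,
      condition = "synthetic",
      replicate = grid$replicate,
      dg_true_cal = vapply(grid$temperature, .true_dg, numeric(1),
                           cfg = cfg),
      stringsAsFactors = FALSE
    )
    attr(out, "n_clipped") <- sum(clipped)
    out
  })
}

#' Simulate-and-estimate parameter-recovery experiment
#'
#' Runs `n_replicates` simulated campaigns and scores how well the
#' estimators recover the ground truth: per replicate the per-subunit
#' energy is estimated from each observation via [dg_from_assembly()]
#' (and averaged over temperatures), and in enthalpy/entropy mode a
#' [vant_hoff()] fit over the temperature series recovers dH0 and dS0.
#'
#' @param cfg a [synth_config()].
#' @return an object of class `"recovery_report"`: list with `dg`
#'   (`bias`, `rmse`, per-replicate estimates, truth) and, in
#'   enthalpy/entropy mode, `dh0` and `ds0` entries of the same shape
#'   plus 95% CI `coverage` where standard errors exist.
#' @export
recovery_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  vh_mode <- !is.null(cfg$dh_true) && length(cfg$temperatures) >= 2L
  reps <- seq_len(cfg$n_replicates)
  one_cfg <- cfg
  one_cfg$n_replicates <- 1L
  dg_hat <- numeric(length(reps))
  dh_hat <- ds_hat <- rep(NA_real_, length(reps))
  dh_cover <- ds_cover <- rep(NA, length(reps))
  for (r in reps) {
    one_cfg$seed <- cfg$seed + r - 1L
    sim <- simulate_assembly_observations(one_cfg)
    est <- vapply(seq_len(nrow(sim)), function(i) {
      obs <- invitro_obs(sim$label[i], "assembly", sim$temperature_K[i],
                         sim$efficiency[i], dlp0 = sim$dlp0_M[i],
                         vp7_0 = sim$vp7_0_M[i])
      dg_from_assembly(obs)$dg_subunit_cal
    }, numeric(1))
    dg_hat[r] <- mean(est)
    if (vh_mode) {
      lnk <- vapply(seq_len(nrow(sim)), function(i) {
        obs <- invitro_obs(sim$label[i], "assembly", sim$temperature_K[i],
                           sim$efficiency[i], dlp0 = sim$dlp0_M[i],
                           vp7_0 = sim$vp7_0_M[i])
        dg_from_assembly(obs)$ln_keq
      }, numeric(1))
      vh <- vant_hoff(sim$temperature_K, lnk)
      # back to the per-subunit scale of the ground truth:
      # ln K = -(50 dH)/RT + (50 dS/R + ln 2)
      dh_hat[r] <- vh$dh0 / 50
      ds_hat[r] <- (vh$ds0 - R_CAL * log(2)) / 50
      if (is.finite(vh$dh0_se)) {
        dh_cover[r] <- abs(dh_hat[r] - cfg$dh_true) <=
          1.96 * vh$dh0_se / 50
        ds_cover[r] <- abs(ds_hat[r] - cfg$ds_true) <=
          1.96 * vh$ds0_se / 50
      }
    }
  }
  score <- function(hat, truth) {
    err <- hat - truth
    list(truth = truth, estimates = hat, bias = mean(err),
         rmse = sqrt(mean(err^2)))
  }
  out <- list(
    dg = score(dg_hat, mean(vapply(cfg$temperatures, .true_dg,
                                   numeric(1), cfg = cfg))),
    n_replicates = cfg$n_replicates, noise_sd = cfg$noise_sd
  )
  if (vh_mode) {
    out$dh0 <- c(score(dh_hat, cfg$dh_true),
                 list(coverage = mean(dh_cover, na.rm = TRUE)))
    out$ds0 <- c(score(ds_hat, cfg$ds_true),
                 list(coverage = mean(ds_cover, na.rm = TRUE)))
  }
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "<recovery_report> %d replicate(s), noise sd %.3g\n  dG: truth %.1f, bias %.3g, RMSE %.3g cal/mol\n",
    x$n_replicates, x$noise_sd, x$dg$truth, x$dg$bias, x$dg$rmse))
  if (!is.null(x$dh0)) {
    cat(sprintf("  dH0: truth %.1f, bias %.3g, RMSE %.3g cal/mol\n",
                x$dh0$truth, x$dh0$bias, x$dh0$rmse))
    cat(sprintf("  dS0: truth %.3f, bias %.3g, RMSE %.3g cal/mol/K\n",
                x$ds0$truth, x$ds0$bias, x$ds0$rmse))
  }
  invisible(x)
}

#' Random model specification for solver property testing
#'
#' Draws a reproducible 1-3 layer model with association energies and
#' initial concentrations sampled uniformly (energies linear, total
#' concentrations log-uniform) from the given ranges.
#'
#' @param seed integer seed.
#' @param n_layers 1, 2 or 3.
#' @param dg_range energy range, kcal/mol.
#' @param conc_range total-protein concentration range, M (log-uniform).
#' @param temperature K.
#' @return a [vlp_model()].
#' @export
random_model_spec <- function(seed, n_layers = 3L,
                              dg_range = c(-5, -0.5),
                              conc_range = c(1e-5, 10),
                              temperature = 298.15) {
  stopifnot(n_layers %in% 1:3)
  .with_seed(seed, {
    dg <- stats::runif(3, dg_range[1], dg_range[2])
    conc <- exp(stats::runif(3, log(conc_range[1]), log(conc_range[2])))
    full <- rlp_model(dg_vp2 = dg[1], dg_vp6 = dg[2], dg_vp7 = dg[3],
                      conc0 = c(vp2 = conc[1], vp6 = conc[2],
                                vp7 = conc[3]),
                      temperature = temperature)
    vlp_model(full$layers[seq_len(n_layers)],
              full$conc0[seq_len(n_layers)], temperature)
  })
}
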