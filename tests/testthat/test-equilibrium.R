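test_that("law of mass action holds for every species", {
  tab <- species_table(rlp_model())
  ln_free <- log(c(1e-4, 2e-3, 5e-3))
  ln_sp <- species_ln_conc(tab, ln_free)
  expect_equal(ln_sp[1], ln_free[1])
  # dimer of the inner layer: ln[2] = cum_ln_k(2) + 2 ln[x]
  expect_equal(ln_sp[2], tab$cum_ln_k[2] + 2 * ln_free[1])
  # first docked species: 20 inner subunits + one 13-trimer subunit
  expect_equal(ln_sp[21], tab$cum_ln_k[21] + 20 * ln_free[1] +
                 13 * ln_free[2])
  # complete particle
  expect_equal(ln_sp[60], tab$cum_ln_k[60] + 20 * ln_free[1] +
                 260 * ln_free[2] + 260 * ln_free[3])
  expect_error(species_ln_conc(tab, ln_free[1:2]), "one entry per layer")
})

test_that("default model solves with tight mass conservation", {
  st <- solve_equilibrium(rlp_model())
  expect_s3_class(st, "vlp_equilibrium")
  expect_true(all(mass_balance_residual(rlp_model(), st) <= 1e-8))
  expect_gt(st$efficiency_mass, 0)
  expect_lt(st$efficiency_mass, 1)
})

test_that("solver matches an independent single-layer oracle", {
  # trace concentration: conservation solved from first principles with
  # plain uniroot on the polynomial total, no solver machinery shared
  m <- slp_model(dg = -4.38, conc0 = 1e-7)
  tab <- species_table(m)
  total <- function(x) {
    6 * sum((1:20) * exp(tab$cum_ln_k + (1:20) * log(x))) - 1e-7
  }
  x_oracle <- stats::uniroot(total, c(1e-30, 1e-7 / 6), tol = 1e-22)$root
  st <- solve_equilibrium(m)
  expect_equal(exp(st$ln_free[[1]]), x_oracle, tolerance = 1e-7)
  expect_equal(st$ln_species,
               tab$cum_ln_k + (1:20) * log(x_oracle), tolerance = 1e-7)
})

test_that("solver result is independent of the warm start", {
  m <- rlp_model(-4.08, -4.08, -1)
  cold <- solve_equilibrium(m)
  other <- solve_equilibrium(rlp_model(-3, -3, -3))
  warm <- solve_equilibrium(m, init = other)
  expect_equal(warm$ln_free, cold$ln_free, tolerance = 1e-9)
  warm2 <- solve_equilibrium(m, init = c(-20, -20, -20))
  expect_equal(warm2$ln_free, cold$ln_free, tolerance = 1e-9)
})

test_that("fuzzed models conserve mass and stay in bounds", {
  for (seed in 1:8) {
    n_layers <- 1L + (seed %% 3L)
    m <- random_model_spec(seed, n_layers = n_layers)
    st <- solve_equilibrium(m)
    expect_true(all(mass_balance_residual(m, st) <= 1e-8),
                label = sprintf("seed %d conservation", seed))
    expect_gte(st$efficiency_mass, 0)
    expect_lte(st$efficiency_mass, 1)
    if (n_layers == 3L) {
      ub <- irreversible_efficiency(m$conc0[1], m$conc0[2], m$conc0[3])
      expect_lte(st$efficiency_mass, ub + 1e-12)
    }
  }
})

test_that("efficiency is monotone in each layer's association energy", {
  base <- c(-3.5, -3.5, -3.5)
  eff <- function(dg) {
    solve_equilibrium(rlp_model(dg[1], dg[2], dg[3]))$efficiency_mass
  }
  e0 <- eff(base)
  for (l in 1:3) {
    stronger <- base
    stronger[l] <- -4.5
    expect_gt(eff(stronger), e0)
    weaker <- base
    weaker[l] <- -2.5
    expect_lt(eff(weaker), e0)
  }
})

test_that("zero-concentration layers short-circuit correctly", {
  # no outer-layer protein: no complete particles, vp6 still docks
  m <- rlp_model(conc0 = c(vp2 = 1.2, vp6 = 7.8, vp7 = 0))
  st <- solve_equilibrium(m)
  expect_identical(st$ln_free[["vp7"]], -Inf)
  expect_true(all(st$conc[41:60] == 0))
  expect_gt(st$conc[40], 0)  # double-layered particles form
  expect_equal(st$efficiency_mass, 0)

  # no middle-layer protein: outer layer has nothing to dock onto and
  # keeps all of its protein as free trimer
  m2 <- rlp_model(conc0 = c(vp2 = 1.2, vp6 = 0, vp7 = 7.8))
  st2 <- solve_equilibrium(m2)
  expect_identical(st2$ln_free[["vp6"]], -Inf)
  expect_equal(exp(st2$ln_free[["vp6"]]), 0)
  expect_equal(exp(st2$ln_free[["vp7"]]), 7.8 / 3)
  expect_true(all(st2$conc[21:60] == 0))
  expect_gt(st2$conc[20], 0)  # the inner layer still assembles

  # nothing at all
  m3 <- rlp_model(conc0 = c(vp2 = 0, vp6 = 0, vp7 = 0))
  st3 <- solve_equilibrium(m3)
  expect_true(all(st3$conc == 0))
  expect_true(is.na(st3$efficiency_mass))
  expect_error(efficiency_mass(m3, st3), "no initial protein")
})

test_that("mass-balance residual flags inconsistent states", {
  m <- rlp_model()
  st <- solve_equilibrium(m)
  broken <- st
  broken$ln_free <- st$ln_free + c(1, 0, 0)
  expect_gt(mass_balance_residual(m, broken)[["vp2"]], 1e-3)
})

test_that("invalid solver inputs raise descriptive errors", {
  m <- rlp_model()
  m$conc0[1] <- -1
  expect_error(solve_equilibrium(m), "finite and >= 0")
  m$conc0[1] <- NaN
  expect_error(solve_equilibrium(m), "finite and >= 0")
})

test_that("equilibrium methods report the solved state", {
  st <- solve_equilibrium(rlp_model(dg_vp7 = -1))
  expect_identical(residuals(st), st$residuals)
  sm <- summary(st)
  expect_s3_class(sm, "summary.vlp_equilibrium")
  expect_equal(sm$efficiency_mass, st$efficiency_mass)
  expect_true(all(sm$dominant_species$conc_M > 0))
  expect_output(print(st), "mass assembly efficiency")
  expect_output(print(sm), "Dominant species")
})
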