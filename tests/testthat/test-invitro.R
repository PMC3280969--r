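std_obs <- invitro_obs("standard", "assembly", 298.15, 0.48,
                       dlp0 = 10e-12, vp7_0 = 7.8e-9)

test_that("assembly efficiency from particle concentrations", {
  expect_equal(assembly_efficiency(10e-12, 5.2e-12), 0.48)
  expect_equal(disassembly_efficiency(1e-9, 1e-9), 0)
  expect_equal(assembly_efficiency(1e-9, 0), 1)
  expect_error(assembly_efficiency(0, 0), "> 0")
  expect_error(assembly_efficiency(1e-9, 2e-9), "\\[0, p0\\]")
})

test_that("standard-condition estimate reproduces the published values", {
  est <- dg_from_assembly(std_obs)
  # per-subunit and whole-layer energies to 4 significant figures
  expect_equal(est$dg_subunit_cal, -4830.157, tolerance = 1e-6)
  expect_equal(est$dg_layer_kcal, -241.9185, tolerance = 1e-6)
  expect_equal(est$ln_keq, 408.3536, tolerance = 1e-6)
})

test_that("detection-boundary estimates at both temperatures", {
  b298 <- dg_from_assembly(invitro_obs("b298", "assembly", 298.15, 0.10,
                                       dlp0 = 10e-12, vp7_0 = 7.8e-9))
  expect_equal(b298$dg_subunit_cal, -4675.078, tolerance = 1e-6)
  b308 <- dg_from_assembly(invitro_obs("b308", "assembly", 308.15, 0.10,
                                       dlp0 = 10e-12, vp7_0 = 7.8e-9))
  expect_equal(b308$dg_subunit_cal, -4831.881, tolerance = 1e-6)
})

test_that("layer and per-subunit energies are consistent", {
  est <- dg_from_assembly(std_obs)
  # layer energy ~ 50 contacts x per-subunit energy, up to the ln 2 factor
  expect_equal(1000 * est$dg_layer_kcal / est$dg_subunit_cal, 50,
               tolerance = 2e-3)
  expect_named(coef(est), c("ln_keq", "dg_layer_kcal", "dg_subunit_cal"))
})

test_that("estimator is strictly decreasing in efficiency", {
  effs <- c(0.2, 0.4, 0.6, 0.8)
  dgs <- vapply(effs, function(e) {
    dg_from_assembly(invitro_obs("x", "assembly", 298.15, e,
                                 dlp0 = 10e-12, vp7_0 = 7.8e-9))$dg_subunit_cal
  }, numeric(1))
  expect_true(all(diff(dgs) < 0))
})

test_that("efficiency_from_dg inverts the estimator", {
  for (eff in c(0.05, 0.48, 0.9)) {
    obs <- invitro_obs("x", "assembly", 298.15, eff,
                       dlp0 = 10e-12, vp7_0 = 7.8e-9)
    dg <- dg_from_assembly(obs)$dg_subunit_cal
    back <- efficiency_from_dg(dg)
    expect_equal(as.numeric(back), eff, tolerance = 1e-6)
  }
  # far outside the feasible range: boundary flagged
  lo <- efficiency_from_dg(-1000)
  expect_true(attr(lo, "boundary"))
  expect_lt(as.numeric(lo), 1e-6)
  hi <- efficiency_from_dg(-20000)
  expect_true(attr(hi, "boundary"))
})

test_that("observation constructor and estimator validate inputs", {
  expect_error(invitro_obs("x", "assembly", 298.15, 0), "strictly")
  expect_error(invitro_obs("x", "assembly", 298.15, 1), "strictly")
  expect_error(invitro_obs("x", "assembly", -1, 0.5), "temperature")
  expect_error(invitro_obs("x", "wrong", 298.15, 0.5))
  dis <- invitro_obs("x", "disassembly", 298.15, 0.5, rlp0 = 1e-9)
  expect_error(dg_from_assembly(dis), "assembly")
  # all vp7 consumed: infeasible
  bad <- invitro_obs("x", "assembly", 298.15, 0.99,
                     dlp0 = 1e-11, vp7_0 = 7e-9)
  expect_error(dg_from_assembly(bad), "infeasible")
})

test_that("van't Hoff fit recovers exact enthalpy and entropy", {
  tt <- c(288.15, 298.15, 308.15)
  lnk <- (30000 / 1.987) / tt + (-85 / 1.987)  # dH0 = -30 kcal, dS0 = -85
  vh <- vant_hoff(tt, lnk)
  expect_equal(vh$dh0, -30000, tolerance = 1e-8)
  expect_equal(vh$ds0, -85, tolerance = 1e-8)
  expect_lt(vh$dh0_se, 1e-4)
  expect_named(coef(vh), c("dh0", "ds0"))
  expect_output(print(vh), "dH0")
  expect_output(print(summary(vh)), "dS0")
})

test_that("two-point van't Hoff gives consistent layer thermodynamics", {
  # efficiency drops from 0.48 at 298 K to 0.10 at 308 K: strongly
  # exothermic layer assembly
  e298 <- dg_from_assembly(std_obs)
  e308 <- dg_from_assembly(invitro_obs("hot", "assembly", 308.15, 0.10,
                                       dlp0 = 10e-12, vp7_0 = 7.8e-9))
  vh <- vant_hoff(c(298.15, 308.15), c(e298$ln_keq, e308$ln_keq))
  expect_lt(vh$dh0, -2e5)
  # thermodynamic identity at the fit points: dG = dH - T dS
  dg_fit <- vh$dh0 - 298.15 * vh$ds0
  expect_equal(dg_fit, 1000 * e298$dg_layer_kcal, tolerance = 1e-6)
  expect_true(is.na(vh$dh0_se))  # no residual degrees of freedom
  expect_error(vant_hoff(c(298.15, 298.15), c(1, 2)), "distinct")
})

test_that("packaged observation table estimates end to end", {
  path <- system.file("extdata", "invitro_assembly.csv",
                      package = "vlpthermo")
  obs <- read_observations(path)
  est <- estimate_observations(obs)
  expect_identical(est$label, c("standard", "high_pH", "high_T"))
  expect_equal(est$dg_subunit_cal[est$label == "standard"], -4830.157,
               tolerance = 1e-6)
  expect_equal(est$dg_subunit_cal[est$label == "high_pH"], -4675.078,
               tolerance = 1e-6)
  expect_equal(est$dg_subunit_cal[est$label == "high_T"], -4831.881,
               tolerance = 1e-6)
})
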