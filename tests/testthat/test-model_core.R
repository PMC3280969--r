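test_that("free-standing contact schedule covers the icosahedral shell", {
  sched <- contact_schedule(docked = FALSE)
  expect_length(sched, 20L)
  expect_identical(sched[1], 0L)
  expect_true(all(sched[-1] >= 1L))
  expect_true(all(sched <= 3L))
  # the last subunit closes the shell against three neighbours
  expect_identical(sched[20], 3L)
  # 30 icosahedron edges, each counted once
  expect_identical(sum(sched), 30L)
})

test_that("docked contact schedule adds one template contact per subunit", {
  free <- contact_schedule(docked = FALSE)
  dock <- contact_schedule(docked = TRUE)
  expect_identical(dock, free + 1L)
  expect_identical(sum(dock), 50L)
})

test_that("icosahedron face-adjacency graph is 3-regular on 20 faces", {
  adj <- vlpthermo:::icosahedron_adjacency()
  expect_identical(dim(adj), c(20L, 20L))
  expect_true(all(rowSums(adj) == 3))
  expect_true(isTRUE(all.equal(adj, t(adj))))
  expect_true(all(diag(adj) == 0))
})

test_that("single-contact association constant matches its definition", {
  expect_equal(ln_k_contact(-4080, 1, 298.15), 4080 / (1.987 * 298.15))
  expect_equal(ln_k_contact(-4080, 0, 298.15), 0)
  expect_equal(ln_k_contact(-1000, 3, 310), 3000 / (1.987 * 310))
  # favourable (negative) energies give K > 1
  expect_gt(ln_k_contact(-1, 1, 298.15), 0)
  expect_error(ln_k_contact(-4080, 1, 0), "temperature")
  expect_error(ln_k_contact(-4080, -1, 298.15))
})

test_that("species table enumerates the 60-species ladder", {
  tab <- species_table(rlp_model())
  expect_s3_class(tab, "species_table")
  expect_identical(nrow(tab), 60L)
  expect_identical(tab$index, 1:60)
  expect_identical(tab$layer, rep(c("vp2", "vp6", "vp7"), each = 20L))
  expect_identical(tab$m_subunits, rep(1:20, 3L))
  # species 1 is the 1 M reference
  expect_identical(tab$cum_ln_k[1], 0)
  expect_identical(tab$ln_stat[1], 0)
})

test_that("cumulative association constants are additive over steps", {
  tab <- species_table(rlp_model())
  steps <- tab$ln_stat + ln_k_contact(
    rep(c(-4080, -4080, -4080), each = 20L), tab$n_contacts, 298.15)
  steps[1] <- 0
  expect_equal(tab$cum_ln_k, cumsum(steps))
})

test_that("complete single layer carries the layer total constant", {
  m <- slp_model(dg = -4.08)
  tab <- species_table(m)
  expect_equal(ln_k_layer(tab),
               vlp_ln_stat_vp2() + 30 * 4080 / (1.987 * 298.15))
  expect_error(ln_k_layer(species_table(rlp_model())), "single-layer")
})

test_that("stronger association raises every cumulative constant", {
  weak <- species_table(rlp_model(-3, -3, -3))
  strong <- species_table(rlp_model(-4, -4, -4))
  expect_true(all(strong$cum_ln_k[-1] > weak$cum_ln_k[-1]))
})

test_that("per-step statistical overrides are validated and honoured", {
  m <- rlp_model()
  tab <- species_table(m)
  expect_error(species_table(m, ln_stat_overrides = rep(0, 10)),
               "length 60")
  bad <- tab$ln_stat
  bad[1] <- 1
  expect_error(species_table(m, ln_stat_overrides = bad), "species-1")
  # overriding with the defaults reproduces the table exactly
  same <- species_table(m, ln_stat_overrides = tab$ln_stat)
  expect_equal(same$cum_ln_k, tab$cum_ln_k)
  # moving weight between steps of a layer keeps the layer ends fixed
  shift <- tab$ln_stat
  shift[5] <- shift[5] + 1
  shift[6] <- shift[6] - 1
  shifted <- species_table(m, ln_stat_overrides = shift)
  expect_equal(shifted$cum_ln_k[c(20, 40, 60)], tab$cum_ln_k[c(20, 40, 60)])
  expect_false(isTRUE(all.equal(shifted$cum_ln_k[5], tab$cum_ln_k[5])))
})

test_that("layer and model constructors validate their inputs", {
  expect_error(layer_spec("x", 50, -4000, n_subunits = 12L),
               "20-subunit")
  expect_error(layer_spec("x", 50, -4000, s2 = 13, z = 3,
                          free_pool_exponent = 5L), "divide")
  expect_error(layer_spec("x", -1, -4000))
  v2 <- layer_spec("vp2", 102.7, -4.08, s2 = 3, z = 2, docked = FALSE,
                   dg_unit = "kcal")
  v6 <- layer_spec("vp6", 44.9, -4.08, dg_unit = "kcal")
  expect_equal(v2$dg, -4080)  # kcal input, canonical cal storage
  expect_equal(v2$proteins_per_subunit, 6)
  expect_equal(v6$proteins_per_subunit, 39)
  expect_equal(v6$pool_proteins, 3)  # trimer pool
  expect_error(vlp_model(list(v6), 1), "free-standing")
  expect_error(vlp_model(list(v2, v2), c(1, 1)), "docked")
  expect_error(vlp_model(list(v2), 1, temperature = -5), "temperature")
  expect_error(vlp_model(list(v2), c(1, 2)))
})

test_that("the default model matches the published composition", {
  m <- rlp_model()
  pps <- vapply(m$layers, `[[`, numeric(1), "proteins_per_subunit")
  expect_equal(20 * pps, c(120, 780, 780))  # particle stoichiometry
  expect_equal(vapply(m$layers, `[[`, numeric(1), "protein_mass"),
               c(102.7, 44.9, 37.2))
  expect_equal(unname(m$conc0), c(1.2, 7.8, 7.8))
  expect_equal(m$temperature, 298.15)
})
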