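test_that("default world is fully parameterized and internally consistent", {
  w <- default_world()
  expect_equal(nrow(w$compartments), 20)  # 4 regions x 5 media
  expect_silent(validate_world(w))
  # closed atmospheric circulation: flow out of ARC equals flow into ARC
  air <- dplyr::filter(w$flows, medium == "air")
  expect_equal(sum(air$flow_m3_h[air$from == "ARC"]),
               sum(air$flow_m3_h[air$to == "ARC"]))
  expect_error(default_world(7), "4-region")
})

test_that("climate scenario application is exact, local and composable", {
  w <- default_world()
  null <- tibble::tibble(region = c("ARC", "NEU", "SAF", "ROW"),
                         dT = 0, dPrecip = 0)
  expect_equal(apply_climate_scenario(w, null)$compartments, w$compartments)

  arc5 <- apply_climate_scenario(
    w, tibble::tibble(region = "ARC", dT = 5, dPrecip = 0))
  delta <- arc5$compartments$temp_K - w$compartments$temp_K
  expect_equal(delta[w$compartments$region == "ARC"], rep(5, 5))
  expect_equal(delta[w$compartments$region != "ARC"], rep(0, 15))

  wet <- apply_climate_scenario(
    w, tibble::tibble(region = "NEU", dT = 0, dPrecip = 0.20))
  i <- w$compartments$region == "NEU" & w$compartments$medium == "air"
  expect_equal(wet$compartments$rain_m_h[i], w$compartments$rain_m_h[i] * 1.2)

  # dT composes additively
  two_step <- apply_climate_scenario(
    apply_climate_scenario(w, tibble::tibble(region = "SAF", dT = 1, dPrecip = 0)),
    tibble::tibble(region = "SAF", dT = 2.5, dPrecip = 0))
  one_step <- apply_climate_scenario(
    w, tibble::tibble(region = "SAF", dT = 3.5, dPrecip = 0))
  expect_equal(two_step$compartments, one_step$compartments)

  expect_error(apply_climate_scenario(
    w, tibble::tibble(region = "XXX", dT = 1, dPrecip = 0)), "Unknown region")
  expect_error(apply_climate_scenario(
    w, tibble::tibble(region = "ARC", dT = 1, dPrecip = -1.5)), "dPrecip")
})

test_that("emission maps follow the low-Arctic-source pattern", {
  w <- default_world()
  em <- build_emission_map(w)
  expect_equal(nrow(em), 4)
  expect_true(all(em$emission_mol_h > 0))
  expect_equal(em$emission_mol_h[em$region == "ARC"],
               0.001 * em$emission_mol_h[em$region == "NEU"])
  custom <- build_emission_map(
    w, "custom", tibble::tibble(region = "NEU", medium = "air",
                                emission_mol_h = 10))
  expect_equal(nrow(custom), 1)
  expect_error(build_emission_map(
    w, "custom", tibble::tibble(region = "NEU", medium = "air",
                                emission_mol_h = 0)), "emission rate")
})

test_that("emission-temperature scaling matches convention and frozen value", {
  expect_equal(scale_emission_with_temperature(100, 0, 330), 100)
  expect_equal(scale_emission_with_temperature(100, -80, 298.15), 100)
  # frozen from independent evaluation at dU_A = -80, 298.15 -> 303.15 K:
  # warming increases passive volatilization with the condensation convention
  expect_equal(scale_emission_with_temperature(100, -80, 303.15), 170.29,
               tolerance = 1e-4)
  expect_error(scale_emission_with_temperature(-1, -80, 303.15), "E_ref")
})

test_that("steady-state outputs are linear in emissions", {
  w <- default_world()
  chem <- pcb153()
  res1 <- solve_steady_state(build_fate_system(chem, w, build_emission_map(w)))
  res2 <- solve_steady_state(build_fate_system(
    chem, w, build_emission_map(w, base_rate = 2000)))
  expect_equal(res2$conc_bulk_mol_m3, 2 * res1$conc_bulk_mol_m3)
})

test_that("worlds serialize losslessly through YAML", {
  w <- default_world()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_world(w, path)
  w2 <- read_world(path)
  expect_equal(w2$compartments, w$compartments)
  expect_equal(w2$flows, w$flows)
  expect_equal(w2$transfer, w$transfer)
  expect_gt(nrow(world_parameter_table(w)), 200)
})
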