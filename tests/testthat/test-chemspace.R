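test_that("null climate scenario yields unit ratio maps", {
  w <- default_world()
  null <- tibble::tibble(region = unique(w$compartments$region),
                         dT = 0, dPrecip = 0)
  map <- run_chemspace(small_grid(), w, null)
  expect_true(all(abs(map$ratio - 1) < 1e-12))
})

test_that("ratio maps are invariant to emission magnitude", {
  w <- default_world()
  m1 <- run_chemspace(small_grid(), w, emissions = build_emission_map(w))
  m10 <- run_chemspace(small_grid(), w,
                       emissions = build_emission_map(w, base_rate = 1e4))
  expect_equal(m10$ratio, m1$ratio, tolerance = 1e-12)
})

test_that("swapping baseline and perturbed worlds inverts every ratio", {
  w <- default_world()
  deltas <- default_climate_deltas()
  fwd <- run_chemspace(small_grid(), w, deltas)
  w_gcc <- apply_climate_scenario(w, deltas)
  undo <- deltas |>
    dplyr::mutate(dT = -dT, dPrecip = 1 / (1 + dPrecip) - 1)
  rev <- run_chemspace(small_grid(), w_gcc, undo)
  expect_equal(rev$ratio, 1 / fwd$ratio, tolerance = 1e-9)
})

test_that("ratio-map summaries equal a naive recomputation", {
  set.seed(11)
  map <- tidyr::expand_grid(logKOA = seq(5, 7), logKAW = c(-3, -1),
                            region = c("ARC", "NEU"), output = c("air", "soil")) |>
    dplyr::mutate(baseline = runif(dplyr::n()),
                  perturbed = baseline * exp(stats::rnorm(dplyr::n(), 0, 0.3)),
                  ratio = perturbed / baseline)
  s <- summarize_ratios(map)
  overall <- s[s$region == "all", ]
  expect_equal(overall$max_fold, max(pmax(map$ratio, 1 / map$ratio)))
  expect_equal(overall$median_abs_dev_pct, 100 * median(abs(map$ratio - 1)))
  expect_equal(overall$frac_within_20pct, mean(abs(map$ratio - 1) <= 0.2))
  # one synthetic halved cell gives fold-change 2
  m2 <- map
  m2$ratio[1] <- 0.5
  expect_equal(summarize_ratios(m2)[summarize_ratios(m2)$region == "all", ]$max_fold, 2)
})

test_that("grid refinement barely moves the overall maximum fold-change", {
  coarse <- run_chemspace(chemspace_grid(step = 2))
  fine <- run_chemspace(chemspace_grid(step = 1))
  fold <- function(m) max(pmax(m$ratio, 1 / m$ratio))
  expect_lt(abs(fold(fine) - fold(coarse)) / fold(coarse), 0.05)
})

test_that("reference-chemical run reproduces the scenario directions", {
  null <- tibble::tibble(region = c("ARC", "NEU", "SAF", "ROW"),
                         dT = 0, dPrecip = 0)
  r0 <- run_reference_chemical(deltas = null)
  expect_true(all(abs(r0$ratio - 1) < 1e-12))

  ref <- run_reference_chemical()
  air <- ref[ref$metric == "air_conc", ]
  expect_true(all(air$ratio > 1))                       # atmosphere elevated
  expect_lt(ref$ratio[ref$metric == "inventory"], 1)    # global burden reduced
  expect_lt(ref$ratio[ref$metric == "P_OV"], 1)         # persistence reduced

  # a temperature-responsive source (negative dU_A) raises air further
  scaled <- run_reference_chemical(emission_scaling = TRUE)
  expect_true(all(scaled$ratio[scaled$metric == "air_conc"] > air$ratio))
})

test_that("uncertainty screen is seeded, reproducible and guarded", {
  a <- uncertainty_screen(pcb153(), n = 100, seed = 5,
                          output = "arc_air_baseline")
  b <- uncertainty_screen(pcb153(), n = 100, seed = 5,
                          output = "arc_air_baseline")
  expect_equal(a, b)
  expect_true(all(a$variance >= 0))
  expect_true(all(is.finite(a$share)))
  expect_error(uncertainty_screen(pcb153(), n = 10), "n")
  expect_error(
    uncertainty_screen(pcb153(), property_sd = c(logK = 0, log10_hl = 0),
                       dT_range = c(2, 2), dPrecip_range = c(0, 0), n = 100),
    "Degenerate")
})
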