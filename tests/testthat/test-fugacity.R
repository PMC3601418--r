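test_that("Z-values reproduce closed forms", {
  comp_air <- default_world()$compartments |>
    dplyr::filter(region == "NEU", medium == "air")
  chem <- chemical("unit", logKAW = 0, logKOA = 5, dU_OW = -20, dU_OA = -20)
  z <- compute_z_values(chem, comp_air, T_K = 298.15)
  expect_equal(z$Z_air, 1 / (8.314 * 298.15))        # 4.0342e-4 mol m^-3 Pa^-1
  expect_equal(z$Z_water, z$Z_air)                   # K_AW = 1: equipartition
  # bulk Z of water with zero POC equals the pure water Z
  comp_fw <- default_world()$compartments |>
    dplyr::filter(region == "NEU", medium == "freshwater") |>
    dplyr::mutate(frac_poc = 0)
  zf <- compute_z_values(pcb153(), comp_fw, T_K = 283)
  expect_equal(zf$Z_bulk, zf$Z_water)
})

test_that("one-box steady state matches f = E/D", {
  sys <- one_box_system(D_deg = 2, E = 10)
  res <- solve_steady_state(sys)
  expect_equal(res$fugacity_Pa, 10 / 2)
  expect_equal(res$mass_mol, 5 * 4e-4 * 1e6)
  # no emissions, no chemical anywhere
  res0 <- solve_steady_state(one_box_system(E = 0))
  expect_equal(res0$fugacity_Pa, 0)
  expect_equal(attr(res0, "inventory_mol"), 0)
})

test_that("solver equals brute-force inversion for random small systems", {
  # independent oracle: assemble the 2x2 / 3x3 balance by hand and invert
  for (seed in 1:6) {
    for (n in 2:3) {
      sys <- random_system(n, seed = seed * 100 + n)
      res <- solve_steady_state(sys)
      f_oracle <- solve(sys$A) %*% sys$emissions
      expect_equal(res$fugacity_Pa, as.vector(f_oracle))
      # conservation: emissions equal degradation + boundary removal
      lost <- sum(sys$D_deg * res$fugacity_Pa) +
        sum(sys$D_removal * res$fugacity_Pa)
      expect_equal(lost, sum(sys$emissions), tolerance = 1e-12)
    }
  }
})

test_that("two-box analytic inverse is reproduced exactly", {
  sys <- random_system(2, seed = 42)
  a <- sys$A
  det <- a[1, 1] * a[2, 2] - a[1, 2] * a[2, 1]
  f1 <- (a[2, 2] * sys$emissions[1] - a[1, 2] * sys$emissions[2]) / det
  f2 <- (a[1, 1] * sys$emissions[2] - a[2, 1] * sys$emissions[1]) / det
  res <- solve_steady_state(sys)
  expect_equal(res$fugacity_Pa, c(f1, f2))
})

test_that("mass balance closes for the full default world", {
  w <- default_world()
  res <- solve_steady_state(build_fate_system(pcb153(), w, build_emission_map(w)))
  budget <- attr(res, "loss_budget")
  expect_equal(sum(budget), sum(build_emission_map(w)$emission_mol_h),
               tolerance = 1e-9)
  expect_true(all(res$fugacity_Pa > 0))
})

test_that("overall persistence increases with every half-life", {
  w <- default_world()
  em <- build_emission_map(w)
  chem <- chemical("base", logKAW = -2, logKOA = 9)
  longer <- chem
  for (col in c("hl_air_h", "hl_water_h", "hl_soil_h", "hl_sed_h")) {
    longer[[col]] <- 2 * longer[[col]]
  }
  pov <- function(c) attr(solve_steady_state(build_fate_system(c, w, em)), "P_OV_h")
  expect_gt(pov(longer), pov(chem))
})

test_that("dynamic integration converges to the steady state", {
  sys <- random_system(3, seed = 7)
  res <- solve_steady_state(sys)
  rates <- diag(sys$A) / (sys$volumes * sys$Z_bulk)
  # step resolves the fastest compartment, horizon outlasts the slowest
  traj <- dynamic_solve(sys, horizon_h = 30 / min(rates),
                        step_h = 0.2 / max(rates))
  final <- as.numeric(traj[nrow(traj), -1])
  expect_equal(final, res$mass_mol, tolerance = 1e-3)
  expect_true(all(as.matrix(traj[, -1]) >= 0))
  # decay run: no emissions, positive start, monotone decline to zero
  sys0 <- sys
  sys0$emissions <- rep(0, 3)
  dec <- dynamic_solve(sys0, horizon_h = 30 / min(rates),
                       step_h = 0.2 / max(rates), M0 = res$mass_mol)
  expect_true(all(diff(dec[[2]]) <= 1e-12))
  expect_lt(dec[[2]][nrow(dec)], 1e-6 * res$mass_mol[1])
  expect_error(dynamic_solve(sys, horizon_h = 10 / min(rates),
                             step_h = 10 / max(rates) + 1e6), "too large")
})
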