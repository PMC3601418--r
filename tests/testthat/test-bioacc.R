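test_that("seasonal temperature cycle has the documented structure", {
  expect_equal(annual_temperature(1:10, mean = 8, amplitude = 0, offset = 2),
               rep(10, 10))
  base <- annual_temperature(1:365)
  shifted <- annual_temperature(1:365, offset = 3)
  expect_equal(shifted - base, rep(3, 365))
  # the sinusoid integrates to zero over a full year
  expect_equal(mean(base), 12, tolerance = 1e-9)
  expect_equal(which.max(base), 213, tolerance = 1)  # peak in early August
})

test_that("thermal performance hits its landmarks", {
  tr <- thermal_traits()
  expect_equal(thermal_performance(tr$T_opt, tr), 1.0)
  expect_equal(thermal_performance(c(tr$CT_max, tr$CT_max + 2), tr), c(0, 0))
  expect_equal(thermal_performance(c(tr$CT_min, tr$CT_min - 5), tr), c(0, 0))
  # consumption rises monotonically below the optimum
  sub <- thermal_performance(seq(1, tr$T_opt, by = 1), tr)
  expect_true(all(diff(sub) > 0))
  # respiration follows Q10 exactly and is not capped at CT_max
  expect_equal(thermal_performance(tr$T_ref_b + 10, tr, "respiration"), tr$Q10)
  expect_gt(thermal_performance(tr$CT_max + 5, tr, "respiration"), 1)
})

test_that("growth responds to temperature as the energy budget dictates", {
  # no feeding below CT_min: weight can only shrink (down to the floor)
  cold <- simulate_growth(rep(-5, 400), W0 = 1)
  expect_true(all(diff(cold$weight_g) <= 0))
  expect_true(all(cold$weight_g > 0))

  # a year at the optimum beats a year five degrees colder
  opt <- simulate_growth(rep(26, 366))
  cooler <- simulate_growth(rep(21, 366))
  expect_gt(dplyr::last(opt$weight_g), dplyr::last(cooler$weight_g))

  # scenario ordering: +2 boosts growth; +3 falls back below +2
  days <- 0:(5 * 365)
  final_w <- sapply(c(0, 2, 3), function(off) {
    dplyr::last(simulate_growth(annual_temperature(days, offset = off))$weight_g)
  })
  expect_gt(final_w[2], final_w[1])
  expect_lt(final_w[3], final_w[2])
})

test_that("rate constants follow their definitions", {
  ks <- rate_constants(W = 10, T_C = 20, logKOW = 6, HL_B_d = 0.1)
  expect_equal(ks$kM, log(2) / 0.1)
  # no feeding, no dietary uptake
  ks_cold <- rate_constants(W = 10, T_C = -3, logKOW = 6, HL_B_d = 1)
  expect_equal(ks_cold$kD, 0)
  # elimination falls as hydrophobicity rises
  k2s <- sapply(4:8, function(lk)
    rate_constants(W = 10, T_C = 20, logKOW = lk, HL_B_d = 1)$k2)
  expect_true(all(diff(k2s) < 0))
})

test_that("constant-environment simulation matches the algebraic steady state", {
  nd <- 2000
  tr <- thermal_traits()
  pr <- bioenergetic_params()
  cons <- pr$CA * 10^pr$CB * pr$p * thermal_performance(20, tr)
  growth <- tibble::tibble(
    day = 0:nd, temp_C = 20, weight_g = 10, cons_spec = cons,
    growth_g_d = 0, kG = 0)
  chem <- fish_chemical(logKOW = 6, HL_B_d = 10)
  traj <- simulate_bioaccumulation(chem, growth = growth)
  ks <- rate_constants(10, 20, 6, 10, tr, pr, cons_spec = cons)
  C_star <- (ks$k1 * chem$C_wd + ks$kD * chem$C_diet) / (ks$k2 + ks$kE + ks$kM)
  expect_equal(dplyr::last(traj$conc_mol_g), C_star, tolerance = 1e-3)
})

test_that("bioaccumulation trajectories behave in their limits", {
  chem0 <- fish_chemical(logKOW = 6, HL_B_d = 10, C_wd = 0, C_diet = 0)
  traj0 <- simulate_bioaccumulation(chem0, years = 1)
  expect_true(all(traj0$conc_mol_g == 0))
  expect_equal(nrow(simulate_bioaccumulation(fish_chemical(6, 1))), 5 * 365 + 1)

  # near-instant biotransformation wipes out the body burden
  y3 <- function(traj) mean(traj$conc_mol_g[traj$day >= 731 & traj$day <= 1095])
  fast <- simulate_bioaccumulation(fish_chemical(7, 0.001))
  slow <- simulate_bioaccumulation(fish_chemical(7, 1000))
  expect_lt(y3(fast), 1e-4 * y3(slow))

  # longer biotransformation half-life never lowers the year-3 burden
  burdens <- sapply(c(0.1, 1, 10, 100, 1000), function(hl)
    y3(simulate_bioaccumulation(fish_chemical(6, hl))))
  expect_true(all(diff(burdens) > 0))
})

test_that("zero warming offset gives unit concentration ratios", {
  scan <- ratio_scan(logKOW = c(2, 6, 8), HL_B_d = c(0.1, 100), offsets = 0)
  cols <- c("max_ratio_spring_autumn", "min_ratio_summer",
            "max_ratio_annual", "min_ratio_annual")
  for (col in cols) expect_true(all(abs(scan[[col]] - 1) < 1e-12))
})

test_that("warming scan reproduces the seasonal sign structure", {
  scan <- ratio_scan()
  fast <- dplyr::filter(scan, HL_B_d <= 1, logKOW > 6, offset_C == 3)
  # spring/autumn gains, summer losses for rapidly biotransformed chemicals
  expect_true(all(fast$max_ratio_spring_autumn > 1))
  expect_true(all(fast$min_ratio_summer < 1))

  # the strongest response sits at short half-life and high hydrophobicity
  dev <- pmax(scan$max_ratio_annual - 1, 1 - scan$min_ratio_annual)
  worst <- scan[which.max(dev), ]
  expect_lte(worst$HL_B_d, 1)
  expect_gt(worst$logKOW, 6)

  # POP-like damping: persistent hydrophobics respond less than fast ones
  pop <- dplyr::filter(scan, logKOW >= 6, logKOW <= 8, HL_B_d >= 100)
  fast_all <- dplyr::filter(scan, HL_B_d <= 1, logKOW > 6)
  dev_of <- function(d) max(abs(c(d$max_ratio_annual - 1, 1 - d$min_ratio_annual)))
  expect_lt(dev_of(pop), dev_of(fast_all))
})
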