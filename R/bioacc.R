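#' Seasonal water temperature
#'
#' Sinusoidal annual cycle `T = mean + offset + amplitude sin(2 pi (day -
#' phase) / 365)`. The defaults emulate a Lake-Erie-like annual cycle
#' (0-24 deg C, warmest in early August); warming scenarios shift the annual
#' mean through `offset` only.
#'
#' @param day Day index (any numeric vector; the cycle repeats every 365 d).
#' @param mean Annual mean temperature, deg C.
#' @param amplitude Seasonal amplitude, deg C (>= 0).
#' @param phase Phase shift, d (maximum falls at `phase + 365/4`).
#' @param offset Scenario warming offset added to the mean, deg C.
#' @return Temperature, deg C.
#' @export
annual_temperature <- function(day, mean = 12, amplitude = 12,
                               phase = 121.75, offset = 0) {
  if (any(amplitude < 0)) abort("`amplitude` must be >= 0.")
  mean + offset + amplitude * sin(2 * pi * (day - phase) / 365)
}

#' Thermal traits of the model fish
#'
#' Landmarks of the thermal performance curve for a round-goby-like benthic
#' fish: the lower critical limit below which feeding stops, the growth
#' optimum, the upper limit at which consumption collapses, the Q10
#' coefficients of consumption (sub-optimal limb) and respiration, the
#' respiration reference temperature, and the steepness of the supra-optimal
#' consumption decline. `CT_max` here is the feeding-collapse threshold (the
#' point where the consumption rate, not survival, reaches zero), which for
#' a warm-water benthic fish sits a few degrees above the growth optimum.
#'
#' @param CT_min,T_opt,CT_max Critical thermal landmarks, deg C
#'   (`CT_min < T_opt < CT_max`).
#' @param Q10 Respiration temperature coefficient.
#' @param Q10_cons Consumption temperature coefficient on the sub-optimal
#'   limb.
#' @param T_ref_b Reference temperature of the respiration Q10 relation,
#'   deg C.
#' @param fall_exp Exponent of the supra-optimal consumption decline
#'   (larger = steeper collapse between `T_opt` and `CT_max`).
#' @return Named list of traits.
#' @export
thermal_traits <- function(CT_min = -0.5, T_opt = 26, CT_max = 30, Q10 = 2,
                           Q10_cons = 2.3, T_ref_b = 26, fall_exp = 2) {
  if (!(CT_min < T_opt && T_opt < CT_max)) {
    abort("Thermal traits must satisfy CT_min < T_opt < CT_max.")
  }
  list(CT_min = CT_min, T_opt = T_opt, CT_max = CT_max, Q10 = Q10,
       Q10_cons = Q10_cons, T_ref_b = T_ref_b, fall_exp = fall_exp)
}

#' Bioenergetic and toxicokinetic parameters
#'
#' Weight- and temperature-dependent rate coefficients of the energy budget
#' (maximum specific consumption `CA W^CB`, realized fraction `p`,
#' respiration `RA W^RB` with Q10 scaling), energy densities and the
#' assimilated fraction, plus the constants of the kinetic uptake/loss model
#' (gill ventilation allometry, fish and prey lipid fractions, chemical
#' egestion fraction).
#'
#' @param CA,CB Maximum specific consumption: coefficient (g prey / g fish /
#'   d at 1 g) and weight exponent.
#' @param p Proportion of maximum consumption realized.
#' @param RA,RB Specific respiration: coefficient (g O2 / g fish / d at 1 g)
#'   and weight exponent.
#' @param assim Fraction of consumed energy assimilated (after egestion,
#'   excretion and digestion costs).
#' @param ED_prey,ED_fish Energy densities, J/g wet weight.
#' @param oxycal Oxycalorific coefficient, J per g O2 respired.
#' @param gill_coef,gill_exp Gill ventilation allometry, m^3/d at 1 g and
#'   weight exponent.
#' @param lipid_fish,lipid_diet Lipid fractions of fish and diet.
#' @param egestion_chem_frac Chemical egestion rate as a fraction of dietary
#'   uptake rate.
#' @return Named list of parameters.
#' @export
bioenergetic_params <- function(CA = 0.2, CB = -0.27, p = 0.35,
                                RA = 0.006, RB = -0.2,
                                assim = 0.6, ED_prey = 3500, ED_fish = 5000,
                                oxycal = 13560,
                                gill_coef = 8e-4, gill_exp = 0.65,
                                lipid_fish = 0.05, lipid_diet = 0.02,
                                egestion_chem_frac = 0.1) {
  stopifnot(CA > 0, RA > 0, p > 0, p < 1, assim > 0, assim < 1,
            ED_prey > 0, ED_fish > 0, lipid_fish > 0, lipid_diet > 0)
  as.list(environment())
}

#' Thermal performance multiplier
#'
#' Consumption: zero at or outside the critical limits; on the sub-optimal
#' limb a Q10 exponential `Q10_cons^((T - T_opt)/10)` normalized to 1 at
#' `T_opt`; above the optimum a steep power-law collapse
#' `((CT_max - T)/(CT_max - T_opt))^fall_exp` reaching zero at `CT_max`.
#' Respiration: an uncapped Q10 exponential `Q10^((T - T_ref_b)/10)` -
#' metabolic costs keep climbing past the consumption optimum, which is what
#' penalizes growth near `CT_max`.
#'
#' @param T_C Temperature, deg C (vectorized).
#' @param traits Traits list from [thermal_traits()].
#' @param role `"consumption"` or `"respiration"`.
#' @return Multiplier in `[0, Inf)`.
#' @export
thermal_performance <- function(T_C, traits = thermal_traits(),
                                role = c("consumption", "respiration")) {
  role <- match.arg(role)
  if (role == "respiration") {
    return(traits$Q10^((T_C - traits$T_ref_b) / 10))
  }
  rise <- traits$Q10_cons^((T_C - traits$T_opt) / 10)
  fall <- ((traits$CT_max - T_C) / (traits$CT_max - traits$T_opt))^traits$fall_exp
  out <- ifelse(T_C <= traits$T_opt, rise, fall)
  out[T_C <= traits$CT_min | T_C >= traits$CT_max] <- 0
  out
}

#' Simulate fish growth from the daily energy budget
#'
#' Explicit daily integration of
#' `dW/dt = W (assim * C_spec * ED_prey - R_spec * oxycal) / ED_fish`, where
#' specific consumption `C_spec = CA W^CB p f_C(T)` follows the thermal
#' performance curve and specific respiration `RA W^RB Q10^((T-T_ref)/10)`
#' keeps rising with temperature. Weight is clamped at a starvation floor
#' (prolonged periods below `CT_min` burn reserves but do not kill the model
#' fish).
#'
#' @param temps_C Daily temperature series, deg C (the trajectory has one row
#'   per element, day 0 first).
#' @param traits,params Trait and parameter lists.
#' @param W0 Initial weight, g (> 0).
#' @param floor_g Starvation floor, g (default half the initial weight).
#' @return Tibble: `day`, `temp_C`, `weight_g`, `cons_spec` (g/g/d),
#'   `growth_g_d`, `kG` (1/d).
#' @export
simulate_growth <- function(temps_C, traits = thermal_traits(),
                            params = bioenergetic_params(), W0 = 1,
                            floor_g = 0.5 * W0) {
  if (W0 <= 0) abort("`W0` must be > 0.")
  nd <- length(temps_C)
  fC <- thermal_performance(temps_C, traits, "consumption")
  fR <- thermal_performance(temps_C, traits, "respiration")
  W <- cons <- dWs <- numeric(nd)
  w <- W0
  for (t in seq_len(nd)) {
    c_spec <- params$CA * w^params$CB * params$p * fC[t]
    r_spec <- params$RA * w^params$RB * fR[t]
    dW <- w * (params$assim * c_spec * params$ED_prey -
                 r_spec * params$oxycal) / params$ED_fish
    if (!is.finite(dW)) abort("Non-finite growth increment; check parameters.")
    W[t] <- w; cons[t] <- c_spec; dWs[t] <- dW
    w <- max(w + dW, floor_g)
  }
  tibble(day = seq_len(nd) - 1, temp_C = temps_C, weight_g = W,
         cons_spec = cons, growth_g_d = dWs, kG = dWs / W)
}

#' Hypothetical chemical for the bioaccumulation model
#'
#' Exposure concentrations are held constant through the simulation; if the
#' dietary concentration is not supplied it is set at lipid-water equilibrium
#' with the freely dissolved concentration (`C_diet = C_wd * lipid_diet *
#' KOW * 1e-6` mol/g).
#'
#' @param logKOW log10 octanol-water partition coefficient.
#' @param HL_B_d Biotransformation half-life, days (> 0).
#' @param C_wd Freely dissolved water concentration, mol/m^3.
#' @param C_diet Dietary concentration, mol/g (or `NULL` for equilibrium).
#' @param lipid_diet Diet lipid fraction used for the equilibrium default.
#' @return One-row tibble.
#' @export
fish_chemical <- function(logKOW, HL_B_d, C_wd = 1e-6, C_diet = NULL,
                          lipid_diet = bioenergetic_params()$lipid_diet) {
  if (any(HL_B_d <= 0)) abort("`HL_B_d` must be > 0.")
  tibble(
    logKOW = logKOW, HL_B_d = HL_B_d, C_wd = C_wd,
    C_diet = C_diet %||% (C_wd * lipid_diet * 10^logKOW * 1e-6)
  )
}

#' Kinetic uptake and loss rate constants
#'
#' First-order rate constants of the single-organism kinetic model at a
#' given weight and temperature: gill uptake `k1` (ventilation allometry
#' scaled by the respiration multiplier, times a KOW-dependent gill
#' extraction efficiency), elimination `k2 = k1 / (lipid_fish KOW)` (per-gram
#' lipid partitioning), dietary uptake `kD` (specific consumption times a
#' KOW-dependent gut assimilation efficiency), fecal egestion `kE`, growth
#' dilution `kG` and biotransformation `kM = ln 2 / HL_B`.
#'
#' @param W Weight, g (> 0).
#' @param T_C Temperature, deg C.
#' @param logKOW,HL_B_d Chemical descriptors.
#' @param traits,params Trait and parameter lists.
#' @param cons_spec Specific consumption, g/g/d (default recomputed from `W`,
#'   `T_C`).
#' @param growth_g_d Growth increment, g/d (for `kG = growth / W`).
#' @return Tibble of `k1` (m^3/g/d), `k2`, `kD`, `kE`, `kG`, `kM` (1/d).
#' @export
rate_constants <- function(W, T_C, logKOW, HL_B_d,
                           traits = thermal_traits(),
                           params = bioenergetic_params(),
                           cons_spec = NULL, growth_g_d = 0) {
  if (any(W <= 0)) abort("`W` must be > 0.")
  KOW <- 10^logKOW
  Ew <- 1 / (1.85 + 155 / KOW)            # gill extraction efficiency
  Ed <- 1 / (3e-7 * KOW + 2)              # gut assimilation efficiency
  fR <- thermal_performance(T_C, traits, "respiration")
  cons_spec <- cons_spec %||%
    (params$CA * W^params$CB * params$p *
       thermal_performance(T_C, traits, "consumption"))
  k1 <- Ew * params$gill_coef * W^(params$gill_exp - 1) * fR
  K_BW <- params$lipid_fish * KOW * 1e-6  # m^3 water per g fish
  tibble(
    k1 = k1,
    k2 = k1 / K_BW,
    kD = Ed * cons_spec,
    kE = params$egestion_chem_frac * Ed * cons_spec,
    kG = growth_g_d / W,
    kM = log(2) / HL_B_d
  )
}

# Exact update of dC/dt = U - loss * C over one day with constant daily rates.
step_conc <- function(C, U, loss) {
  Cinf <- U / loss
  Cinf + (C - Cinf) * exp(-loss)
}

#' Simulate whole-body concentration over a multi-year run
#'
#' Couples the growth model to the kinetic bioaccumulation balance
#' `dC/dt = k1 C_wd + kD C_diet - (k2 + kE + kG + kM) C` (concentration in
#' mol per g wet weight), advancing one day at a time with the exact solution
#' for piecewise-constant daily rates.
#'
#' @param chem One-row tibble from [fish_chemical()].
#' @param traits,params Trait and parameter lists.
#' @param years Simulation length, years (the trajectory has
#'   `years * 365 + 1` daily points).
#' @param offset Warming offset applied to the annual mean, deg C.
#' @param temp_mean,temp_amplitude,temp_phase Baseline seasonal cycle
#'   parameters (see [annual_temperature()]).
#' @param W0 Initial weight, g.
#' @param growth Optional precomputed growth trajectory (a tibble from
#'   [simulate_growth()] with matching length); when supplied, the
#'   temperature column of that trajectory drives the toxicokinetics.
#' @return A `bioacc_trajectory` tibble: `day`, `temp_C`, `weight_g`,
#'   `conc_mol_g`.
#' @export
simulate_bioaccumulation <- function(chem, traits = thermal_traits(),
                                     params = bioenergetic_params(),
                                     years = 5, offset = 0,
                                     temp_mean = 12, temp_amplitude = 12,
                                     temp_phase = 121.75, W0 = 1,
                                     growth = NULL) {
  if (is.null(growth)) {
    days <- 0:(years * 365)
    temps <- annual_temperature(days, temp_mean, temp_amplitude, temp_phase, offset)
    growth <- simulate_growth(temps, traits, params, W0 = W0)
  }
  ks <- rate_constants(
    growth$weight_g, growth$temp_C, chem$logKOW, chem$HL_B_d,
    traits, params, cons_spec = growth$cons_spec, growth_g_d = growth$growth_g_d)
  U <- ks$k1 * chem$C_wd + ks$kD * chem$C_diet
  loss <- ks$k2 + ks$kE + pmax(ks$kG, 0) + ks$kM
  C <- numeric(nrow(growth))
  c_now <- 0
  for (t in seq_len(nrow(growth))[-1]) {
    c_now <- step_conc(c_now, U[t - 1], loss[t - 1])
    C[t] <- c_now
  }
  if (any(C < 0)) abort("Negative concentration: integration failure.")
  out <- tibble(day = growth$day, temp_C = growth$temp_C,
                weight_g = growth$weight_g, conc_mol_g = C)
  structure(out, class = c("bioacc_trajectory", class(out)), chem = chem)
}

season_windows <- list(spring = 60:151, summer = 152:243, autumn = 244:334)

#' Warming-scenario scan over hydrophobicity and biotransformation half-life
#'
#' For every chemical on a log KOW x biotransformation-half-life grid and
#' every warming offset, simulates five years of growth and bioaccumulation
#' under the baseline seasonal cycle and the offset cycle, forms the daily
#' year-3 concentration ratio `r(t) = C_offset(t) / C_baseline(t)` (ratios
#' > 1 mean more bioaccumulation under warming), and summarizes the maximum
#' ratio over the spring and autumn windows, the minimum over summer, and the
#' annual extremes.
#'
#' @param logKOW,HL_B_d Grid axes (defaults: log KOW 0-8 in unit steps;
#'   half-lives 0.1, 1, 10, 100, 1000 d).
#' @param offsets Warming offsets, deg C.
#' @param traits,params Trait and parameter lists.
#' @param C_wd Freely dissolved water concentration, mol/m^3 (ratios are
#'   invariant to its magnitude).
#' @param years Simulation length (ratios are evaluated over year 3).
#' @param temp_mean,temp_amplitude,temp_phase Baseline cycle parameters.
#' @param W0 Initial weight, g.
#' @return A `bioacc_scan` tibble with one row per (cell, offset):
#'   `logKOW`, `HL_B_d`, `offset_C`, `max_ratio_spring_autumn`,
#'   `min_ratio_summer`, `max_ratio_annual`, `min_ratio_annual`. Daily
#'   year-3 ratios are attached as attribute `"daily"`.
#' @export
ratio_scan <- function(logKOW = 0:8, HL_B_d = 10^(-1:3), offsets = c(2, 3),
                       traits = thermal_traits(), params = bioenergetic_params(),
                       C_wd = 1e-6, years = 5,
                       temp_mean = 12, temp_amplitude = 12, temp_phase = 121.75,
                       W0 = 1) {
  cells <- tidyr::expand_grid(logKOW = logKOW, HL_B_d = HL_B_d)
  nc <- nrow(cells)
  KOW <- 10^cells$logKOW
  Ew <- 1 / (1.85 + 155 / KOW)
  Ed <- 1 / (3e-7 * KOW + 2)
  K_BW <- params$lipid_fish * KOW * 1e-6
  kM <- log(2) / cells$HL_B_d
  C_diet <- C_wd * params$lipid_diet * KOW * 1e-6

  days <- 0:(years * 365)
  y3 <- which(days >= 2 * 365 + 1 & days <= 3 * 365)  # year-3 daily indices
  doy <- days[y3] - 2 * 365

  run_scenario <- function(offset) {
    temps <- annual_temperature(days, temp_mean, temp_amplitude, temp_phase, offset)
    g <- simulate_growth(temps, traits, params, W0 = W0)
    fR <- thermal_performance(temps, traits, "respiration")
    gill_spec <- params$gill_coef * g$weight_g^(params$gill_exp - 1) * fR
    kG <- pmax(g$kG, 0)
    Cmat <- matrix(0, length(days), nc)
    c_now <- numeric(nc)
    for (t in seq_along(days)[-1]) {
      k1 <- Ew * gill_spec[t - 1]
      kD <- Ed * g$cons_spec[t - 1]
      U <- k1 * C_wd + kD * C_diet
      # loss = k2 + kE + kG + kM
      loss <- k1 / K_BW + params$egestion_chem_frac * kD + kG[t - 1] + kM
      c_now <- step_conc(c_now, U, loss)
      Cmat[t, ] <- c_now
    }
    Cmat[y3, , drop = FALSE]
  }

  base <- run_scenario(0)
  rows <- list(); daily <- list()
  for (off in offsets) {
    warm <- run_scenario(off)
    r <- warm / base
    sa <- doy %in% c(season_windows$spring, season_windows$autumn)
    su <- doy %in% season_windows$summer
    rows[[as.character(off)]] <- cells |>
      mutate(
        offset_C = off,
        max_ratio_spring_autumn = apply(r[sa, , drop = FALSE], 2, max),
        min_ratio_summer = apply(r[su, , drop = FALSE], 2, min),
        max_ratio_annual = apply(r, 2, max),
        min_ratio_annual = apply(r, 2, min)
      )
    daily[[as.character(off)]] <- tidyr::expand_grid(
      offset_C = off, cell = seq_len(nc), day_of_year = doy) |>
      arrange(.data$cell, .data$day_of_year) |>
      mutate(
        logKOW = cells$logKOW[.data$cell], HL_B_d = cells$HL_B_d[.data$cell],
        ratio = as.vector(r)
      ) |>
      select("logKOW", "HL_B_d", "offset_C", "day_of_year", "ratio")
  }
  out <- list_rbind(rows)
  structure(out, class = c("bioacc_scan", class(out)),
            daily = list_rbind(daily))
}
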