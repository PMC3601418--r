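output_levels <- c("air", "soil", "freshwater_dissolved",
                   "sediment_porewater", "ocean_dissolved")

extract_outputs <- function(result) {
  result |>
    mutate(output = dplyr::case_when(
      .data$medium == "air" ~ "air",
      .data$medium == "soil" ~ "soil",
      .data$medium == "freshwater" ~ "freshwater_dissolved",
      .data$medium == "sediment" ~ "sediment_porewater",
      .data$medium == "ocean" ~ "ocean_dissolved"
    )) |>
    transmute(
      region = .data$region, output = .data$output,
      value = ifelse(.data$output %in% c("air", "soil"),
                     .data$conc_bulk_mol_m3, .data$conc_dissolved_mol_m3)
    )
}

#' Scan a chemical grid under baseline and perturbed climate
#'
#' For every chemical in the grid, solves the steady-state fate model under
#' the baseline world and under the climate scenario obtained with
#' [apply_climate_scenario()], and records the perturbed-to-baseline ratio of
#' the five reported outputs (bulk air and soil concentrations, freely
#' dissolved freshwater and surface-ocean concentrations, sediment pore-water
#' concentration) in each reporting region. The run is fully deterministic.
#'
#' @param chemicals Tibble of chemicals, e.g. [chemspace_grid()].
#' @param world Baseline `fate_world`.
#' @param deltas Climate deltas tibble (see [default_climate_deltas()]).
#' @param emissions Emission map; default the `air_temperate` pattern.
#' @param regions Regions to report (default ARC, NEU, SAF; remaining regions
#'   are still simulated and can be requested for audit).
#' @return A `ratio_map` tibble: `logKOA`, `logKAW`, `region`, `output`,
#'   `baseline`, `perturbed`, `ratio`.
#' @export
run_chemspace <- function(chemicals, world = default_world(),
                          deltas = default_climate_deltas(),
                          emissions = build_emission_map(world),
                          regions = c("ARC", "NEU", "SAF")) {
  validate_chemicals(chemicals)
  world_gcc <- apply_climate_scenario(world, deltas)
  rows <- vector("list", nrow(chemicals))
  for (k in seq_len(nrow(chemicals))) {
    chem <- chemicals[k, ]
    pair <- tryCatch(
      list(
        base = solve_steady_state(build_fate_system(chem, world, emissions)),
        gcc = solve_steady_state(build_fate_system(chem, world_gcc, emissions))
      ),
      error = function(e) abort(sprintf(
        "Solver failure at grid node logKOA=%g, logKAW=%g: %s",
        chem$logKOA, chem$logKAW, conditionMessage(e)))
    )
    rows[[k]] <- extract_outputs(pair$base) |>
      rename(baseline = "value") |>
      mutate(perturbed = extract_outputs(pair$gcc)$value,
             logKOA = chem$logKOA, logKAW = chem$logKAW, .before = 1) |>
      filter(.data$region %in% regions)
  }
  map <- list_rbind(rows) |>
    mutate(ratio = .data$perturbed / .data$baseline)
  structure(map, class = c("ratio_map", class(map)),
            logKOA_axis = sort(unique(map$logKOA)),
            logKAW_axis = sort(unique(map$logKAW)))
}

#' Summarize a ratio map
#'
#' Per (region, output) and overall: the maximum fold-change
#' `max(r, 1/r)`, the median absolute deviation of the ratio from unity (in
#' percent), the fraction of grid cells within +/-20% of baseline, and the
#' partitioning-space location of the extreme cell.
#'
#' @param map A `ratio_map` from [run_chemspace()].
#' @return A tibble; the final row (`region = "all"`, `output = "all"`) pools
#'   every (cell, region, output) ratio.
#' @export
summarize_ratios <- function(map) {
  if (nrow(map) == 0) abort("Empty ratio map.")
  one <- function(d) {
    fold <- pmax(d$ratio, 1 / d$ratio)
    i <- which.max(fold)
    tibble(
      max_fold = fold[i],
      median_abs_dev_pct = 100 * median(abs(d$ratio - 1)),
      frac_within_20pct = mean(abs(d$ratio - 1) <= 0.2),
      at_logKOA = d$logKOA[i], at_logKAW = d$logKAW[i], at_ratio = d$ratio[i]
    )
  }
  per <- map |>
    group_by(.data$region, .data$output) |>
    group_modify(~ one(.x)) |>
    ungroup()
  bind_rows(per, bind_cols(tibble(region = "all", output = "all"), one(map)))
}

#' Run the reference chemical through the scenario pair
#'
#' Runs a single chemical with chemical-specific half-lives and phase-change
#' energies (default: the PCB-153 fixture) under baseline and perturbed
#' climate, holding primary emission rates unchanged unless
#' `emission_scaling = TRUE`, in which case air emissions are additionally
#' scaled by [scale_emission_with_temperature()] using each region's air
#' warming.
#'
#' @param chemical One-row chemical tibble (default [pcb153()]).
#' @param world Baseline world.
#' @param deltas Climate deltas.
#' @param emissions Emission map.
#' @param emission_scaling Scale emissions with regional warming? Default
#'   `FALSE` (the headline scenario assumption).
#' @return Tibble with rows for each region's air concentration plus the
#'   total inventory and overall persistence `P_OV`; columns `metric`,
#'   `region`, `baseline`, `perturbed`, `ratio`.
#' @export
run_reference_chemical <- function(chemical = pcb153(), world = default_world(),
                                   deltas = default_climate_deltas(),
                                   emissions = build_emission_map(world),
                                   emission_scaling = FALSE) {
  world_gcc <- apply_climate_scenario(world, deltas)
  em_gcc <- emissions
  if (emission_scaling) {
    air_T <- function(w) {
      comp <- w$compartments
      setNames(comp$temp_K[comp$medium == "air"], comp$region[comp$medium == "air"])
    }
    T0 <- air_T(world); T1 <- air_T(world_gcc)
    em_gcc <- emissions |>
      mutate(emission_mol_h = ifelse(
        .data$medium == "air",
        scale_emission_with_temperature(
          .data$emission_mol_h, chemical$dU_A,
          T_K = T1[.data$region], T_ref = T0[.data$region]),
        .data$emission_mol_h))
  }
  base <- solve_steady_state(build_fate_system(chemical, world, emissions))
  gcc <- solve_steady_state(build_fate_system(chemical, world_gcc, em_gcc))

  air <- tibble(
    metric = "air_conc",
    region = base$region[base$medium == "air"],
    baseline = base$conc_bulk_mol_m3[base$medium == "air"],
    perturbed = gcc$conc_bulk_mol_m3[gcc$medium == "air"]
  )
  totals <- tibble(
    metric = c("inventory", "P_OV"),
    region = NA_character_,
    baseline = c(attr(base, "inventory_mol"), attr(base, "P_OV_h")),
    perturbed = c(attr(gcc, "inventory_mol"), attr(gcc, "P_OV_h"))
  )
  bind_rows(air, totals) |> mutate(ratio = .data$perturbed / .data$baseline)
}

#' Monte Carlo screen of input-uncertainty contributions
#'
#' Compares the variance contributed to a model output by uncertain chemical
#' inputs (partition coefficients perturbed log-normally in log10 space,
#' degradation half-lives perturbed log-normally) against the variance
#' contributed by the climate forcing itself (temperature and precipitation
#' deltas drawn uniformly within the multi-model projection envelope,
#' +1.1 to +6.4 K and -20% to +20% by default). Three seeded Monte Carlo
#' sets are run - chemical inputs only, climate inputs only, and both - and
#' the variance share of each group on the chosen output is reported.
#'
#' @param chemical One-row chemical tibble.
#' @param world Baseline world.
#' @param property_sd Named vector: `logK` (sd of the log10 partition
#'   coefficients), `log10_hl` (sd of the log10 half-lives).
#' @param dT_range,dPrecip_range Uniform sampling ranges for the scenario
#'   deltas (applied to all regions).
#' @param n Draws per Monte Carlo set (>= 100).
#' @param seed Integer seed; the screen is reproducible given the seed.
#' @param output Which scalar output to analyse: the perturbed/baseline
#'   Arctic air-concentration ratio, or the baseline Arctic air
#'   concentration.
#' @return A tibble with the variance of the output under each input group
#'   and its share of the all-inputs variance; draws are attached as
#'   attribute `"draws"`.
#' @export
uncertainty_screen <- function(chemical, world = default_world(),
                               property_sd = c(logK = 0.5, log10_hl = 0.5),
                               dT_range = c(1.1, 6.4),
                               dPrecip_range = c(-0.2, 0.2),
                               n = 200, seed = 1,
                               output = c("arc_air_ratio", "arc_air_baseline")) {
  output <- match.arg(output)
  if (n < 100) abort("`n` must be >= 100 for a stable variance decomposition.")
  if (any(property_sd < 0)) abort("`property_sd` entries must be >= 0.")
  if (all(property_sd == 0) && diff(dT_range) == 0 && diff(dPrecip_range) == 0) {
    abort("Degenerate screen: all input uncertainties are zero.")
  }
  emissions <- build_emission_map(world)
  regions <- unique(world$compartments$region)

  eval_one <- function(chem, dT, dPrecip) {
    deltas <- tibble(region = regions, dT = dT, dPrecip = dPrecip)
    base <- solve_steady_state(build_fate_system(chem, world, emissions))
    arc_air <- function(res) res$conc_bulk_mol_m3[res$region == "ARC" & res$medium == "air"]
    if (output == "arc_air_baseline") return(arc_air(base))
    gcc <- solve_steady_state(
      build_fate_system(chem, apply_climate_scenario(world, deltas), emissions))
    arc_air(gcc) / arc_air(base)
  }
  draw_chem <- function() {
    dKAW <- rnorm(1, 0, property_sd[["logK"]])
    dKOA <- rnorm(1, 0, property_sd[["logK"]])
    chem <- chemical
    chem$logKAW <- chem$logKAW + dKAW
    chem$logKOA <- chem$logKOA + dKOA
    chem$logKOW <- chem$logKAW + chem$logKOA
    for (col in c("hl_air_h", "hl_water_h", "hl_soil_h", "hl_sed_h")) {
      chem[[col]] <- chem[[col]] * 10^rnorm(1, 0, property_sd[["log10_hl"]])
    }
    chem
  }
  draw_clim <- function() {
    list(dT = runif(1, dT_range[1], dT_range[2]),
         dPrecip = runif(1, dPrecip_range[1], dPrecip_range[2]))
  }
  mid <- list(dT = mean(dT_range), dPrecip = mean(dPrecip_range))

  run_set <- function(vary_chem, vary_clim) {
    map_dbl(seq_len(n), function(i) {
      chem <- if (vary_chem) draw_chem() else chemical
      cl <- if (vary_clim) draw_clim() else mid
      eval_one(chem, cl$dT, cl$dPrecip)
    })
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  y_chem <- run_set(TRUE, FALSE)
  y_clim <- run_set(FALSE, TRUE)
  y_both <- run_set(TRUE, TRUE)

  v <- c(chemical = var(y_chem), climate = var(y_clim), all_inputs = var(y_both))
  res <- tibble(
    group = names(v), variance = unname(v),
    share = unname(v) / v[["all_inputs"]]
  )
  attr(res, "draws") <- tibble(chemical = y_chem, climate = y_clim, all_inputs = y_both)
  attr(res, "output") <- output
  res
}
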