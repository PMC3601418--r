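#' Construct the default reduced multi-region world
#'
#' Builds a fully parameterized box-model world of interconnected regions,
#' each holding five bulk compartments (air, freshwater, sediment, soil,
#' surface ocean). The default four-region world comprises an Arctic region
#' (ARC), northern Europe (NEU), southern Africa (SAF) and a rest-of-world
#' reservoir (ROW), connected by a closed chain of balanced atmospheric and
#' surface-ocean flows ARC - NEU - ROW - SAF. Geometry (1,000 m atmospheric
#' mixing height, 10 cm soil, 20 m freshwater, 3 cm sediment, 100 m ocean
#' mixed layer), sub-phase volume fractions and regional annual-mean
#' temperatures and rain rates are conventional multimedia-model values; every
#' number sits in the returned object and can be edited before use.
#'
#' @param n_regions Number of regions; only the 4-region reduced world is
#'   currently parameterized.
#' @return A `fate_world`: a list with tibbles `compartments` (one row per
#'   region-medium) and `flows` (directed advective links, m^3/h), and a named
#'   list `transfer` of mass-transfer parameters.
#' @examples
#' w <- default_world()
#' nrow(w$compartments) # 4 regions x 5 media
#' @export
default_world <- function(n_regions = 4) {
  if (!identical(as.numeric(n_regions), 4)) {
    abort("Only the 4-region reduced world (ARC, NEU, SAF, ROW) is parameterized.")
  }
  regions <- tibble(
    region = c("ARC", "NEU", "SAF", "ROW"),
    area_m2 = c(3.0e13, 2.0e13, 2.5e13, 4.35e14),
    frac_ocean = c(0.65, 0.40, 0.40, 0.72),
    frac_fresh = c(0.005, 0.020, 0.010, 0.010),
    temp_K = c(268, 283, 293, 288),
    rain_m_h = c(2.9e-5, 9.1e-5, 6.8e-5, 1.14e-4)
  )
  depth <- c(air = 1000, freshwater = 20, sediment = 0.03, soil = 0.1, ocean = 100)
  comp <- regions |>
    tidyr::expand_grid(medium = names(depth)) |>
    mutate(
      area_comp_m2 = dplyr::case_when(
        .data$medium == "air" ~ .data$area_m2,
        .data$medium == "ocean" ~ .data$area_m2 * .data$frac_ocean,
        .data$medium %in% c("freshwater", "sediment") ~ .data$area_m2 * .data$frac_fresh,
        .data$medium == "soil" ~ .data$area_m2 * (1 - .data$frac_ocean - .data$frac_fresh)
      ),
      depth_m = unname(depth[.data$medium]),
      volume_m3 = .data$area_comp_m2 * .data$depth_m,
      rain_m_h = ifelse(.data$medium == "air", .data$rain_m_h, 0),
      frac_aerosol = ifelse(.data$medium == "air", 2e-11, 0),
      frac_poc = dplyr::case_when(
        .data$medium == "freshwater" ~ 5e-6,
        .data$medium == "ocean" ~ 5e-7,
        TRUE ~ 0
      ),
      frac_air = dplyr::case_when(
        .data$medium == "soil" ~ 0.2,
        .data$medium == "air" ~ 1,
        TRUE ~ 0
      ),
      frac_water = dplyr::case_when(
        .data$medium == "soil" ~ 0.3,
        .data$medium == "sediment" ~ 0.8,
        .data$medium %in% c("freshwater", "ocean") ~ 1,
        TRUE ~ 0
      ),
      frac_solids = dplyr::case_when(
        .data$medium == "soil" ~ 0.5,
        .data$medium == "sediment" ~ 0.2,
        TRUE ~ 0
      ),
      foc = dplyr::case_when(
        .data$medium == "soil" ~ 0.02,
        .data$medium == "sediment" ~ 0.04,
        TRUE ~ 0
      )
    ) |>
    select(
      "region", "medium", "area_comp_m2", "depth_m", "volume_m3", "temp_K",
      "rain_m_h", "frac_aerosol", "frac_poc", "frac_air", "frac_water",
      "frac_solids", "foc"
    )

  # Closed circulation: balanced bidirectional flows along ARC-NEU-ROW-SAF.
  vol_air <- setNames(
    comp$volume_m3[comp$medium == "air"], comp$region[comp$medium == "air"]
  )
  vol_oc <- setNames(
    comp$volume_m3[comp$medium == "ocean"], comp$region[comp$medium == "ocean"]
  )
  chain <- list(c("ARC", "NEU"), c("NEU", "ROW"), c("ROW", "SAF"))
  edge_flows <- function(vols, tau_h) {
    purrr::map(chain, function(e) {
      q <- min(vols[e]) / tau_h
      tibble(from = e, to = rev(e), flow_m3_h = q)
    }) |> list_rbind()
  }
  flows <- bind_rows(
    edge_flows(vol_air, tau_h = 168) |> mutate(medium = "air"),
    edge_flows(vol_oc, tau_h = 43800) |> mutate(medium = "ocean")
  ) |> select("medium", "from", "to", "flow_m3_h")

  world <- structure(
    list(compartments = comp, flows = flows, transfer = default_transfer_params()),
    class = "fate_world"
  )
  validate_world(world)
}

#' Default mass-transfer and partitioning sub-model parameters
#'
#' One editable table of the conventional two-film, deposition and scavenging
#' parameters used when assembling transport D-values, plus the aerosol and
#' organic-carbon partitioning sub-models (a KOA-based particle-gas relation
#' with organic-matter fraction `aerosol_fom`, and Koc = 0.35 KOW).
#'
#' @return Named list of parameters (units in the names' documentation:
#'   mass-transfer coefficients and velocities in m/h; fractions and the
#'   scavenging ratio dimensionless; aerosol density in ug/m^3).
#' @export
default_transfer_params <- function() {
  list(
    mtc_air_water_air = 3,       # air-side MTC over water surfaces, m/h
    mtc_air_water_water = 0.03,  # water-side MTC, m/h
    mtc_air_soil_air = 1,        # air boundary layer over soil, m/h
    mtc_soil_air_diff = 0.007,   # effective gas diffusion across 5 cm of soil, m/h
    mtc_soil_water_diff = 1e-5,  # water-phase diffusion in soil, m/h
    mtc_sed_water = 1e-4,        # sediment-water diffusion MTC, m/h
    dep_solids_vel = 4.6e-8,     # suspended-solids deposition velocity, m/h
    resusp_solids_vel = 1.1e-8,  # sediment resuspension velocity, m/h
    burial_solids_vel = 2.2e-8,  # sediment burial velocity, m/h
    runoff_solids_vel = 2.3e-8,  # soil solids runoff velocity, m/h
    runoff_water_vel = 3.9e-5,   # soil water runoff velocity, m/h
    dry_dep_vel = 10,            # aerosol dry deposition velocity, m/h
    scavenging_ratio = 2e5,      # rain washout volume ratio for aerosol
    ocean_export_vel = 4.6e-8,   # POC settling export below the mixed layer, m/h
    fw_residence_h = 8766,       # freshwater hydraulic residence time, h
    aerosol_fom = 0.2,           # organic-matter fraction of aerosol
    aerosol_density_ug_m3 = 1.4e12,
    koc_kow_ratio = 0.35         # Karickhoff-style Koc/Kow
  )
}

media_levels <- c("air", "freshwater", "sediment", "soil", "ocean")

#' Validate a fate world
#'
#' Checks that each region holds exactly one compartment per medium, volumes
#' are positive, volume fractions lie in `[0, 1]`, rain rates and flows are
#' non-negative, and flow endpoints name existing regions.
#'
#' @param world A `fate_world`.
#' @return The world, invisibly unchanged.
#' @export
validate_world <- function(world) {
  comp <- world$compartments
  counts <- comp |> count(.data$region, .data$medium)
  if (any(counts$n != 1) ||
      !all(sort(unique(comp$medium)) == sort(media_levels))) {
    abort("Each region must hold exactly one compartment per medium.")
  }
  if (any(comp$volume_m3 <= 0)) abort("Compartment volumes must be > 0.")
  fr <- as.matrix(comp[, c("frac_aerosol", "frac_poc", "frac_air",
                           "frac_water", "frac_solids", "foc")])
  if (any(fr < 0 | fr > 1)) abort("Volume fractions must lie in [0, 1].")
  if (any(comp$rain_m_h < 0)) abort("Rain rates must be >= 0.")
  if (any(world$flows$flow_m3_h < 0)) abort("Advective flows must be >= 0.")
  if (!all(c(world$flows$from, world$flows$to) %in% comp$region)) {
    abort("Flow endpoints must name existing regions.")
  }
  world
}

#' @export
print.fate_world <- function(x, ...) {
  regions <- unique(x$compartments$region)
  cat("<fate_world> ", length(regions), " regions (",
      paste(regions, collapse = ", "), "), ",
      nrow(x$compartments), " compartments, ",
      nrow(x$flows), " advective links\n", sep = "")
  invisible(x)
}

#' Default climate-change scenario deltas
#'
#' Per-region annual-mean temperature shifts and relative precipitation
#' changes representative of an end-of-century mid-range forcing scenario:
#' amplified Arctic warming (+5.0 K) with wetter high latitudes (+15%),
#' moderate mid-latitude warming (+3.0 to +3.5 K) and subtropical drying
#' (-10% over SAF). All values sit inside the multi-model envelope of +1.1 to
#' +6.4 deg C warming and -20% to +20% precipitation change.
#'
#' @return A tibble with columns `region`, `dT` (K), `dPrecip` (fractional),
#'   `wind_scale`, `current_scale`.
#' @export
default_climate_deltas <- function() {
  tibble(
    region = c("ARC", "NEU", "SAF", "ROW"),
    dT = c(5.0, 3.0, 3.5, 3.0),
    dPrecip = c(0.15, 0.10, -0.10, 0.0),
    wind_scale = 1, current_scale = 1
  )
}

#' Apply a climate scenario to a world
#'
#' Returns a new world in which, for each delta row, every compartment of the
#' named region is warmed by `dT`, the region's rain rate is scaled by
#' `(1 + dPrecip)`, and (optionally) atmospheric and oceanic flows leaving the
#' region are scaled by `wind_scale` and `current_scale`. The input world is
#' left untouched, so baseline and perturbed runs can be compared.
#'
#' @param world A `fate_world`.
#' @param deltas Tibble with columns `region`, `dT` (K), `dPrecip`
#'   (fraction, > -1); optional `wind_scale`, `current_scale`.
#' @return A perturbed `fate_world`.
#' @export
apply_climate_scenario <- function(world, deltas) {
  deltas <- as_tibble(deltas)
  if (!all(c("region", "dT", "dPrecip") %in% names(deltas))) {
    abort("`deltas` needs columns region, dT, dPrecip.")
  }
  unknown <- setdiff(deltas$region, world$compartments$region)
  if (length(unknown)) {
    abort(paste0("Unknown region code(s) in deltas: ", paste(unknown, collapse = ", ")))
  }
  if (any(deltas$dPrecip <= -1)) abort("`dPrecip` must be > -1.")
  if (!"wind_scale" %in% names(deltas)) deltas$wind_scale <- 1
  if (!"current_scale" %in% names(deltas)) deltas$current_scale <- 1

  comp <- world$compartments |>
    left_join(deltas, by = "region") |>
    mutate(
      temp_K = .data$temp_K + dplyr::coalesce(.data$dT, 0),
      rain_m_h = .data$rain_m_h * (1 + dplyr::coalesce(.data$dPrecip, 0))
    ) |>
    select(-"dT", -"dPrecip", -"wind_scale", -"current_scale")

  scale_of <- function(region, col) {
    s <- deltas[[col]][match(region, deltas$region)]
    dplyr::coalesce(s, 1)
  }
  flows <- world$flows |>
    mutate(flow_m3_h = .data$flow_m3_h * ifelse(
      .data$medium == "air",
      scale_of(.data$from, "wind_scale"),
      scale_of(.data$from, "current_scale")
    ))
  out <- world
  out$compartments <- comp
  out$flows <- flows
  validate_world(out)
}

#' Build an emission map
#'
#' The default `air_temperate` mode emits `base_rate` mol/h into the air of
#' every non-Arctic region and `arc_fraction * base_rate` into Arctic air,
#' reflecting that primary emissions to the Arctic are very low and its
#' burden arrives by long-range transport. `custom` mode takes a user table.
#'
#' @param world A `fate_world`.
#' @param mode `"air_temperate"` or `"custom"`.
#' @param table For `custom`: tibble with columns `region`, `medium`,
#'   `emission_mol_h`.
#' @param base_rate Emission rate to each source region's air, mol/h.
#' @param arc_fraction Arctic emission as a fraction of `base_rate`.
#' @return Tibble with columns `region`, `medium`, `emission_mol_h`.
#' @export
build_emission_map <- function(world, mode = c("air_temperate", "custom"),
                               table = NULL, base_rate = 1000,
                               arc_fraction = 0.001) {
  mode <- match.arg(mode)
  regions <- unique(world$compartments$region)
  if (mode == "air_temperate") {
    em <- tibble(
      region = regions, medium = "air",
      emission_mol_h = ifelse(regions == "ARC", base_rate * arc_fraction, base_rate)
    )
  } else {
    em <- as_tibble(table)
    if (is.null(table) || !all(c("region", "medium", "emission_mol_h") %in% names(em))) {
      abort("`table` needs columns region, medium, emission_mol_h.")
    }
  }
  if (any(em$emission_mol_h < 0)) abort("Emission rates must be >= 0.")
  if (!any(em$emission_mol_h > 0)) abort("At least one emission rate must be > 0.")
  em
}

#' Scale an emission rate with temperature
#'
#' Passive volatilization from materials and stockpiles responds to ambient
#' temperature through the internal energy of vaporization:
#' \deqn{E(T) = E_{ref} \exp\left(\frac{\Delta U_A}{R}\left(\frac{1}{T} -
#'   \frac{1}{T_{ref}}\right)\right)}
#' With the condensation sign convention used throughout the package
#' (negative `dU_A`), warming increases the emission rate. This scaling is OFF
#' by default in the scenario runs, which hold primary emissions unchanged.
#'
#' @param E_ref Emission rate at `T_ref`, mol/h (>= 0).
#' @param dU_A Internal energy of vaporization, kJ/mol (negative by
#'   convention).
#' @param T_K Ambient temperature, K.
#' @param T_ref Reference temperature, K.
#' @return Scaled emission rate, mol/h.
#' @examples
#' scale_emission_with_temperature(100, dU_A = -80, T_K = 303.15)
#' @export
scale_emission_with_temperature <- function(E_ref, dU_A, T_K, T_ref = 298.15) {
  if (any(E_ref < 0)) abort("`E_ref` must be >= 0.")
  E_ref * exp((dU_A * 1000 / R_GAS) * (1 / T_K - 1 / T_ref))
}

#' Flatten a world to a parameter audit table
#'
#' @param world A `fate_world`.
#' @return A long tibble (`table`, `key`/columns, `value`) concatenating the
#'   compartment table, flow table and transfer parameters for audit export.
#' @export
world_parameter_table <- function(world) {
  bind_rows(
    world$compartments |>
      tidyr::pivot_longer(-c("region", "medium"), names_to = "key") |>
      mutate(table = "compartments", .before = 1),
    world$flows |>
      mutate(key = paste(.data$medium, .data$from, .data$to, sep = "_")) |>
      transmute(table = "flows", region = .data$from, medium = .data$medium,
                key = .data$key, value = .data$flow_m3_h),
    tibble(
      table = "transfer", region = NA_character_, medium = NA_character_,
      key = names(world$transfer),
      value = unlist(world$transfer, use.names = FALSE)
    )
  )
}

#' Serialize a world to (and from) a YAML file
#'
#' @param world A `fate_world`.
#' @param path File path.
#' @return `write_world()` the input invisibly; `read_world()` a validated
#'   `fate_world` that is field-equal to what was written.
#' @export
write_world <- function(world, path) {
  yaml::write_yaml(
    list(
      compartments = lapply(
        seq_len(nrow(world$compartments)),
        function(i) as.list(world$compartments[i, ])
      ),
      flows = lapply(
        seq_len(nrow(world$flows)),
        function(i) as.list(world$flows[i, ])
      ),
      transfer = world$transfer
    ),
    path
  )
  invisible(world)
}

#' @rdname write_world
#' @export
read_world <- function(path) {
  raw <- yaml::read_yaml(path)
  world <- structure(
    list(
      compartments = purrr::map(raw$compartments, as_tibble) |> list_rbind(),
      flows = purrr::map(raw$flows, as_tibble) |> list_rbind(),
      transfer = raw$transfer
    ),
    class = "fate_world"
  )
  validate_world(world)
}
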