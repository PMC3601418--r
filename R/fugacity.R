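#' Fugacity capacities (Z-values) of a compartment
#'
#' Computes pure-phase and bulk fugacity capacities (mol m^-3 Pa^-1) for one
#' compartment at a given temperature. Partition coefficients are first moved
#' to `T_K` by [adjust_partition_coefficient()]; then
#' `Z_air = 1/(R T)`, `Z_water = Z_air / K_AW(T)`,
#' `Z_oc = 0.35 K_OW(T) Z_water` (organic carbon, Karickhoff-style), and the
#' aerosol Z follows a K_OA-based particle-gas partition relation
#' (`log Kp = log K_OA + log f_OM - 11.91`, Kp in m^3/ug, converted to a
#' volumetric ratio with the aerosol density). The bulk Z is the
#' volume-fraction-weighted sum of the sub-phases present.
#'
#' @param chemical One-row chemical tibble (see [chemical()]).
#' @param compartment One row of a world's `compartments` tibble.
#' @param T_K Temperature, K (default: the compartment temperature).
#' @param transfer Transfer/partitioning parameter list
#'   (default [default_transfer_params()]).
#' @return Named list: `Z_air`, `Z_water`, `Z_octanol`, `Z_oc`, `Z_aerosol`,
#'   `Z_solid` (per m^3 of solids, including `foc`), `Z_bulk`, plus the
#'   temperature-adjusted `K_AW`, `K_OW`, `K_OA`.
#' @export
compute_z_values <- function(chemical, compartment, T_K = compartment$temp_K,
                             transfer = default_transfer_params()) {
  K_AW <- adjust_partition_coefficient(
    10^chemical$logKAW, chemical$dU_AW, T_K, chemical$T_ref_K)
  K_OW <- adjust_partition_coefficient(
    10^chemical$logKOW, chemical$dU_OW, T_K, chemical$T_ref_K)
  K_OA <- adjust_partition_coefficient(
    10^chemical$logKOA, chemical$dU_OA, T_K, chemical$T_ref_K)
  if (K_AW <= 0) abort("K_AW(T) must be > 0.")

  Z_air <- 1 / (R_GAS * T_K)
  Z_water <- Z_air / K_AW
  Z_octanol <- K_OW * Z_water
  Z_oc <- transfer$koc_kow_ratio * K_OW * Z_water
  # particle-gas partitioning: volumetric aerosol/air ratio from Kp (m^3/ug)
  Kp <- 10^(log10(K_OA) + log10(transfer$aerosol_fom) - 11.91)
  Z_aerosol <- Z_air * Kp * transfer$aerosol_density_ug_m3
  Z_solid <- compartment$foc * Z_oc

  Z_bulk <- switch(
    compartment$medium,
    air = (1 - compartment$frac_aerosol) * Z_air +
      compartment$frac_aerosol * Z_aerosol,
    freshwater = ,
    ocean = (1 - compartment$frac_poc) * Z_water +
      compartment$frac_poc * Z_oc,
    soil = ,
    sediment = compartment$frac_air * Z_air +
      compartment$frac_water * Z_water +
      compartment$frac_solids * Z_solid,
    abort(paste0("Unknown medium: ", compartment$medium))
  )
  list(Z_air = Z_air, Z_water = Z_water, Z_octanol = Z_octanol, Z_oc = Z_oc,
       Z_aerosol = Z_aerosol, Z_solid = Z_solid, Z_bulk = Z_bulk,
       K_AW = K_AW, K_OW = K_OW, K_OA = K_OA)
}

hl_col_for <- c(air = "hl_air_h", freshwater = "hl_water_h",
                ocean = "hl_water_h", soil = "hl_soil_h", sediment = "hl_sed_h")
ea_col_for <- c(air = "Ea_air", freshwater = "Ea_water",
                ocean = "Ea_water", soil = "Ea_soil", sediment = "Ea_sed")

#' Assemble the steady-state fugacity mass balance (D-values)
#'
#' Builds the full transfer system for one chemical in a world: degradation
#' D-values (`(ln 2 / HL_m(T)) V Z_bulk` with Arrhenius-adjusted half-lives),
#' inter-region advection through air and surface ocean, two-film air-water
#' diffusion, rain dissolution, wet and dry aerosol deposition, air-soil
#' diffusion through a boundary layer in series with soil-phase diffusion,
#' soil solids and water runoff to freshwater, freshwater discharge to the
#' ocean, sediment-water diffusion, deposition, resuspension, and the two
#' permanent removal pathways (sediment burial and POC export below the ocean
#' mixed layer). Temperature acts through Z(T) and HL(T); precipitation
#' deltas act on the rain-driven terms.
#'
#' @param chemical One-row chemical tibble.
#' @param world A `fate_world`.
#' @param emissions Emission map tibble (`region`, `medium`,
#'   `emission_mol_h`), e.g. from [build_emission_map()].
#' @return A `fate_system`: list with the compartment index, loss matrix `A`
#'   (mol Pa^-1 h^-1; diagonal = total losses, off-diagonal = -gains), the
#'   degradation and boundary-removal D vectors, bulk and water Z-values,
#'   volumes and the emission vector.
#' @export
build_fate_system <- function(chemical, world, emissions) {
  comp <- world$compartments
  tr <- world$transfer %||% default_transfer_params()
  n <- nrow(comp)
  idx <- comp |> mutate(i = dplyr::row_number()) |> select("region", "medium", "i")
  key <- function(region, medium) idx$i[idx$region == region & idx$medium == medium]

  Z <- vector("list", n)
  for (i in seq_len(n)) Z[[i]] <- compute_z_values(chemical, comp[i, ], transfer = tr)
  Z_bulk <- map_dbl(Z, "Z_bulk")

  # degradation
  hl_T <- numeric(n)
  for (i in seq_len(n)) {
    m <- comp$medium[i]
    hl_T[i] <- adjust_halflife(
      chemical[[hl_col_for[[m]]]], chemical[[ea_col_for[[m]]]],
      comp$temp_K[i], chemical$T_ref_K)
  }
  D_deg <- (log(2) / hl_T) * comp$volume_m3 * Z_bulk

  Tm <- matrix(0, n, n)       # Tm[i, j]: D-value for transfer i -> j
  D_removal <- numeric(n)     # burial / deep export (leaves the system)

  add <- function(from, to, D) Tm[from, to] <<- Tm[from, to] + D

  for (r in unique(comp$region)) {
    i_air <- key(r, "air"); i_fw <- key(r, "freshwater")
    i_sed <- key(r, "sediment"); i_soil <- key(r, "soil"); i_oc <- key(r, "ocean")
    rain <- comp$rain_m_h[i_air]
    vQ <- comp$frac_aerosol[i_air]
    Za <- Z[[i_air]]$Z_air; Zq <- Z[[i_air]]$Z_aerosol

    # air <-> surface waters (freshwater and ocean)
    for (i_w in c(i_fw, i_oc)) {
      A_w <- comp$area_comp_m2[i_w]
      Zw <- Z[[i_w]]$Z_water
      D_diff <- A_w / (1 / (tr$mtc_air_water_air * Za) +
                       1 / (tr$mtc_air_water_water * Zw))
      add(i_air, i_w, D_diff + A_w * rain * Zw +
            A_w * rain * tr$scavenging_ratio * vQ * Zq +
            A_w * tr$dry_dep_vel * vQ * Zq)
      add(i_w, i_air, D_diff)
    }

    # air <-> soil
    A_s <- comp$area_comp_m2[i_soil]
    Zw_s <- Z[[i_soil]]$Z_water
    D_soil_side <- A_s * (tr$mtc_soil_air_diff * Za + tr$mtc_soil_water_diff * Zw_s)
    D_as_diff <- 1 / (1 / (A_s * tr$mtc_air_soil_air * Za) + 1 / D_soil_side)
    add(i_air, i_soil, D_as_diff + A_s * rain * Zw_s +
          A_s * rain * tr$scavenging_ratio * vQ * Zq +
          A_s * tr$dry_dep_vel * vQ * Zq)
    add(i_soil, i_air, D_as_diff)

    # soil -> freshwater runoff (solids + water)
    add(i_soil, i_fw, A_s * (tr$runoff_solids_vel * Z[[i_soil]]$Z_solid +
                               tr$runoff_water_vel * Zw_s))

    # freshwater -> ocean discharge
    Q_fw <- comp$volume_m3[i_fw] / tr$fw_residence_h
    add(i_fw, i_oc, Q_fw * Z_bulk[i_fw])

    # freshwater <-> sediment
    A_f <- comp$area_comp_m2[i_fw]
    Zw_f <- Z[[i_fw]]$Z_water
    D_ws_diff <- A_f * tr$mtc_sed_water * Zw_f
    add(i_fw, i_sed, D_ws_diff + A_f * tr$dep_solids_vel * Z[[i_fw]]$Z_oc)
    add(i_sed, i_fw, D_ws_diff + A_f * tr$resusp_solids_vel * Z[[i_sed]]$Z_solid)
    D_removal[i_sed] <- D_removal[i_sed] +
      A_f * tr$burial_solids_vel * Z[[i_sed]]$Z_solid

    # ocean POC export below the mixed layer
    D_removal[i_oc] <- D_removal[i_oc] +
      comp$area_comp_m2[i_oc] * tr$ocean_export_vel * Z[[i_oc]]$Z_oc
  }

  # inter-region advection
  for (k in seq_len(nrow(world$flows))) {
    fl <- world$flows[k, ]
    m <- if (fl$medium == "air") "air" else "ocean"
    i <- key(fl$from, m); j <- key(fl$to, m)
    add(i, j, fl$flow_m3_h * Z_bulk[i])
  }

  A <- -t(Tm)
  diag(A) <- D_deg + rowSums(Tm) + D_removal

  E <- numeric(n)
  for (k in seq_len(nrow(emissions))) {
    i <- key(emissions$region[k], emissions$medium[k])
    if (length(i) != 1) abort("Emission entry does not match a compartment.")
    E[i] <- E[i] + emissions$emission_mol_h[k]
  }

  structure(
    list(
      index = idx, A = A, transfers = Tm, D_deg = D_deg, D_removal = D_removal,
      Z_bulk = Z_bulk, Z_water = map_dbl(Z, "Z_water"),
      volumes = comp$volume_m3, emissions = E
    ),
    class = "fate_system"
  )
}

#' Solve the steady-state mass balance
#'
#' Solves `(losses - gains) f = E` for the compartmental fugacities and
#' derives bulk concentrations (`C = Z_bulk f`), freely dissolved
#' concentrations in the water-containing media (`f Z_water`, the
#' bioavailable fraction for pelagic exposure; in sediment this is the
#' pore-water concentration), masses, the total inventory, the overall
#' persistence `P_OV = total mass / total degradation rate`, and the loss
#' budget split between degradation and permanent boundary removal.
#'
#' @param system A `fate_system` from [build_fate_system()].
#' @return A `fate_result` tibble (one row per compartment: `region`,
#'   `medium`, `fugacity_Pa`, `conc_bulk_mol_m3`, `conc_dissolved_mol_m3`,
#'   `mass_mol`) with attributes `inventory_mol`, `P_OV_h`, `loss_budget`.
#' @export
solve_steady_state <- function(system) {
  E <- system$emissions
  f <- tryCatch(
    solve(system$A, E),
    error = function(e) abort(paste0("Singular fate system: ", conditionMessage(e)))
  )
  if (any(f < -1e-12 * max(abs(f), 1e-300))) {
    abort("Negative fugacities: the fate system is not well posed.")
  }
  f <- pmax(f, 0)

  deg_rate <- sum(system$D_deg * f)
  removal_rate <- sum(system$D_removal * f)
  total_in <- sum(E)
  if (total_in > 0) {
    rel_err <- abs(total_in - deg_rate - removal_rate) / total_in
    if (rel_err > 1e-9) {
      abort(sprintf("Mass balance failed to close (relative error %.3g).", rel_err))
    }
  }

  masses <- system$Z_bulk * f * system$volumes
  res <- system$index |>
    mutate(
      fugacity_Pa = f,
      conc_bulk_mol_m3 = system$Z_bulk * f,
      conc_dissolved_mol_m3 = ifelse(
        .data$medium %in% c("freshwater", "ocean", "sediment"),
        system$Z_water * f, NA_real_),
      mass_mol = masses
    ) |>
    select(-"i")
  structure(
    res,
    inventory_mol = sum(masses),
    P_OV_h = if (deg_rate > 0) sum(masses) / deg_rate else Inf,
    loss_budget = c(degradation_mol_h = deg_rate, advection_mol_h = removal_rate),
    class = c("fate_result", class(res))
  )
}

#' @export
print.fate_result <- function(x, ...) {
  NextMethod()
  cat(sprintf("# inventory: %.6g mol; P_OV: %.6g h\n",
              attr(x, "inventory_mol"), attr(x, "P_OV_h")))
  invisible(x)
}

#' Dynamic integration of the compartmental masses
#'
#' Integrates `dM/dt = E - A f` (with `f = M / (V Z)`) by explicit Euler
#' steps; used to verify that [solve_steady_state()] is the long-time limit
#' of the dynamic system. The step must resolve the fastest compartmental
#' loss rate or the integration is rejected as unstable.
#'
#' @param system A `fate_system`.
#' @param horizon_h Integration horizon, hours.
#' @param step_h Time step, hours.
#' @param M0 Initial masses, mol (default zero).
#' @return Tibble with `time_h` and one mass column per compartment
#'   (`region.medium`).
#' @export
dynamic_solve <- function(system, horizon_h, step_h, M0 = NULL) {
  if (horizon_h <= 0 || step_h <= 0) abort("`horizon_h` and `step_h` must be > 0.")
  vz <- system$volumes * system$Z_bulk
  rates <- diag(system$A) / vz        # 1/h loss rate per compartment
  if (step_h > 1 / max(rates)) {
    abort(sprintf(
      "`step_h` too large for stability: must be <= %.4g h.", 1 / max(rates)))
  }
  n <- length(vz)
  M <- M0 %||% numeric(n)
  times <- seq(0, horizon_h, by = step_h)
  out <- matrix(NA_real_, length(times), n)
  out[1, ] <- M
  for (t in seq_along(times)[-1]) {
    f <- M / vz
    M <- M + step_h * (system$emissions - as.vector(system$A %*% f))
    M <- pmax(M, 0)
    out[t, ] <- M
  }
  colnames(out) <- paste(system$index$region, system$index$medium, sep = ".")
  bind_cols(tibble(time_h = times), as_tibble(out))
}
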