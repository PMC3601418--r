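#' Temperature adjustment of a partition coefficient (van't Hoff)
#'
#' Adjusts an equilibrium partition coefficient from a reference temperature to
#' another temperature using the internal energy of the corresponding phase
#' change:
#' \deqn{K(T) = K_{ref} \exp\left(-\frac{\Delta U}{R}\left(\frac{1}{T} -
#'   \frac{1}{T_{ref}}\right)\right)}
#' With this sign convention a positive \eqn{\Delta U} makes \eqn{K} increase
#' with temperature (e.g. the air-water partition coefficient of most
#' semivolatile organics).
#'
#' @param K_ref Partition coefficient (linear, not log10) at `T_ref`.
#' @param dU Internal energy of phase change, kJ/mol.
#' @param T_K Target temperature, K.
#' @param T_ref Reference temperature, K (default 298.15).
#' @return The partition coefficient at `T_K` (same shape as the inputs,
#'   which are recycled vectorwise).
#' @examples
#' adjust_partition_coefficient(1e-3, dU = 60, T_K = 288.15)
#' @export
adjust_partition_coefficient <- function(K_ref, dU, T_K, T_ref = 298.15) {
  if (any(K_ref <= 0)) abort("`K_ref` must be > 0.")
  if (any(T_K <= 0)) abort("`T_K` must be > 0.")
  if (any(T_ref <= 0)) abort("`T_ref` must be > 0.")
  K_ref * exp(-(dU * 1000 / R_GAS) * (1 / T_K - 1 / T_ref))
}

#' Internal energy of air-water phase change from the thermodynamic triangle
#'
#' The three partition coefficients of a neutral organic are linked by
#' \eqn{K_{OW} = K_{AW} K_{OA}}; internal consistency of their temperature
#' dependence requires \eqn{\Delta U_{AW} = \Delta U_{OW} - \Delta U_{OA}}.
#'
#' @param dU_OW Internal energy of octanol-water phase change, kJ/mol.
#' @param dU_OA Internal energy of octanol-air phase change, kJ/mol.
#' @return \eqn{\Delta U_{AW}} in kJ/mol.
#' @export
derive_dU_AW <- function(dU_OW, dU_OA) dU_OW - dU_OA

#' Temperature adjustment of a degradation half-life (Arrhenius)
#'
#' The first-order degradation rate constant \eqn{k = \ln 2 / HL} follows
#' Arrhenius temperature dependence with activation energy `Ea`; warming with
#' `Ea > 0` therefore shortens the half-life.
#'
#' @param HL_ref Half-life at `T_ref`, hours.
#' @param Ea Activation energy, kJ/mol (>= 0).
#' @param T_K Target temperature, K.
#' @param T_ref Reference temperature, K (default 298.15).
#' @return Half-life at `T_K`, hours.
#' @examples
#' adjust_halflife(100, Ea = 30, T_K = 308.15)
#' @export
adjust_halflife <- function(HL_ref, Ea, T_K, T_ref = 298.15) {
  if (any(HL_ref <= 0)) abort("`HL_ref` must be > 0.")
  if (any(Ea < 0)) abort("`Ea` must be >= 0.")
  k_ref <- log(2) / HL_ref
  k_T <- k_ref * exp(-(Ea * 1000 / R_GAS) * (1 / T_K - 1 / T_ref))
  log(2) / k_T
}

chem_cols <- c(
  "name", "logKOW", "logKAW", "logKOA", "dU_OW", "dU_OA", "dU_AW", "dU_A",
  "hl_air_h", "hl_water_h", "hl_soil_h", "hl_sed_h",
  "Ea_air", "Ea_water", "Ea_soil", "Ea_sed", "T_ref_K"
)

#' Construct a chemical property record
#'
#' A chemical is one row of a tibble holding the partitioning triplet at the
#' reference temperature, the internal energies of phase change that drive its
#' temperature dependence, and medium-specific degradation half-lives with
#' their activation energies. `logKOW` is derived from the thermodynamic
#' triangle (`logKAW + logKOA`) and `dU_AW` from [derive_dU_AW()], so records
#' built here are internally consistent by construction.
#'
#' @param name Chemical name.
#' @param logKAW,logKOA log10 air-water and octanol-air partition coefficients
#'   at `T_ref_K`.
#' @param dU_OW,dU_OA Internal energies of octanol-water and octanol-air phase
#'   change, kJ/mol.
#' @param dU_A Internal energy of vaporization used for optional
#'   emission-temperature scaling, kJ/mol (negative values mean warming
#'   increases passive volatilization).
#' @param hl_air_h,hl_water_h,hl_soil_h,hl_sed_h Degradation half-lives at
#'   `T_ref_K`, hours.
#' @param Ea_air,Ea_water,Ea_soil,Ea_sed Activation energies for degradation,
#'   kJ/mol.
#' @param T_ref_K Reference temperature, K.
#' @return A one-row tibble with the standard chemical columns.
#' @examples
#' chemical("hypothetical", logKAW = -2, logKOA = 9)
#' @export
chemical <- function(name = "chem",
                     logKAW, logKOA,
                     dU_OW = -20, dU_OA = -(10 + 3.5 * logKOA), dU_A = -80,
                     hl_air_h = 1000, hl_water_h = 10000,
                     hl_soil_h = 30000, hl_sed_h = 30000,
                     Ea_air = 10, Ea_water = 30, Ea_soil = 30, Ea_sed = 30,
                     T_ref_K = 298.15) {
  chem <- tibble(
    name = name, logKOW = logKAW + logKOA, logKAW = logKAW, logKOA = logKOA,
    dU_OW = dU_OW, dU_OA = dU_OA, dU_AW = derive_dU_AW(dU_OW, dU_OA),
    dU_A = dU_A,
    hl_air_h = hl_air_h, hl_water_h = hl_water_h,
    hl_soil_h = hl_soil_h, hl_sed_h = hl_sed_h,
    Ea_air = Ea_air, Ea_water = Ea_water, Ea_soil = Ea_soil, Ea_sed = Ea_sed,
    T_ref_K = T_ref_K
  )[, chem_cols]
  validate_chemicals(chem)
}

#' Validate a tibble of chemical records
#'
#' Checks column presence, the thermodynamic triangle
#' (`logKOW = logKAW + logKOA`), internal consistency of the phase-change
#' energies (`dU_AW = dU_OW - dU_OA`), and positivity of half-lives and the
#' reference temperature.
#'
#' @param chemicals Tibble with the standard chemical columns.
#' @return The input, invisibly unchanged, for piping.
#' @export
validate_chemicals <- function(chemicals) {
  missing <- setdiff(chem_cols, names(chemicals))
  if (length(missing)) {
    abort(paste0("Missing chemical columns: ", paste(missing, collapse = ", ")))
  }
  if (any(abs(chemicals$logKOW - chemicals$logKAW - chemicals$logKOA) > 1e-9)) {
    abort("Thermodynamic triangle violated: logKOW must equal logKAW + logKOA.")
  }
  if (any(abs(chemicals$dU_AW - (chemicals$dU_OW - chemicals$dU_OA)) > 1e-9)) {
    abort("dU_AW must equal dU_OW - dU_OA.")
  }
  hl <- as.matrix(chemicals[, c("hl_air_h", "hl_water_h", "hl_soil_h", "hl_sed_h")])
  if (any(hl <= 0)) abort("Half-lives (`hl_*_h`) must be > 0.")
  if (any(chemicals$T_ref_K <= 0)) abort("`T_ref_K` must be > 0.")
  chemicals
}

#' Hypothetical-chemical grid over the partitioning space
#'
#' Builds a regular grid of internally consistent hypothetical chemicals in
#' the (log KOA, log KAW) plane; log KOW follows from the thermodynamic
#' triangle. All non-partitioning fields are copied from `template` except
#' `dU_OA`, which is set from a configurable linear function of log KOA
#' (`dU_OA = -(intercept + slope * logKOA)` kJ/mol), and `dU_AW`, which is
#' recomputed for consistency. The default axes span the partitioning space
#' occupied by known persistent organic pollutants with margin on all sides.
#'
#' @param logKOA_min,logKOA_max,logKAW_min,logKAW_max Axis bounds (log10).
#' @param step Grid spacing on both axes (log10 units).
#' @param template A one-row chemical tibble supplying non-partitioning fields
#'   (default: a persistent hypothetical chemical, half-lives 1,000 h air /
#'   10,000 h water / 30,000 h soil and sediment).
#' @param dU_OA_intercept,dU_OA_slope Coefficients of the dU_OA(logKOA)
#'   relation, kJ/mol and kJ/mol per log unit.
#' @return A tibble of chemicals, one row per grid node.
#' @examples
#' nrow(chemspace_grid()) # 21 x 15 = 315
#' @export
chemspace_grid <- function(logKOA_min = 4, logKOA_max = 14,
                           logKAW_min = -6, logKAW_max = 1,
                           step = 0.5,
                           template = chemical("template", logKAW = -2, logKOA = 9),
                           dU_OA_intercept = 10, dU_OA_slope = 3.5) {
  if (logKOA_max <= logKOA_min || logKAW_max <= logKAW_min) {
    abort("Axis maxima must exceed minima.")
  }
  if (step <= 0) abort("`step` must be > 0.")
  grid <- tidyr::expand_grid(
    logKOA = seq(logKOA_min, logKOA_max, by = step),
    logKAW = seq(logKAW_min, logKAW_max, by = step)
  )
  if (nrow(grid) == 0) abort("Empty chemical grid.")
  chem <- grid |>
    mutate(
      name = sprintf("KOA%g_KAW%g", .data$logKOA, .data$logKAW),
      logKOW = .data$logKOA + .data$logKAW,
      dU_OW = template$dU_OW,
      dU_OA = -(dU_OA_intercept + dU_OA_slope * .data$logKOA),
      dU_AW = derive_dU_AW(.data$dU_OW, .data$dU_OA),
      dU_A = template$dU_A,
      hl_air_h = template$hl_air_h, hl_water_h = template$hl_water_h,
      hl_soil_h = template$hl_soil_h, hl_sed_h = template$hl_sed_h,
      Ea_air = template$Ea_air, Ea_water = template$Ea_water,
      Ea_soil = template$Ea_soil, Ea_sed = template$Ea_sed,
      T_ref_K = template$T_ref_K
    ) |>
    select(all_of(chem_cols))
  validate_chemicals(chem)
}

#' Reference chemical fixture: PCB-153
#'
#' Partitioning properties, chemical-specific degradation half-lives and
#' phase-change energies for 2,2',4,4',5,5'-hexachlorobiphenyl. Values are
#' conventional literature defaults for this congener and are freely editable
#' through the `chemical()` constructor.
#'
#' @return A one-row chemical tibble.
#' @export
pcb153 <- function() {
  chemical(
    "PCB-153",
    logKAW = -2.0, logKOA = 8.9,
    dU_OW = -20, dU_OA = -80, dU_A = -85,
    hl_air_h = 5500, hl_water_h = 55000, hl_soil_h = 55000, hl_sed_h = 170000,
    Ea_air = 10, Ea_water = 30, Ea_soil = 30, Ea_sed = 30
  )
}

#' Read / write chemical records as CSV
#'
#' The CSV schema is fixed:
#' `name,logKOW,logKAW,logKOA,dU_OW,dU_OA,dU_AW,dU_A,hl_air_h,hl_water_h,hl_soil_h,hl_sed_h,Ea_air,Ea_water,Ea_soil,Ea_sed,T_ref_K`.
#'
#' @param path File path.
#' @param chemicals Tibble of chemical records.
#' @return `read_chemicals()` a validated tibble; `write_chemicals()` the
#'   input, invisibly.
#' @export
read_chemicals <- function(path) {
  chem <- readr::read_csv(path, show_col_types = FALSE)
  validate_chemicals(as_tibble(chem)[, chem_cols])
}

#' @rdname read_chemicals
#' @export
write_chemicals <- function(chemicals, path) {
  readr::write_csv(validate_chemicals(chemicals)[, chem_cols], path)
  invisible(chemicals)
}
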