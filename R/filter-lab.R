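# Gravimetric and black-carbon filter processing.
#
# Mass chain: triplicate weighing -> pre/post mass difference ->
# field-blank median subtraction -> division by sampled volume.
# BC chain: attenuation difference -> blank subtraction -> surface
# loading via the mass absorption cross-section -> filter area ->
# division by sampled volume. ATN follows the transmissometer
# convention ATN = 100*ln(I0/I), under which a loading of 1 ug/cm^2
# corresponds to a blank-corrected ATN equal to the MAC in m^2/g.

#' Laboratory constants
#'
#' Constants of the gravimetric/optical measurement chain: the 880-nm
#' mass absorption cross-section (16.6 m^2/g), the sampled filter area
#' (8.6 cm^2), per-season field-blank medians for mass (2 ug dry, 4 ug
#' wet) and attenuation (2.03 dry, 0.15 wet), and the triplicate weighing
#' acceptance tolerance (3 ug).
#'
#' @param mac Mass absorption cross-section (m^2/g).
#' @param filter_area Sampled filter surface area (cm^2).
#' @param mass_blank Named per-season mass blank medians (ug).
#' @param atn_blank Named per-season attenuation blank medians (ATN).
#' @param weighing_tolerance Maximum triplicate spread (ug).
#' @return A list of class `lab_constants`.
#' @export
lab_constants <- function(mac = 16.6,
                          filter_area = 8.6,
                          mass_blank = c(dry = 2, wet = 4),
                          atn_blank = c(dry = 2.03, wet = 0.15),
                          weighing_tolerance = 3) {
  stopifnot(mac > 0, filter_area > 0, all(mass_blank > 0),
            all(atn_blank >= 0), weighing_tolerance > 0)
  structure(list(mac = mac, filter_area = filter_area,
                 mass_blank = mass_blank, atn_blank = atn_blank,
                 weighing_tolerance = weighing_tolerance),
            class = "lab_constants")
}

#' Accept a triplicate weighing
#'
#' A filter weighing is accepted when the spread (max - min) of three
#' consecutive weights is below the tolerance (default 3 ug), in which
#' case the accepted mass is their mean; otherwise the filter must be
#' re-weighed.
#'
#' @param triplicate Numeric vector of exactly three weights (ug).
#' @param constants A [lab_constants()].
#' @return Accepted mass (ug).
#' @export
accept_weighing <- function(triplicate, constants = lab_constants()) {
  if (length(triplicate) != 3 || any(!is.finite(triplicate)))
    abort("a weighing consists of exactly three finite weights",
          class = "airsound_error_input")
  spread <- max(triplicate) - min(triplicate)
  if (spread >= constants$weighing_tolerance)
    abort(sprintf("triplicate spread %.2f ug >= %g ug: re-weigh required",
                  spread, constants$weighing_tolerance),
          class = "airsound_error_reweigh")
  mean(triplicate)
}

#' Sampled air volume
#'
#' `volume (m^3) = minutes * flow (L/min) * duty cycle / 1000`.
#'
#' @param achieved_minutes Minutes the pump program ran.
#' @param flow_rate Pump flow rate (L/min).
#' @param duty_cycle Fraction of time the pump is on, in (0, 1].
#' @return Sampled volume (m^3).
#' @export
sampled_volume <- function(achieved_minutes, flow_rate = 1.0,
                           duty_cycle = 0.5) {
  if (any(achieved_minutes <= 0))
    abort("achieved_minutes must be positive", class = "airsound_error_input")
  if (any(flow_rate <= 0) || any(duty_cycle <= 0) || any(duty_cycle > 1))
    abort("flow_rate must be > 0 and duty_cycle in (0, 1]",
          class = "airsound_error_input")
  achieved_minutes * flow_rate * duty_cycle / 1000
}

# strict = TRUE flags only genuinely negative values; strict = FALSE also
# flags exact zeros (a blank-corrected mass at or below the blank median
# carries no usable signal and is audited either way).
floor_at_zero <- function(x, strict = TRUE) {
  floored <- if (strict) is.finite(x) & x < 0 else is.finite(x) & x <= 0
  structure(pmax(x, 0), floored = floored)
}

#' Blank-corrected sampled mass
#'
#' Subtracts the season's field-blank median from the pre/post mass
#' difference. Negative corrected masses are floored at zero and flagged
#' (attribute `floored`).
#'
#' @param mass_delta Post minus pre sampled mass (ug), vectorised.
#' @param season `"dry"` or `"wet"` (recycled).
#' @param constants A [lab_constants()].
#' @return Corrected mass (ug) with logical attribute `floored`.
#' @export
blank_corrected_mass <- function(mass_delta, season,
                                 constants = lab_constants()) {
  floor_at_zero(mass_delta - unname(constants$mass_blank[season]),
                strict = FALSE)
}

#' Gravimetric PM2.5 concentration
#'
#' @param corrected_mass Blank-corrected mass (ug).
#' @param volume Sampled volume (m^3).
#' @return Concentration (ug/m^3).
#' @export
gravimetric_concentration <- function(corrected_mass, volume) {
  if (any(volume <= 0))
    abort("sampled volume must be positive", class = "airsound_error_input")
  corrected_mass / volume
}

#' BC surface loading from attenuation
#'
#' Subtracts the season's attenuation blank median and converts the
#' corrected attenuation to a mass surface loading with the mass
#' absorption cross-section: under ATN = 100*ln(I0/I) and a MAC sigma in
#' m^2/g, `loading (ug/cm^2) = ATN_corrected / sigma`. Negative loadings
#' are floored at zero and flagged.
#'
#' @param delta_atn Post minus pre attenuation (ATN units), vectorised.
#' @param season `"dry"` or `"wet"` (recycled).
#' @param constants A [lab_constants()].
#' @return Loading (ug/cm^2) with logical attribute `floored`.
#' @export
bc_loading_from_atn <- function(delta_atn, season,
                                constants = lab_constants()) {
  corrected <- delta_atn - unname(constants$atn_blank[season])
  floor_at_zero(corrected / constants$mac, strict = FALSE)
}

#' BC concentration from surface loading
#'
#' `bc (ug/m^3) = loading (ug/cm^2) * filter area (cm^2) / volume (m^3)`.
#'
#' @param loading BC surface loading (ug/cm^2).
#' @param volume Sampled volume (m^3).
#' @param constants A [lab_constants()].
#' @return BC concentration (ug/m^3).
#' @export
bc_concentration <- function(loading, volume, constants = lab_constants()) {
  if (any(volume <= 0))
    abort("sampled volume must be positive", class = "airsound_error_input")
  loading * constants$filter_area / volume
}

#' Recompute field-blank medians from blank filters
#'
#' @param filters Filter tibble containing `is_blank` rows.
#' @return List with per-season `mass_blank` and `atn_blank` medians.
#' @export
blank_medians <- function(filters) {
  blanks <- filters[filters$is_blank, ]
  if (!nrow(blanks))
    abort("no blank filters present", class = "airsound_error_input")
  pre <- rowMeans(blanks[, c("pre_mass_1", "pre_mass_2", "pre_mass_3")])
  post <- rowMeans(blanks[, c("post_mass_1", "post_mass_2", "post_mass_3")])
  mass <- tapply(post - pre, blanks$season, median)
  atn <- tapply(blanks$post_atn - blanks$pre_atn, blanks$season, median)
  list(mass_blank = mass, atn_blank = atn)
}

#' Process filter records into gravimetric results
#'
#' Runs the full laboratory chain on a filter table: triplicate
#' acceptance (rows failing the spread rule are flagged `reweigh` and
#' yield no concentration), sampled-volume arithmetic from the matched
#' deployment's achieved minutes, blank correction, and the PM and BC
#' concentration formulas. Blank filters are passed through with a
#' `blank` flag and no concentrations.
#'
#' @param filters Filter tibble (schema of [simulate_filter_samples()]).
#' @param deployments Deployment table supplying `achieved_minutes`.
#' @param constants A [lab_constants()]; set
#'   `recompute_blanks = TRUE` to replace its blank medians with medians
#'   over the supplied blank filters.
#' @param recompute_blanks Recompute blank medians from the data.
#' @return Tibble with one row per filter: `filter_id`, `deployment_id`,
#'   `season`, `sampled_volume`, `pm_mass`, `pm_conc`, `bc_loading`,
#'   `bc_conc`, `qc_flags` (semicolon-separated).
#' @export
process_filters <- function(filters, deployments,
                            constants = lab_constants(),
                            recompute_blanks = FALSE) {
  if (recompute_blanks) {
    med <- blank_medians(filters)
    constants$mass_blank[names(med$mass_blank)] <- med$mass_blank
    constants$atn_blank[names(med$atn_blank)] <- med$atn_blank
  }
  dep <- deployments[match(filters$deployment_id, deployments$deployment_id), ]
  if (anyNA(dep$deployment_id))
    abort("filter references an unknown deployment",
          class = "airsound_error_input")

  n <- nrow(filters)
  res <- tibble::tibble(
    filter_id = filters$filter_id,
    deployment_id = filters$deployment_id,
    season = filters$season,
    sampled_volume = NA_real_, pm_mass = NA_real_, pm_conc = NA_real_,
    bc_loading = NA_real_, bc_conc = NA_real_, qc_flags = ""
  )
  add_flag <- function(flags, idx, flag) {
    flags[idx] <- ifelse(flags[idx] == "", flag,
                         paste(flags[idx], flag, sep = ";"))
    flags
  }

  pre_m <- as.matrix(filters[, c("pre_mass_1", "pre_mass_2", "pre_mass_3")])
  post_m <- as.matrix(filters[, c("post_mass_1", "post_mass_2", "post_mass_3")])
  spread_ok <- function(m) {
    apply(m, 1, function(w) max(w) - min(w)) < constants$weighing_tolerance
  }
  ok <- spread_ok(pre_m) & spread_ok(post_m)
  res$qc_flags <- add_flag(res$qc_flags, !ok, "reweigh")

  blank <- filters$is_blank
  res$qc_flags <- add_flag(res$qc_flags, blank, "blank")

  use <- ok & !blank
  if (any(use)) {
    vol <- sampled_volume(dep$achieved_minutes[use],
                          filters$flow_rate[use], filters$duty_cycle[use])
    delta <- rowMeans(post_m[use, , drop = FALSE]) -
      rowMeans(pre_m[use, , drop = FALSE])
    pm_mass <- blank_corrected_mass(delta, filters$season[use], constants)
    loading <- bc_loading_from_atn(filters$post_atn[use] - filters$pre_atn[use],
                                   filters$season[use], constants)
    res$sampled_volume[use] <- vol
    res$pm_mass[use] <- as.numeric(pm_mass)
    res$pm_conc[use] <- gravimetric_concentration(as.numeric(pm_mass), vol)
    res$bc_loading[use] <- as.numeric(loading)
    res$bc_conc[use] <- bc_concentration(as.numeric(loading), vol, constants)

    floored <- rep(FALSE, n)
    floored[use] <- attr(pm_mass, "floored") | attr(loading, "floored")
    res$qc_flags <- add_flag(res$qc_flags, floored, "floored")
  }
  res
}
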