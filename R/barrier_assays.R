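#' Transepithelial electrical resistance (TER) with blank correction
#'
#' The mean resistance of bare filters (no cells) is subtracted from each
#' cell-filter reading and the difference is multiplied by the growth area
#' of the filter:
#' \deqn{TER = (R_{cell} - \bar R_{blank}) \times A \quad [\Omega\,cm^2]}
#' A reading below the blank mean yields a negative TER, which is reported
#' as-is with a warning flag rather than clamped — it usually indicates a
#' damaged monolayer or a mis-read blank.
#'
#' @param cell_resistances Resistances of filters with cells, Ohm.
#' @param blank_resistances Resistances of bare filters, Ohm (>= 1 reading).
#' @param area_cm2 Growth area of the filter, cm^2 (default 1.12, the
#'   nominal area of a 12-mm insert).
#' @return An object of class `ter_result`: data.frame `per_filter`
#'   (`resistance_ohm`, `ter`, `negative_flag`), `mean_ter`, `sd_ter`
#'   (`NA` when a single filter), `area_cm2`, `blank_mean_ohm`.
#' @examples
#' compute_ter(500, c(100, 100, 100), area_cm2 = 1.12)$mean_ter  # 448
#' @export
compute_ter <- function(cell_resistances, blank_resistances,
                        area_cm2 = 1.12) {
  check_scalar(area_cm2, "area_cm2", positive = TRUE)
  if (length(cell_resistances) == 0L || !is.numeric(cell_resistances)) {
    stop_epibarrier("epibarrier_data_error", "no cell resistances supplied")
  }
  if (length(blank_resistances) == 0L || !is.numeric(blank_resistances)) {
    stop_epibarrier("epibarrier_data_error", "at least one blank reading is required")
  }
  blank_mean <- mean(blank_resistances)
  ter <- (cell_resistances - blank_mean) * area_cm2
  if (any(ter < 0)) {
    warning("blank-corrected resistance is negative for ",
            sum(ter < 0), " filter(s)", call. = FALSE)
  }
  structure(list(
    per_filter = data.frame(resistance_ohm = cell_resistances, ter = ter,
                            negative_flag = ter < 0),
    mean_ter = mean(ter),
    sd_ter = if (length(ter) > 1L) sd(ter) else NA_real_,
    area_cm2 = area_cm2, blank_mean_ohm = blank_mean
  ), class = "ter_result")
}

#' Geometry and dosing of a Transwell tracer-flux assay
#'
#' Defaults reflect a standard 12-mm insert protocol: 1.12 cm^2 growth area,
#' 250 ul apical dose of 200 uM tracer, 1 ml basal chamber, 2 h incubation.
#' `initial_concentration` is in mol cm^-3 (200 uM = 2e-7 mol cm^-3) so that
#' Papp comes out directly in cm s^-1.
#'
#' @param area_cm2 Filter growth area, cm^2.
#' @param apical_volume_ml Apical (donor) volume, ml.
#' @param basal_volume_ml Basal (receiver) volume, ml.
#' @param initial_concentration Tracer concentration dosed apically,
#'   mol cm^-3.
#' @param duration_s Incubation time, seconds.
#' @return An object of class `flux_geometry`.
#' @export
flux_geometry <- function(area_cm2 = 1.12, apical_volume_ml = 0.25,
                          basal_volume_ml = 1.0,
                          initial_concentration = 2e-7,
                          duration_s = 7200) {
  for (nm in c("area_cm2", "apical_volume_ml", "basal_volume_ml",
               "initial_concentration", "duration_s")) {
    check_scalar(get(nm), nm, positive = TRUE,
                 subclass = "epibarrier_domain_error")
  }
  structure(list(area_cm2 = area_cm2, apical_volume_ml = apical_volume_ml,
                 basal_volume_ml = basal_volume_ml,
                 initial_concentration = initial_concentration,
                 duration_s = duration_s),
            class = "flux_geometry")
}

#' Convert a blank-corrected fluorescence intensity to transported amount
#'
#' The tracer amount dQ that reached the basal chamber is reconstructed from
#' the reader intensity through a single linear calibration factor
#' (intensity units per mol cm^-3 of tracer in the read medium):
#' \deqn{dQ = \max(0, I - I_{blank}) / k \times V_{basal} \quad [mol]}
#' Negative blank-corrected intensities — noise below the detection limit —
#' clamp to zero with a warning so permeabilities cannot go negative.
#'
#' @param intensity Sample intensity (vectorised), arbitrary units.
#' @param blank_intensity Intensity of tracer-free medium, same units.
#' @param calibration Intensity units per mol cm^-3.
#' @param basal_volume_ml Receiver-chamber volume, ml (1 ml = 1 cm^3).
#' @return Transported amount(s), mol.
#' @export
intensity_to_amount <- function(intensity, blank_intensity, calibration,
                                basal_volume_ml = 1.0) {
  check_scalar(calibration, "calibration", positive = TRUE)
  check_scalar(basal_volume_ml, "basal_volume_ml", positive = TRUE)
  corrected <- intensity - blank_intensity
  if (any(corrected < 0)) {
    warning(sum(corrected < 0),
            " intensity reading(s) below blank clamped to zero",
            call. = FALSE)
    corrected <- pmax(corrected, 0)
  }
  corrected / calibration * basal_volume_ml
}

#' Apparent permeability (Papp) from tracer flux
#'
#' \deqn{P_{app} = \frac{dQ/dt}{A\,C_o} \quad [cm\,s^{-1}]}
#' where dQ is the tracer amount transported to the basal chamber over the
#' incubation time dt, A the filter area, and Co the initial apical tracer
#' concentration. Assumes sink conditions (no back-flux or apical depletion
#' correction) over the incubation window.
#'
#' @param sample_intensities Per-filter basal-medium intensities, arbitrary
#'   units, or pass `dq_mol` directly.
#' @param blank_intensity Intensity of tracer-free medium.
#' @param calibration Intensity units per mol cm^-3 (see
#'   [intensity_to_amount()]).
#' @param geometry A [flux_geometry()].
#' @param dq_mol Optional: transported amounts in mol, bypassing the
#'   intensity conversion.
#' @return An object of class `papp_result`: data.frame `per_filter`
#'   (`dq_mol`, `papp`), `mean_papp`, `sd_papp` (`NA` for one filter).
#' @examples
#' compute_papp(dq_mol = 2e-9,
#'              geometry = flux_geometry(area_cm2 = 1.12))$mean_papp
#' @export
compute_papp <- function(sample_intensities = NULL, blank_intensity = NULL,
                         calibration = NULL, geometry = flux_geometry(),
                         dq_mol = NULL) {
  stopifnot(inherits(geometry, "flux_geometry"))
  if (is.null(dq_mol)) {
    if (is.null(sample_intensities) || is.null(blank_intensity) ||
        is.null(calibration)) {
      stop_epibarrier("epibarrier_config_error",
                      "supply either dq_mol or intensities with a blank and calibration")
    }
    dq_mol <- intensity_to_amount(sample_intensities, blank_intensity,
                                  calibration, geometry$basal_volume_ml)
  }
  papp <- (dq_mol / geometry$duration_s) /
          (geometry$area_cm2 * geometry$initial_concentration)
  structure(list(
    per_filter = data.frame(dq_mol = dq_mol, papp = papp),
    mean_papp = mean(papp),
    sd_papp = if (length(papp) > 1L) sd(papp) else NA_real_,
    geometry = geometry
  ), class = "papp_result")
}
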