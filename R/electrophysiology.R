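#' Physical constants for the GHK voltage equation
#'
#' CODATA values of the molar gas constant and the Faraday constant. These
#' enter only the Goldman-Hodgkin-Katz (GHK) computations, where the thermal
#' voltage RT/F sets the millivolt scale of dilution potentials.
#'
#' @param R Molar gas constant, J mol^-1 K^-1.
#' @param faraday Faraday constant, C mol^-1.
#' @return An object of class `physical_constants`.
#' @export
physical_constants <- function(R = 8.314462618, faraday = 96485.33212) {
  check_scalar(R, "R", positive = TRUE)
  check_scalar(faraday, "faraday", positive = TRUE)
  structure(list(R = R, faraday = faraday), class = "physical_constants")
}

#' NaCl bath composition on the two sides of an epithelium
#'
#' Describes the apical and basolateral NaCl concentrations during a
#' dilution-potential measurement. The default is the standard dilution
#' protocol: 150 mM NaCl basolateral, 75 mM NaCl apical (osmotically
#' balanced with mannitol, which carries no charge and is ignored), at
#' 37 degrees C.
#'
#' @param na_apical,cl_apical Apical Na+ and Cl- concentrations, mM.
#' @param na_basolateral,cl_basolateral Basolateral concentrations, mM.
#' @param temperature Absolute temperature, K.
#' @return An object of class `solution_pair`.
#' @export
solution_pair <- function(na_apical = 75, cl_apical = 75,
                          na_basolateral = 150, cl_basolateral = 150,
                          temperature = 310.15) {
  for (nm in c("na_apical", "cl_apical", "na_basolateral", "cl_basolateral",
               "temperature")) {
    check_scalar(get(nm), nm, positive = TRUE,
                 subclass = "epibarrier_domain_error")
  }
  structure(list(na_apical = na_apical, cl_apical = cl_apical,
                 na_basolateral = na_basolateral,
                 cl_basolateral = cl_basolateral,
                 temperature = temperature),
            class = "solution_pair")
}

#' Limiting molar ionic conductivities of Na+ and Cl-
#'
#' Free-solution mobilities (molar ionic conductivities) used to define the
#' permeability ratio of a simple pore with no charge selectivity. Defaults
#' are the tabulated aqueous values: Na+ 50.11 and Cl- 75.23 S cm^2 eq^-1.
#'
#' @param na_mobility,cl_mobility Molar ionic conductivities, S cm^2 eq^-1.
#' @return An object of class `ion_mobilities`.
#' @export
ion_mobilities <- function(na_mobility = 50.11, cl_mobility = 75.23) {
  check_scalar(na_mobility, "na_mobility", positive = TRUE,
               subclass = "epibarrier_domain_error")
  check_scalar(cl_mobility, "cl_mobility", positive = TRUE,
               subclass = "epibarrier_domain_error")
  structure(list(na_mobility = na_mobility, cl_mobility = cl_mobility),
            class = "ion_mobilities")
}

# thermal voltage RT/F in millivolts
thermal_voltage_mV <- function(temperature, constants) {
  1000 * constants$R * temperature / constants$faraday
}

#' Transepithelial conductance from a voltage/current pair
#'
#' Applies Ohm's law to a single open-circuit voltage deflection and the
#' corresponding current, normalised by the exposed membrane area. With
#' voltage in mV and current in uA the ratio I/V is already in mS, so
#' G_t = (I/V)/area is in mS cm^-2.
#'
#' @param voltage_mV Voltage deflection, mV.
#' @param current_uA Current, uA. Must have the same sign as the voltage.
#' @param area_cm2 Exposed membrane area, cm^2.
#' @return An object of class `conductance_record` with element `g_t`
#'   (mS cm^-2).
#' @examples
#' conductance_from_iv(1, 1, 1)$g_t  # 1 mS cm^-2
#' @export
conductance_from_iv <- function(voltage_mV, current_uA, area_cm2) {
  check_scalar(area_cm2, "area_cm2", positive = TRUE)
  check_scalar(voltage_mV, "voltage_mV")
  check_scalar(current_uA, "current_uA")
  if (current_uA == 0) {
    g <- 0
  } else {
    if (voltage_mV == 0) {
      stop_epibarrier("epibarrier_measurement_error",
                      "nonzero current at zero voltage: short circuit")
    }
    g <- (current_uA / voltage_mV) / area_cm2
    if (g < 0) {
      stop_epibarrier("epibarrier_measurement_error",
                      "voltage and current have opposite signs")
    }
  }
  structure(list(voltage_mV = voltage_mV, current_uA = current_uA,
                 area_cm2 = area_cm2, g_t = g),
            class = "conductance_record")
}

#' Blank-correct a measured dilution potential
#'
#' The potential measured across a bare filter (no cells) under the same
#' dilution is subtracted from the raw potential, removing the filter's
#' contribution. Vectorised over `raw_mV`.
#'
#' @param raw_mV Measured potential(s), mV.
#' @param blank_mV Blank-filter potential, mV (single value).
#' @return A data.frame with columns `raw_mV`, `blank_mV`, `corrected_mV`.
#' @export
correct_blank <- function(raw_mV, blank_mV) {
  if (!is.numeric(raw_mV) || !is.numeric(blank_mV) || length(blank_mV) != 1L) {
    stop_epibarrier("epibarrier_config_error",
                    "'raw_mV' must be numeric and 'blank_mV' a single number")
  }
  data.frame(raw_mV = raw_mV, blank_mV = blank_mV,
             corrected_mV = raw_mV - blank_mV)
}

#' Forward GHK dilution potential for a NaCl gradient
#'
#' Computes the transepithelial potential predicted by the
#' Goldman-Hodgkin-Katz voltage equation for a monovalent NaCl dilution,
#' given the permeability ratio beta = P_Na/P_Cl:
#'
#' \deqn{V = (RT/F)\,\ln\frac{\beta\,[Na]_{ap} + [Cl]_{bl}}
#'                           {\beta\,[Na]_{bl} + [Cl]_{ap}}}
#'
#' The sign convention is fixed by the physiology: with the apical side
#' diluted, a cation-selective epithelium (beta > 1) gives a negative
#' potential and an anion-selective one (beta < 1) a positive potential;
#' beta = 1 gives exactly 0 mV. V is strictly decreasing in beta and
#' approaches the Na+ and Cl- Nernst potentials as beta tends to infinity
#' or zero.
#'
#' @param p_ratio P_Na/P_Cl, dimensionless, > 0. Vectorised.
#' @param bath A [solution_pair()].
#' @param constants A [physical_constants()].
#' @return Potential(s) in mV.
#' @examples
#' ghk_dilution_potential(1)            # 0 mV
#' ghk_dilution_potential(2)            # negative: cation-selective
#' @export
ghk_dilution_potential <- function(p_ratio, bath = solution_pair(),
                                   constants = physical_constants()) {
  if (!is.numeric(p_ratio) || any(!is.finite(p_ratio)) || any(p_ratio <= 0)) {
    stop_epibarrier("epibarrier_domain_error",
                    "'p_ratio' must be positive and finite")
  }
  stopifnot(inherits(bath, "solution_pair"))
  vt <- thermal_voltage_mV(bath$temperature, constants)
  vt * log((p_ratio * bath$na_apical + bath$cl_basolateral) /
           (p_ratio * bath$na_basolateral + bath$cl_apical))
}

# Nernst limits of the dilution potential (mV): the potentials approached as
# P_Na/P_Cl tends to +Inf (pure Na+ electrode) and 0 (pure Cl- electrode)
nernst_limits_mV <- function(bath, constants = physical_constants()) {
  vt <- thermal_voltage_mV(bath$temperature, constants)
  c(na = vt * log(bath$na_apical / bath$na_basolateral),
    cl = vt * log(bath$cl_basolateral / bath$cl_apical))
}

#' Invert a dilution potential to the P_Na/P_Cl permeability ratio
#'
#' Closed-form inverse of [ghk_dilution_potential()]: writing
#' E = exp(VF/RT), the GHK expression is linear in beta = P_Na/P_Cl, giving
#'
#' \deqn{\beta = \frac{E\,[Cl]_{ap} - [Cl]_{bl}}{[Na]_{ap} - E\,[Na]_{bl}}}
#'
#' A positive ratio exists only for potentials strictly between the two
#' Nernst limits of the bath; values at or beyond a limit raise an
#' out-of-range error. The returned ratio is classified against the
#' neutral-pore baseline (see [classify_selectivity()]).
#'
#' @param corrected_mV Blank-corrected dilution potential, mV (single value).
#' @param bath A [solution_pair()].
#' @param constants A [physical_constants()].
#' @param mobilities An [ion_mobilities()] used for the selectivity class.
#' @return An object of class `permeability_result` with elements
#'   `p_na_over_p_cl`, `p_cl_over_p_na`, `selectivity`
#'   (`"cation"`, `"anion"`, or `"neutral"`), and `corrected_potential_mV`.
#' @examples
#' pna_pcl_from_dilution(0)$p_na_over_p_cl   # exactly 1
#' @export
pna_pcl_from_dilution <- function(corrected_mV, bath = solution_pair(),
                                  constants = physical_constants(),
                                  mobilities = ion_mobilities()) {
  check_scalar(corrected_mV, "corrected_mV",
               subclass = "epibarrier_domain_error")
  stopifnot(inherits(bath, "solution_pair"))
  lim <- nernst_limits_mV(bath, constants)
  lo <- min(lim); hi <- max(lim)
  if (corrected_mV <= lo || corrected_mV >= hi) {
    stop_epibarrier(
      "epibarrier_range_error",
      sprintf(paste0("potential %.3f mV is at or beyond the Nernst limits ",
                     "(%.3f, %.3f) mV: no positive P_Na/P_Cl exists"),
              corrected_mV, lo, hi))
  }
  vt <- thermal_voltage_mV(bath$temperature, constants)
  E <- exp(corrected_mV / vt)
  ratio <- (E * bath$cl_apical - bath$cl_basolateral) /
           (bath$na_apical - E * bath$na_basolateral)
  structure(list(
    p_na_over_p_cl = ratio,
    p_cl_over_p_na = 1 / ratio,
    selectivity = classify_selectivity(ratio, mobilities),
    corrected_potential_mV = corrected_mV
  ), class = "permeability_result")
}

#' Permeability ratio of a neutral pore
#'
#' The P_Na/P_Cl expected through a simple aqueous pore with no charge
#' selectivity equals the ratio of the free-solution mobilities of the two
#' ions. With the tabulated conductivities (Na+ 50.11, Cl- 75.23
#' S cm^2 eq^-1) the baseline is 50.11/75.23 = 0.666..., conventionally
#' quoted as 0.66. Epithelia above this baseline are cation-selective,
#' below it anion-selective.
#'
#' @param mobilities An [ion_mobilities()].
#' @return The dimensionless ratio na_mobility / cl_mobility.
#' @examples
#' neutral_pore_ratio()  # 0.666...
#' @export
neutral_pore_ratio <- function(mobilities = ion_mobilities()) {
  stopifnot(inherits(mobilities, "ion_mobilities"))
  mobilities$na_mobility / mobilities$cl_mobility
}

#' Classify permselectivity against the neutral-pore baseline
#'
#' @param result A `permeability_result` or a bare numeric P_Na/P_Cl ratio.
#' @param mobilities An [ion_mobilities()] defining the baseline.
#' @param tol Relative tolerance within which the ratio is called neutral.
#' @return `"cation"`, `"anion"`, or `"neutral"`.
#' @export
classify_selectivity <- function(result, mobilities = ion_mobilities(),
                                 tol = 1e-6) {
  ratio <- if (inherits(result, "permeability_result")) {
    result$p_na_over_p_cl
  } else {
    result
  }
  check_scalar(ratio, "p_na_over_p_cl", positive = TRUE,
               subclass = "epibarrier_domain_error")
  baseline <- neutral_pore_ratio(mobilities)
  if (abs(ratio - baseline) <= tol * baseline) {
    "neutral"
  } else if (ratio > baseline) {
    "cation"
  } else {
    "anion"
  }
}

#' Summarise Ussing-chamber runs per group
#'
#' Takes a table of chamber records (cell filters plus at least one blank
#' filter), blank-corrects each cell potential with the mean blank potential,
#' inverts each corrected potential to P_Na/P_Cl, computes transepithelial
#' conductance from each record's voltage/current pair, and reports the
#' per-group mean and SD of each quantity. SD is `NA` for groups with a
#' single record rather than a spurious 0.
#'
#' @param runs A data.frame with columns `kind` (`"cell"` or `"blank"`),
#'   `potential_mV`, `voltage_mV`, `current_uA`, and optionally `group`
#'   (single group assumed if absent) and `record_id`.
#' @param bath A [solution_pair()].
#' @param area_cm2 Exposed chamber-window area, cm^2.
#' @param constants A [physical_constants()].
#' @param mobilities An [ion_mobilities()].
#' @return A data.frame with one row per group: `group`, `n`,
#'   `mean_corrected_mV`, `sd_corrected_mV`, `mean_pna_pcl`, `sd_pna_pcl`,
#'   `selectivity`, `mean_gt`, `sd_gt`.
#' @export
summarize_runs <- function(runs, bath = solution_pair(), area_cm2 = 0.0707,
                           constants = physical_constants(),
                           mobilities = ion_mobilities()) {
  need <- c("kind", "potential_mV", "voltage_mV", "current_uA")
  if (!is.data.frame(runs) || !all(need %in% names(runs))) {
    stop_epibarrier("epibarrier_data_error",
                    sprintf("'runs' must be a data.frame with columns %s",
                            paste(need, collapse = ", ")))
  }
  blanks <- runs[runs$kind == "blank", , drop = FALSE]
  cells <- runs[runs$kind == "cell", , drop = FALSE]
  if (nrow(blanks) == 0L) {
    stop_epibarrier("epibarrier_data_error", "no blank record in 'runs'")
  }
  if (nrow(cells) == 0L) {
    stop_epibarrier("epibarrier_data_error", "no cell records in 'runs'")
  }
  blank_mV <- mean(blanks$potential_mV)
  if (is.null(cells$group)) cells$group <- "all"
  sd_or_na <- function(x) if (length(x) > 1L) sd(x) else NA_real_
  out <- lapply(split(cells, cells$group), function(g) {
    corr <- g$potential_mV - blank_mV
    ratios <- vapply(corr, function(v) {
      pna_pcl_from_dilution(v, bath, constants, mobilities)$p_na_over_p_cl
    }, numeric(1))
    gts <- vapply(seq_len(nrow(g)), function(i) {
      conductance_from_iv(g$voltage_mV[i], g$current_uA[i], area_cm2)$g_t
    }, numeric(1))
    data.frame(
      group = g$group[1L], n = nrow(g),
      mean_corrected_mV = mean(corr), sd_corrected_mV = sd_or_na(corr),
      mean_pna_pcl = mean(ratios), sd_pna_pcl = sd_or_na(ratios),
      selectivity = classify_selectivity(mean(ratios), mobilities),
      mean_gt = mean(gts), sd_gt = sd_or_na(gts),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
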