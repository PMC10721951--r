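# Seeded synthetic-data generators. Each forward model is the exact inverse
# of its analysis stage, so with noise set to zero every generator round-trips
# to the true parameters. All randomness is confined to a local RNG scope so
# generation never disturbs the caller's random stream.

with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_epibarrier("epibarrier_config_error", "'seed' must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Configuration for a synthetic bimodal expression table
#'
#' Describes the generative model the activity caller assumes: a fraction of
#' genes with exactly zero expression in both channels, and the rest drawn
#' as 2^x with x from an "active" (higher-mean) or "inactive" (lower-mean)
#' Gaussian in log2 space. The FPKM channel is `fpkm_scale` times the TPM
#' channel with a small lognormal jitter, so the two channels can agree or
#' disagree controllably.
#'
#' Defaults emulate a typical bulk RNA-seq density: ~20,000 genes, a fifth
#' of them silent, the active mode near log2 = 5 and the inactive mode near
#' 0, each with unit-scale spread.
#'
#' @param n_genes Number of genes.
#' @param active_fraction Proportion of non-zero genes in the active
#'   component, in (0, 1).
#' @param mu_active,sd_active Mean/SD of the active component, log2 units.
#' @param mu_inactive,sd_inactive Mean/SD of the inactive component.
#' @param zero_fraction Proportion of genes with exactly-zero expression,
#'   in \[0, 1).
#' @param fpkm_scale Multiplicative factor relating FPKM to TPM.
#' @param fpkm_jitter_sd SD of the lognormal jitter on the FPKM channel
#'   (natural-log scale); 0 makes the channels exactly proportional.
#' @param seed Integer seed.
#' @return An object of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes = 20000, active_fraction = 0.55,
                                  mu_active = 5, sd_active = 1.5,
                                  mu_inactive = 0, sd_inactive = 1.0,
                                  zero_fraction = 0.2, fpkm_scale = 1.0,
                                  fpkm_jitter_sd = 0.05, seed = 1) {
  check_scalar(n_genes, "n_genes", positive = TRUE)
  if (n_genes != round(n_genes)) {
    stop_epibarrier("epibarrier_config_error", "'n_genes' must be an integer")
  }
  check_scalar(active_fraction, "active_fraction")
  if (active_fraction <= 0 || active_fraction >= 1) {
    stop_epibarrier("epibarrier_config_error",
                    "'active_fraction' must lie strictly in (0, 1)")
  }
  check_scalar(sd_active, "sd_active", positive = TRUE)
  check_scalar(sd_inactive, "sd_inactive", positive = TRUE)
  check_scalar(mu_active, "mu_active")
  check_scalar(mu_inactive, "mu_inactive")
  if (mu_active <= mu_inactive) {
    stop_epibarrier("epibarrier_config_error",
                    "'mu_active' must exceed 'mu_inactive'")
  }
  check_scalar(zero_fraction, "zero_fraction", nonnegative = TRUE)
  if (zero_fraction >= 1) {
    stop_epibarrier("epibarrier_config_error", "'zero_fraction' must be < 1")
  }
  check_scalar(fpkm_scale, "fpkm_scale", positive = TRUE)
  check_scalar(fpkm_jitter_sd, "fpkm_jitter_sd", nonnegative = TRUE)
  structure(list(n_genes = as.integer(n_genes),
                 active_fraction = active_fraction,
                 mu_active = mu_active, sd_active = sd_active,
                 mu_inactive = mu_inactive, sd_inactive = sd_inactive,
                 zero_fraction = zero_fraction, fpkm_scale = fpkm_scale,
                 fpkm_jitter_sd = fpkm_jitter_sd, seed = seed),
            class = "expression_sim_config")
}

#' Simulate a gene-level expression table with truth labels
#'
#' @param config An [expression_sim_config()].
#' @return A data.frame with columns `gene_id`, `tpm`, `fpkm`,
#'   `truth_label` (`"active"`, `"inactive"`, or `"zero"`); exactly
#'   `n_genes` rows; identical seed gives an identical table.
#' @export
simulate_expression_table <- function(config = expression_sim_config()) {
  stopifnot(inherits(config, "expression_sim_config"))
  with_local_seed(config$seed, {
    n <- config$n_genes
    n_zero <- round(config$zero_fraction * n)
    n_expr <- n - n_zero
    is_active <- rbinom(n_expr, 1L, config$active_fraction) == 1L
    x <- ifelse(is_active,
                rnorm(n_expr, config$mu_active, config$sd_active),
                rnorm(n_expr, config$mu_inactive, config$sd_inactive))
    tpm_expr <- 2^x
    jitter <- if (config$fpkm_jitter_sd > 0) {
      exp(rnorm(n_expr, 0, config$fpkm_jitter_sd))
    } else 1
    fpkm_expr <- config$fpkm_scale * tpm_expr * jitter
    tab <- data.frame(
      tpm = c(tpm_expr, rep(0, n_zero)),
      fpkm = c(fpkm_expr, rep(0, n_zero)),
      truth_label = c(ifelse(is_active, "active", "inactive"),
                      rep("zero", n_zero)),
      stringsAsFactors = FALSE
    )
    tab <- tab[sample.int(n), , drop = FALSE]
    tab <- cbind(gene_id = sprintf("gene_%05d", seq_len(n)), tab)
    rownames(tab) <- NULL
    tab
  })
}

#' Configuration for synthetic Ussing-chamber runs
#'
#' The forward model is [ghk_dilution_potential()]: each cell record's
#' measured potential is the GHK potential of `true_ratio` under `bath`,
#' plus the blank-filter offset and additive Gaussian noise. Voltage/current
#' pairs are consistent with the stated areal conductance through Ohm's law.
#'
#' @param true_ratio True P_Na/P_Cl (> 0).
#' @param conductance Transepithelial conductance, mS cm^-2.
#' @param potential_noise_sd SD of the additive potential noise, mV.
#' @param blank_potential Blank-filter dilution potential, mV.
#' @param n_replicates Number of cell records.
#' @param bath A [solution_pair()].
#' @param area_cm2 Exposed chamber-window area, cm^2 (default 0.0707, a
#'   3-mm circular window).
#' @param pulse_mV Voltage deflection used for the Ohm's-law pair, mV.
#' @param seed Integer seed.
#' @return An object of class `ussing_sim_config`.
#' @export
ussing_sim_config <- function(true_ratio = 1, conductance = 10,
                              potential_noise_sd = 0.2,
                              blank_potential = -0.3, n_replicates = 4,
                              bath = solution_pair(), area_cm2 = 0.0707,
                              pulse_mV = 1.0, seed = 1) {
  check_scalar(true_ratio, "true_ratio", positive = TRUE,
               subclass = "epibarrier_domain_error")
  check_scalar(conductance, "conductance", nonnegative = TRUE)
  check_scalar(potential_noise_sd, "potential_noise_sd", nonnegative = TRUE)
  check_scalar(blank_potential, "blank_potential")
  check_scalar(n_replicates, "n_replicates", positive = TRUE)
  if (n_replicates != round(n_replicates)) {
    stop_epibarrier("epibarrier_config_error",
                    "'n_replicates' must be an integer")
  }
  check_scalar(area_cm2, "area_cm2", positive = TRUE)
  check_scalar(pulse_mV, "pulse_mV", positive = TRUE)
  stopifnot(inherits(bath, "solution_pair"))
  structure(list(true_ratio = true_ratio, conductance = conductance,
                 potential_noise_sd = potential_noise_sd,
                 blank_potential = blank_potential,
                 n_replicates = as.integer(n_replicates), bath = bath,
                 area_cm2 = area_cm2, pulse_mV = pulse_mV, seed = seed),
            class = "ussing_sim_config")
}

#' Simulate dilution-potential and voltage/current records
#'
#' @param config An [ussing_sim_config()].
#' @return A data.frame with `n_replicates` cell records plus one blank
#'   record: columns `record_id`, `kind` (`"cell"`/`"blank"`),
#'   `potential_mV`, `voltage_mV`, `current_uA` (`NA` for the blank).
#' @export
simulate_ussing_runs <- function(config = ussing_sim_config()) {
  stopifnot(inherits(config, "ussing_sim_config"))
  with_local_seed(config$seed, {
    n <- config$n_replicates
    true_mV <- ghk_dilution_potential(config$true_ratio, config$bath)
    noise <- if (config$potential_noise_sd > 0) {
      rnorm(n, 0, config$potential_noise_sd)
    } else rep(0, n)
    current <- config$conductance * config$area_cm2 * config$pulse_mV
    cells <- data.frame(
      record_id = sprintf("cell_%02d", seq_len(n)), kind = "cell",
      potential_mV = true_mV + config$blank_potential + noise,
      voltage_mV = config$pulse_mV, current_uA = current,
      stringsAsFactors = FALSE
    )
    blank <- data.frame(record_id = "blank_01", kind = "blank",
                        potential_mV = config$blank_potential,
                        voltage_mV = NA_real_, current_uA = NA_real_,
                        stringsAsFactors = FALSE)
    rbind(cells, blank)
  })
}

#' Configuration for a synthetic Transwell plate assay
#'
#' Forward models are [compute_ter()] and [compute_papp()]: each cell
#' filter's resistance is the blank mean plus `true_ter / area` plus noise,
#' and the basal-chamber intensity is the blank intensity plus
#' `fluorescence_gain` times the tracer concentration produced by
#' `true_papp` over the incubation, plus noise.
#'
#' @param true_ter True TER, Ohm cm^2.
#' @param blank_resistance_mean,blank_resistance_sd Bare-filter resistance
#'   distribution, Ohm.
#' @param cell_resistance_sd SD of the cell-filter resistance noise, Ohm.
#' @param true_papp True apparent permeability, cm s^-1.
#' @param geometry A [flux_geometry()].
#' @param fluorescence_gain Intensity units per mol cm^-3.
#' @param blank_intensity Intensity of tracer-free medium, arbitrary units.
#' @param intensity_noise_sd SD of the intensity noise.
#' @param n_filters Number of cell filters.
#' @param n_blanks Number of bare filters / blank wells.
#' @param seed Integer seed.
#' @return An object of class `plate_sim_config`.
#' @export
plate_sim_config <- function(true_ter = 500, blank_resistance_mean = 100,
                             blank_resistance_sd = 2,
                             cell_resistance_sd = 5,
                             true_papp = 1e-6, geometry = flux_geometry(),
                             fluorescence_gain = 1e10,
                             blank_intensity = 50,
                             intensity_noise_sd = 1, n_filters = 3,
                             n_blanks = 3, seed = 1) {
  check_scalar(true_ter, "true_ter", nonnegative = TRUE)
  check_scalar(blank_resistance_mean, "blank_resistance_mean",
               nonnegative = TRUE)
  check_scalar(blank_resistance_sd, "blank_resistance_sd", nonnegative = TRUE)
  check_scalar(cell_resistance_sd, "cell_resistance_sd", nonnegative = TRUE)
  check_scalar(true_papp, "true_papp", nonnegative = TRUE)
  check_scalar(fluorescence_gain, "fluorescence_gain", positive = TRUE)
  check_scalar(blank_intensity, "blank_intensity", nonnegative = TRUE)
  check_scalar(intensity_noise_sd, "intensity_noise_sd", nonnegative = TRUE)
  check_scalar(n_filters, "n_filters", positive = TRUE)
  check_scalar(n_blanks, "n_blanks", positive = TRUE)
  stopifnot(inherits(geometry, "flux_geometry"))
  structure(list(true_ter = true_ter,
                 blank_resistance_mean = blank_resistance_mean,
                 blank_resistance_sd = blank_resistance_sd,
                 cell_resistance_sd = cell_resistance_sd,
                 true_papp = true_papp, geometry = geometry,
                 fluorescence_gain = fluorescence_gain,
                 blank_intensity = blank_intensity,
                 intensity_noise_sd = intensity_noise_sd,
                 n_filters = as.integer(n_filters),
                 n_blanks = as.integer(n_blanks), seed = seed),
            class = "plate_sim_config")
}

#' Simulate a Transwell resistance table and flux table
#'
#' @param config A [plate_sim_config()].
#' @return A list of two data.frames: `resistance` (`filter_id`, `kind`,
#'   `resistance_ohm`) and `flux` (`filter_id`, `kind`, `intensity_au`),
#'   each containing cell filters and blank records.
#' @export
simulate_plate_assay <- function(config = plate_sim_config()) {
  stopifnot(inherits(config, "plate_sim_config"))
  with_local_seed(config$seed, {
    geom <- config$geometry
    n <- config$n_filters
    blanks_r <- config$blank_resistance_mean +
      if (config$blank_resistance_sd > 0) {
        rnorm(config$n_blanks, 0, config$blank_resistance_sd)
      } else rep(0, config$n_blanks)
    cells_r <- config$blank_resistance_mean + config$true_ter / geom$area_cm2 +
      if (config$cell_resistance_sd > 0) {
        rnorm(n, 0, config$cell_resistance_sd)
      } else rep(0, n)
    resistance <- data.frame(
      filter_id = c(sprintf("filter_%02d", seq_len(n)),
                    sprintf("blank_%02d", seq_len(config$n_blanks))),
      kind = c(rep("cell", n), rep("blank", config$n_blanks)),
      resistance_ohm = c(cells_r, blanks_r),
      stringsAsFactors = FALSE
    )
    # forward flux model: dQ = Papp * A * Co * dt; basal concentration in
    # mol cm^-3 maps to intensity through the linear gain
    dq <- config$true_papp * geom$area_cm2 * geom$initial_concentration *
          geom$duration_s
    conc_basal <- dq / geom$basal_volume_ml
    cells_i <- config$blank_intensity + config$fluorescence_gain * conc_basal +
      if (config$intensity_noise_sd > 0) {
        rnorm(n, 0, config$intensity_noise_sd)
      } else rep(0, n)
    blanks_i <- config$blank_intensity +
      if (config$intensity_noise_sd > 0) {
        rnorm(config$n_blanks, 0, config$intensity_noise_sd)
      } else rep(0, config$n_blanks)
    flux <- data.frame(
      filter_id = resistance$filter_id,
      kind = resistance$kind,
      intensity_au = c(cells_i, blanks_i),
      stringsAsFactors = FALSE
    )
    list(resistance = resistance, flux = flux)
  })
}
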