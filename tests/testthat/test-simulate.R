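test_that("expression simulator honours counts, zeros, and determinism", {
  tab <- simulate_expression_table(expression_sim_config(
    n_genes = 10000, zero_fraction = 0, seed = 5))
  expect_equal(nrow(tab), 10000L)
  expect_true(all(tab$tpm > 0) && all(tab$fpkm > 0))
  expect_false(anyDuplicated(tab$gene_id) > 0)

  cfg <- expression_sim_config(n_genes = 4000, zero_fraction = 0.3, seed = 7)
  t1 <- simulate_expression_table(cfg)
  t2 <- simulate_expression_table(cfg)
  expect_identical(t1, t2)
  expect_equal(sum(t1$tpm == 0), round(0.3 * 4000))
  # zeros are zero in both channels; non-zero genes are active xor inactive
  expect_true(all((t1$tpm == 0) == (t1$fpkm == 0)))
  expect_identical(t1$truth_label[t1$tpm == 0],
                   rep("zero", sum(t1$tpm == 0)))
  expect_true(all(t1$truth_label[t1$tpm > 0] %in% c("active", "inactive")))
})

test_that("active-labelled share falls in the binomial 99% interval", {
  cfg <- expression_sim_config(n_genes = 20000, active_fraction = 0.7,
                               zero_fraction = 0, seed = 13)
  tab <- simulate_expression_table(cfg)
  n_active <- sum(tab$truth_label == "active")
  bounds <- qbinom(c(0.005, 0.995), 20000, 0.7)
  expect_gte(n_active, bounds[1])
  expect_lte(n_active, bounds[2])
})

test_that("FPKM channel scales with TPM under controllable jitter", {
  tab <- simulate_expression_table(expression_sim_config(
    n_genes = 2000, zero_fraction = 0, fpkm_scale = 2.5,
    fpkm_jitter_sd = 0, seed = 1))
  expect_equal(tab$fpkm, 2.5 * tab$tpm, tolerance = 1e-12)
  tabj <- simulate_expression_table(expression_sim_config(
    n_genes = 2000, zero_fraction = 0, fpkm_scale = 2.5,
    fpkm_jitter_sd = 0.05, seed = 1))
  expect_false(isTRUE(all.equal(tabj$fpkm, 2.5 * tabj$tpm)))
  lr <- log(tabj$fpkm / (2.5 * tabj$tpm))
  expect_lt(abs(sd(lr) - 0.05), 0.01)
})

test_that("config invariants are enforced with the field named", {
  expect_error(expression_sim_config(active_fraction = 1.2),
               "active_fraction", class = "epibarrier_config_error")
  expect_error(expression_sim_config(sd_active = 0), "sd_active",
               class = "epibarrier_config_error")
  expect_error(expression_sim_config(mu_active = -1, mu_inactive = 0),
               "mu_active", class = "epibarrier_config_error")
  expect_error(expression_sim_config(zero_fraction = 1), "zero_fraction",
               class = "epibarrier_config_error")
  expect_error(ussing_sim_config(true_ratio = 0),
               class = "epibarrier_domain_error")
  expect_error(flux_geometry(area_cm2 = 0), class = "epibarrier_domain_error")
})

test_that("Ussing simulator is the exact inverse of the GHK pipeline", {
  cfg <- ussing_sim_config(true_ratio = 1, potential_noise_sd = 0,
                           blank_potential = 0, n_replicates = 4, seed = 2)
  runs <- simulate_ussing_runs(cfg)
  expect_equal(sum(runs$kind == "cell"), 4L)
  expect_equal(sum(runs$kind == "blank"), 1L)
  expect_equal(runs$potential_mV[runs$kind == "cell"], rep(0, 4))

  cfg2 <- ussing_sim_config(true_ratio = 6.5, potential_noise_sd = 0,
                            blank_potential = -1.1, n_replicates = 3,
                            seed = 2)
  out <- summarize_runs(simulate_ussing_runs(cfg2), bath = cfg2$bath,
                        area_cm2 = cfg2$area_cm2)
  expect_equal(out$mean_pna_pcl, 6.5, tolerance = 1e-9)
  expect_identical(simulate_ussing_runs(cfg2), simulate_ussing_runs(cfg2))
})

test_that("plate simulator round-trips TER and Papp at zero noise", {
  geom <- flux_geometry()
  cfg <- plate_sim_config(true_ter = 650, blank_resistance_sd = 0,
                          cell_resistance_sd = 0, true_papp = 3e-6,
                          intensity_noise_sd = 0, n_filters = 3,
                          geometry = geom, seed = 9)
  sim <- simulate_plate_assay(cfg)
  expect_equal(sum(sim$resistance$kind == "cell"), 3L)
  ter <- compute_ter(
    sim$resistance$resistance_ohm[sim$resistance$kind == "cell"],
    sim$resistance$resistance_ohm[sim$resistance$kind == "blank"],
    area_cm2 = geom$area_cm2)
  expect_equal(ter$mean_ter, 650, tolerance = 1e-9)
  blank <- mean(sim$flux$intensity_au[sim$flux$kind == "blank"])
  papp <- compute_papp(
    sample_intensities = sim$flux$intensity_au[sim$flux$kind == "cell"],
    blank_intensity = blank, calibration = cfg$fluorescence_gain,
    geometry = geom)
  expect_equal(papp$mean_papp, 3e-6, tolerance = 1e-9)

  # zero flux: basal intensity equals the blank intensity
  cfg0 <- plate_sim_config(true_papp = 0, intensity_noise_sd = 0, seed = 4)
  sim0 <- simulate_plate_assay(cfg0)
  expect_equal(sim0$flux$intensity_au[sim0$flux$kind == "cell"],
               rep(cfg0$blank_intensity, cfg0$n_filters))
})

test_that("generators leave the caller's random stream untouched", {
  set.seed(123); before <- .Random.seed
  invisible(simulate_expression_table(expression_sim_config(
    n_genes = 100, seed = 99)))
  expect_identical(.Random.seed, before)
})
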