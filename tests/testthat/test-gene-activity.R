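test_that("log2 transform excludes zeros, adds no pseudocount", {
  tab <- data.frame(gene_id = c("a", "b", "c"), tpm = c(0, 1, 8),
                    fpkm = c(0.5, 2, 4))
  lt <- log2_transform(tab, "tpm")
  expect_equal(lt$values, c(0, 3))
  expect_equal(lt$n_excluded_zeros, 1L)
  expect_equal(log2_transform(tab, "fpkm")$values, c(-1, 1, 2))

  allz <- data.frame(gene_id = c("a", "b"), tpm = c(0, 0), fpkm = c(0, 0))
  lt0 <- log2_transform(allz, "tpm")
  expect_length(lt0$values, 0L)
  expect_equal(lt0$n_excluded_zeros, 2L)

  neg <- data.frame(gene_id = c("a", "bad"), tpm = c(1, -2), fpkm = c(1, 1))
  expect_error(log2_transform(neg, "tpm"), "bad",
               class = "epibarrier_data_error")
})

test_that("density bins at 0.1 with half-away-from-zero rounding", {
  d <- build_density(c(1.04, 1.06, 1.05))
  expect_equal(d$bin_centers, c(1.0, 1.1))
  expect_equal(d$counts, c(1L, 2L))
  # negative side of half-away-from-zero
  dn <- build_density(c(-1.05, -1.04))
  expect_equal(dn$bin_centers, c(-1.1, -1.0))
  expect_equal(dn$counts, c(1L, 1L))
  # gaps kept, conservation of counts
  dg <- build_density(c(0, 0.5, 0.51))
  expect_equal(dg$bin_centers, seq(0, 0.5, by = 0.1))
  expect_equal(sum(dg$counts), 3L)
  expect_error(build_density(numeric(0)), class = "epibarrier_data_error")
})

test_that("histogram of a large normal sample centres on its mean", {
  set.seed(101)
  vals <- rnorm(50000, mean = 5, sd = 1)
  d <- build_density(vals)
  expect_equal(sum(d$counts), 50000L)
  hist_mean <- sum(d$bin_centers * d$counts) / sum(d$counts)
  expect_lt(abs(hist_mean - 5), 0.05)
})

test_that("double-Gaussian fit recovers noise-free parameters within 1%", {
  true <- list(A_a = 300, mu_a = 5, s_a = 1, A_i = 150, mu_i = 0, s_i = 1)
  dens <- do.call(noise_free_density, true)
  fit <- fit_double_gaussian(dens)
  expect_true(fit$converged)
  expect_lt(rel_err(fit$active$amplitude, true$A_a), 0.01)
  expect_lt(rel_err(fit$active$mean, true$mu_a), 0.01)
  expect_lt(rel_err(fit$active$sd, true$s_a), 0.01)
  expect_lt(rel_err(fit$inactive$amplitude, true$A_i), 0.01)
  expect_lt(abs(fit$inactive$mean - true$mu_i), 0.01)  # true mean is 0
  expect_lt(rel_err(fit$inactive$sd, true$s_i), 0.01)
})

test_that("component labelling follows the mean, not the seeding order", {
  # inactive peak taller than the active one: the global maximum seeds the
  # low-mean component first, yet labels must still follow the means
  dens <- noise_free_density(120, 6, 1.2, 400, -1, 0.8)
  fit <- fit_double_gaussian(dens)
  expect_gt(fit$active$mean, fit$inactive$mean)
  expect_lt(rel_err(fit$active$mean, 6), 0.01)
  expect_lt(rel_err(fit$inactive$amplitude, 400), 0.01)
})

test_that("degenerate unimodal densities error or fit a null component", {
  dens <- noise_free_density(300, 3, 1, 0, -2, 1)
  out <- tryCatch(fit_double_gaussian(dens), error = identity)
  if (inherits(out, "error")) {
    expect_s3_class(out, "epibarrier_fit_error")
  } else {
    expect_lt(min(out$active$amplitude, out$inactive$amplitude), 1)
  }
  expect_error(fit_double_gaussian(build_density(c(1, 1.05, 1.11))),
               class = "epibarrier_fit_error")
})

test_that("ratio cutoff matches the closed form and the grid oracle", {
  fit <- structure(list(
    metric = "tpm",
    active = list(amplitude = 0.7, mean = 5, sd = 1),
    inactive = list(amplitude = 0.3, mean = 0, sd = 1),
    residual_norm = 0, converged = TRUE), class = "double_gaussian_fit")
  thr <- activity_threshold(fit, ratio = 5)
  # equal-sigma case: (10x - 25)/2 = ln(5 * 0.3 / 0.7)
  closed <- (25 + 2 * log(5 * 0.3 / 0.7)) / 10
  expect_equal(thr$cutoff_log2, closed, tolerance = 1e-9)
  expect_equal(thr$cutoff_log2, 2.652, tolerance = 1e-3)
  expect_equal(thr$cutoff_log2,
               grid_threshold_oracle(fit$active, fit$inactive, 5),
               tolerance = 1e-3)
  # defining property: curve ratio equals 5 at the cutoff, exceeds it beyond
  at <- function(x) (0.7 * exp(-(x - 5)^2 / 2)) / (0.3 * exp(-x^2 / 2))
  expect_equal(at(thr$cutoff_log2), 5, tolerance = 1e-6)
  expect_true(all(at(seq(thr$cutoff_log2 + 0.01, 12, by = 0.2)) > 5))
})

test_that("cutoff handles symmetry, unequal sigmas, and monotonicity", {
  mkfit <- function(Aa, ma, sa, Ai, mi, si) {
    structure(list(metric = "tpm",
                   active = list(amplitude = Aa, mean = ma, sd = sa),
                   inactive = list(amplitude = Ai, mean = mi, sd = si),
                   residual_norm = 0, converged = TRUE),
              class = "double_gaussian_fit")
  }
  # ratio 1 with equal amplitude and sd: cutoff at the midpoint of the means
  expect_equal(activity_threshold(mkfit(2, 6, 1, 2, 2, 1), 1)$cutoff_log2, 4)
  # broader active component: quadratic case, still matches the grid oracle
  f <- mkfit(250, 5.5, 1.6, 400, 0.5, 1.1)
  thr <- activity_threshold(f, 5)
  expect_equal(thr$cutoff_log2,
               grid_threshold_oracle(f$active, f$inactive, 5),
               tolerance = 1e-3)
  # raising the ratio never lowers the cutoff
  cuts <- vapply(c(1, 2, 5, 10, 50),
                 function(r) activity_threshold(f, r)$cutoff_log2, numeric(1))
  expect_true(all(diff(cuts) >= 0))
  # active narrower than inactive: the ratio falls off to the right -> error
  expect_error(activity_threshold(mkfit(300, 5, 0.8, 300, 0, 2), 5),
               class = "epibarrier_threshold_error")
})

test_that("gene calls use strict inequality and propagate zeros", {
  thr <- function(metric, cut) structure(
    list(metric = metric, cutoff_log2 = cut, ratio = 5),
    class = "activity_threshold")
  tab <- data.frame(gene_id = c("at_cut", "above", "below", "zero_tpm"),
                    tpm = c(2^3, 2^3.1, 2^2, 0),
                    fpkm = c(2^3.5, 2^3.5, 2^2, 5))
  calls <- classify_genes(tab, thr("tpm", 3), thr("fpkm", 3))
  expect_identical(calls$call_tpm, c("inactive", "active", "inactive", "zero"))
  expect_identical(calls$call_combined,
                   c("inactive", "active", "inactive", "zero"))
  # "either" rule promotes the boundary gene via its FPKM call
  either <- classify_genes(tab, thr("tpm", 3), thr("fpkm", 3),
                           combine = "either")
  expect_identical(either$call_combined,
                   c("active", "active", "inactive", "zero"))
  expect_error(classify_genes(tab, thr("fpkm", 3), thr("tpm", 3)),
               class = "epibarrier_config_error")
})

test_that("excluded zeros and density counts conserve the table size", {
  tab <- simulate_expression_table(expression_sim_config(
    n_genes = 5000, zero_fraction = 0.25, seed = 11))
  for (m in c("tpm", "fpkm")) {
    lt <- log2_transform(tab, m)
    d <- build_density(lt$values, metric = m,
                       n_excluded_zeros = lt$n_excluded_zeros)
    expect_equal(sum(d$counts) + d$n_excluded_zeros, nrow(tab))
  }
})

test_that("end-to-end calls on a well-separated mixture match truth", {
  cfg <- expression_sim_config(n_genes = 20000, active_fraction = 0.5,
                               mu_active = 6, sd_active = 1,
                               mu_inactive = 0, sd_inactive = 1,
                               zero_fraction = 0.1, seed = 2024)
  tab <- simulate_expression_table(cfg)
  res <- call_gene_activity(tab, ratio = 5)
  expect_lt(abs(res$fits$tpm$active$mean - 6), 0.1)
  expect_lt(abs(res$fits$tpm$inactive$mean - 0), 0.1)
  acc <- mean(res$calls$call_combined == tab$truth_label)
  expect_gte(acc, 0.99)
})
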