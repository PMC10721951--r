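# Independent oracles kept deliberately separate from the package's code
# paths: a second GHK evaluation written in terms of absolute permeabilities,
# a brute-force grid search for the ratio cutoff, and a noise-free density
# constructor evaluated from known two-Gaussian parameters.

# GHK voltage with explicit absolute permeabilities (any common factor k
# cancels); monovalent cation Na+ and anion Cl-, mV out
ghk_oracle_mV <- function(p_na, p_cl, na_ap, cl_ap, na_bl, cl_bl,
                          temp_K = 310.15) {
  RT_F <- 8.314462618 * temp_K / 96485.33212
  num <- p_na * na_ap + p_cl * cl_bl
  den <- p_na * na_bl + p_cl * cl_ap
  1000 * RT_F * log(num / den)
}

# brute-force search for the largest x where the active/inactive curve ratio
# crosses the target, on a fixed grid; NA when no crossing exists
grid_threshold_oracle <- function(active, inactive, ratio,
                                  lo = -10, hi = 20, step = 1e-4) {
  xs <- seq(lo, hi, by = step)
  g <- function(comp, x) comp$amplitude * exp(-(x - comp$mean)^2 /
                                                (2 * comp$sd^2))
  r <- g(active, xs) / (ratio * g(inactive, xs))
  crossings <- which(diff(sign(log(r))) != 0)
  if (length(crossings) == 0L) return(NA_real_)
  xs[crossings[length(crossings)]]
}

# exact two-Gaussian curve tallied onto 0.1 bins, as a log_density object
noise_free_density <- function(A_a, mu_a, s_a, A_i, mu_i, s_i,
                               lo = -6, hi = 12, metric = "tpm") {
  centers <- seq(lo, hi, by = 0.1)
  counts <- A_a * exp(-(centers - mu_a)^2 / (2 * s_a^2)) +
            A_i * exp(-(centers - mu_i)^2 / (2 * s_i^2))
  structure(list(bin_centers = centers, counts = counts, metric = metric,
                 n_excluded_zeros = 0L),
            class = "log_density")
}

rel_err <- function(est, true) abs(est - true) / abs(true)

# active/inactive curve-height ratio of a double_gaussian_fit at x
gauss_ratio_at <- function(fit, x) {
  g <- function(comp) comp$amplitude * exp(-(x - comp$mean)^2 /
                                             (2 * comp$sd^2))
  g(fit$active) / g(fit$inactive)
}
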