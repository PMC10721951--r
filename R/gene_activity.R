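#' Log2-transform one expression metric, excluding exact zeros
#'
#' Genes with exactly zero expression are excluded before the log transform
#' (no pseudocount is added); their count is reported so that
#' excluded zeros + density counts always reconserve the table size.
#'
#' @param table An expression data.frame with columns `gene_id`, `tpm`,
#'   `fpkm` (see [read_expression_table()]).
#' @param metric `"tpm"` or `"fpkm"`.
#' @return A list with `values` (log2 of the non-zero entries, in table
#'   order), `n_excluded_zeros`, and `metric`.
#' @examples
#' tab <- data.frame(gene_id = c("a", "b", "c"), tpm = c(0, 1, 8),
#'                   fpkm = c(0, 1, 8))
#' log2_transform(tab, "tpm")$values  # 0, 3
#' @export
log2_transform <- function(table, metric = c("tpm", "fpkm")) {
  metric <- match.arg(metric)
  x <- table[[metric]]
  if (is.null(x)) {
    stop_epibarrier("epibarrier_data_error",
                    sprintf("table has no '%s' column", metric))
  }
  bad <- which(x < 0)
  if (length(bad) > 0L) {
    stop_epibarrier("epibarrier_data_error",
                    sprintf("negative %s value for gene '%s'",
                            toupper(metric), table$gene_id[bad[1L]]))
  }
  nz <- x > 0
  list(values = log2(x[nz]), n_excluded_zeros = sum(!nz), metric = metric)
}

# round half away from zero to one decimal, returned as integer tenths
round_to_tenths <- function(x) {
  as.integer(sign(x) * floor(abs(x) * 10 + 0.5))
}

#' Bin log2 expression values into a 0.1-resolution density
#'
#' Each value is rounded to one decimal place (half away from zero) and
#' tallied; the bins cover the rounded range contiguously at 0.1 spacing,
#' with zero-count gaps retained. This binned density — gene counts per
#' 0.1 log2 unit — is the object the double-Gaussian model is fitted to.
#'
#' @param values Numeric vector of log2 expression values (non-empty).
#' @param metric Optional metric label carried through to the fit.
#' @param n_excluded_zeros Number of zero-expression genes excluded upstream.
#' @return An object of class `log_density` with `bin_centers`, `counts`,
#'   `metric`, `n_excluded_zeros`.
#' @export
build_density <- function(values, metric = NA_character_,
                          n_excluded_zeros = 0L) {
  if (length(values) == 0L || !is.numeric(values)) {
    stop_epibarrier("epibarrier_data_error",
                    "cannot build a density from an empty value list")
  }
  tenths <- round_to_tenths(values)
  rng <- range(tenths)
  centers <- seq.int(rng[1L], rng[2L])
  counts <- tabulate(tenths - rng[1L] + 1L, nbins = length(centers))
  structure(list(bin_centers = centers / 10, counts = counts,
                 metric = metric,
                 n_excluded_zeros = as.integer(n_excluded_zeros)),
            class = "log_density")
}

# deterministic initial values for the two-component fit: the global maximum
# seeds one component; the highest bin at least min_sep log2 units away seeds
# the other. Local-maximum candidates are preferred when available.
init_double_gaussian <- function(density, min_sep = 1.0) {
  x <- density$bin_centers
  y <- density$counts
  n <- length(y)
  i1 <- which.max(y)
  is_locmax <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) y[i - 1L] else -Inf
    right <- if (i < n) y[i + 1L] else -Inf
    y[i] > 0 && y[i] >= left && y[i] >= right
  }, logical(1))
  far <- abs(x - x[i1]) >= min_sep
  cand <- which(is_locmax & far)
  if (length(cand) == 0L) cand <- which(far)
  if (length(cand) == 0L) cand <- setdiff(seq_len(n), i1)
  i2 <- cand[which.max(y[cand])]
  ord <- order(c(x[i1], x[i2]))
  idx <- c(i1, i2)[ord]
  list(A1 = y[idx[1L]], mu1 = x[idx[1L]], s1 = 1.0,
       A2 = y[idx[2L]], mu2 = x[idx[2L]], s2 = 1.0)
}

#' Fit a sum of two Gaussian curves to a binned expression density
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt) of
#' \deqn{f(x) = A_a e^{-(x-\mu_a)^2/2\sigma_a^2} +
#'              A_i e^{-(x-\mu_i)^2/2\sigma_i^2}}
#' to the bin counts. Amplitudes are curve heights in gene-count units (the
#' density's y axis), not normalised mixture weights. Initialisation is
#' deterministic — the two highest-count (local-maximum) bins separated by at
#' least 1 log2 unit seed the means, their counts seed the amplitudes, and
#' both sigmas start at 1 — so the fit is reproducible with no random
#' restarts. The component with the larger fitted mean is labelled active.
#'
#' @param density A `log_density` from [build_density()] with at least 6
#'   non-empty bins.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return An object of class `double_gaussian_fit`: `active` and `inactive`
#'   (each a list with `amplitude`, `mean`, `sd`), `metric`,
#'   `residual_norm`, `converged`.
#' @export
fit_double_gaussian <- function(density, max_iter = 200L) {
  stopifnot(inherits(density, "log_density"))
  if (sum(density$counts > 0) < 6L) {
    stop_epibarrier("epibarrier_fit_error",
                    "density has fewer than 6 non-empty bins")
  }
  x <- density$bin_centers
  y <- density$counts
  start <- unlist(init_double_gaussian(density))
  model <- function(p) {
    p["A1"] * exp(-(x - p["mu1"])^2 / (2 * p["s1"]^2)) +
    p["A2"] * exp(-(x - p["mu2"])^2 / (2 * p["s2"]^2))
  }
  # nls.lm rather than an nls-model wrapper: the residual formulation also
  # converges on exact (zero-residual) densities
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = function(p) model(p) - y,
      lower = c(A1 = 0, mu1 = -Inf, s1 = 1e-3,
                A2 = 0, mu2 = -Inf, s2 = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = max_iter)
    ),
    error = function(e) {
      stop_epibarrier("epibarrier_fit_error",
                      paste0("double-Gaussian fit failed: ",
                             conditionMessage(e)),
                      data = list(start = start))
    }
  )
  converged <- fit$info %in% 1:4
  if (!converged) {
    stop_epibarrier("epibarrier_fit_error",
                    paste0("double-Gaussian fit did not converge: ",
                           fit$message),
                    data = list(start = start, info = fit$info))
  }
  p <- fit$par
  comp <- list(
    list(amplitude = unname(p["A1"]), mean = unname(p["mu1"]),
         sd = unname(p["s1"])),
    list(amplitude = unname(p["A2"]), mean = unname(p["mu2"]),
         sd = unname(p["s2"]))
  )
  ord <- order(vapply(comp, `[[`, numeric(1), "mean"), decreasing = TRUE)
  structure(list(
    metric = density$metric,
    active = comp[[ord[1L]]],
    inactive = comp[[ord[2L]]],
    residual_norm = sqrt(fit$deviance),
    converged = converged
  ), class = "double_gaussian_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate one Gaussian component at x
gauss_curve <- function(comp, x) {
  comp$amplitude * exp(-(x - comp$mean)^2 / (2 * comp$sd^2))
}

#' Expression cutoff where the active curve exceeds the inactive curve
#' by a given ratio
#'
#' Solves \eqn{A_a \phi_a(x) = r\, A_i \phi_i(x)} in closed form: taking
#' logs turns the condition into a quadratic (linear when the two sigmas are
#' equal) in x. The cutoff is a lower bound for active expression: when the
#' log-ratio parabola opens upward (active sigma >= inactive sigma) the
#' larger root is returned and the ratio stays at or above `r` for all
#' larger x. When the active component is the narrower one the ratio
#' eventually falls back below `r`; the lower crossing is still accepted if
#' the fall-back lies beyond the active component's support (mean + 6 sd,
#' where both curves are numerically zero), since fitted sigmas of
#' equal-width components always differ by a little sampling noise.
#' Otherwise no usable cutoff exists and an error is raised. Genes above
#' the cutoff are at least `r` times more likely to
#' come from the active component than from the inactive one, in curve-height
#' (gene-rate) terms.
#'
#' @param fit A converged `double_gaussian_fit`.
#' @param ratio Required active/inactive density ratio at the cutoff
#'   (default 5).
#' @return An object of class `activity_threshold` with `cutoff_log2`,
#'   `ratio`, `metric`.
#' @export
activity_threshold <- function(fit, ratio = 5) {
  stopifnot(inherits(fit, "double_gaussian_fit"))
  if (!isTRUE(fit$converged)) {
    stop_epibarrier("epibarrier_fit_error",
                    "cannot derive a threshold from a non-converged fit")
  }
  check_scalar(ratio, "ratio", positive = TRUE)
  a_c <- fit$active; i_c <- fit$inactive
  if (a_c$amplitude <= 0 || i_c$amplitude <= 0) {
    stop_epibarrier("epibarrier_threshold_error",
                    "a component amplitude is zero: no crossing exists")
  }
  # log A_a - (x-mu_a)^2/2s_a^2 = log(r A_i) - (x-mu_i)^2/2s_i^2
  # => qa x^2 + qb x + qc = 0
  qa <- 1 / (2 * i_c$sd^2) - 1 / (2 * a_c$sd^2)
  qb <- a_c$mean / a_c$sd^2 - i_c$mean / i_c$sd^2
  qc <- i_c$mean^2 / (2 * i_c$sd^2) - a_c$mean^2 / (2 * a_c$sd^2) +
        log(a_c$amplitude / (ratio * i_c$amplitude))
  tol <- 1e-12
  if (abs(qa) < tol) {
    if (qb <= 0) {
      stop_epibarrier("epibarrier_threshold_error",
                      "curve ratio is non-increasing: no valid cutoff")
    }
    root <- -qc / qb
  } else {
    disc <- qb^2 - 4 * qa * qc
    if (disc < 0) {
      stop_epibarrier("epibarrier_threshold_error",
                      "the curve ratio never crosses the requested value")
    }
    roots <- sort((-qb + c(-1, 1) * sqrt(disc)) / (2 * qa))
    if (qa > 0) {
      # log-ratio parabola opens upward: ratio >= r for all x beyond the
      # larger root
      root <- roots[2L]
    } else {
      # sigma_active < sigma_inactive: the ratio exceeds r only between the
      # roots and falls back below beyond the larger one. Accept the lower
      # crossing when the fall-back lies outside the active component's
      # support (beyond mean + 6 sd, where both curves are numerically
      # zero and the ratio is meaningless); otherwise no usable cutoff.
      if (roots[2L] <= a_c$mean + 6 * a_c$sd) {
        stop_epibarrier(
          "epibarrier_threshold_error",
          paste0("active component is narrower than the inactive one and ",
                 "the curve ratio falls below the target within its ",
                 "support: no usable cutoff"))
      }
      root <- roots[1L]
    }
  }
  structure(list(metric = fit$metric, cutoff_log2 = root, ratio = ratio),
            class = "activity_threshold")
}

#' Call genes active, inactive, or zero
#'
#' Per metric, a gene is called active iff its log2 value strictly exceeds
#' the metric's cutoff; genes with zero expression in a metric are called
#' `"zero"` for that metric (they were excluded from the density). The
#' combined call is `"active"` only when both per-metric calls are active
#' (`combine = "both"`, the conservative default), or when at least one is
#' (`combine = "either"`); a zero in either metric gives a combined
#' `"zero"`.
#'
#' @param table Expression data.frame (`gene_id`, `tpm`, `fpkm`).
#' @param thr_tpm,thr_fpkm `activity_threshold` objects for the TPM and FPKM
#'   metrics, from fits on this table.
#' @param combine `"both"` or `"either"`.
#' @return A data.frame with columns `gene_id`, `log2_tpm`, `log2_fpkm`
#'   (`NA` for zeros), `call_tpm`, `call_fpkm`, `call_combined`.
#' @export
classify_genes <- function(table, thr_tpm, thr_fpkm,
                           combine = c("both", "either")) {
  combine <- match.arg(combine)
  stopifnot(inherits(thr_tpm, "activity_threshold"),
            inherits(thr_fpkm, "activity_threshold"))
  if (identical(thr_tpm$metric, "fpkm") || identical(thr_fpkm$metric, "tpm")) {
    stop_epibarrier("epibarrier_config_error",
                    "threshold metrics are swapped between tpm and fpkm")
  }
  call_one <- function(x, cutoff) {
    ifelse(x == 0, "zero", ifelse(log2(pmax(x, .Machine$double.xmin)) > cutoff,
                                  "active", "inactive"))
  }
  call_tpm <- call_one(table$tpm, thr_tpm$cutoff_log2)
  call_fpkm <- call_one(table$fpkm, thr_fpkm$cutoff_log2)
  combined <- ifelse(
    call_tpm == "zero" | call_fpkm == "zero", "zero",
    if (combine == "both") {
      ifelse(call_tpm == "active" & call_fpkm == "active",
             "active", "inactive")
    } else {
      ifelse(call_tpm == "active" | call_fpkm == "active",
             "active", "inactive")
    }
  )
  data.frame(
    gene_id = table$gene_id,
    log2_tpm = ifelse(table$tpm > 0, log2(table$tpm), NA_real_),
    log2_fpkm = ifelse(table$fpkm > 0, log2(table$fpkm), NA_real_),
    call_tpm = call_tpm, call_fpkm = call_fpkm, call_combined = combined,
    stringsAsFactors = FALSE
  )
}

#' Run the whole activity-calling track on one expression table
#'
#' Convenience wrapper: log2 transform (zeros excluded), 0.1-bin density,
#' double-Gaussian fit, ratio cutoff, and per-gene calls, for both the TPM
#' and FPKM channels.
#'
#' @param table Expression data.frame (`gene_id`, `tpm`, `fpkm`).
#' @param ratio Active/inactive density ratio defining the cutoff.
#' @param combine Combined-call rule, see [classify_genes()].
#' @return A list with `calls` (per-gene data.frame), `fits` and
#'   `thresholds` (per metric), and `densities`.
#' @export
call_gene_activity <- function(table, ratio = 5,
                               combine = c("both", "either")) {
  combine <- match.arg(combine)
  per_metric <- lapply(c(tpm = "tpm", fpkm = "fpkm"), function(m) {
    lt <- log2_transform(table, m)
    dens <- build_density(lt$values, metric = m,
                          n_excluded_zeros = lt$n_excluded_zeros)
    fit <- fit_double_gaussian(dens)
    list(density = dens, fit = fit,
         threshold = activity_threshold(fit, ratio))
  })
  list(
    calls = classify_genes(table, per_metric$tpm$threshold,
                           per_metric$fpkm$threshold, combine = combine),
    fits = lapply(per_metric, `[[`, "fit"),
    thresholds = lapply(per_metric, `[[`, "threshold"),
    densities = lapply(per_metric, `[[`, "density")
  )
}

#' Plot a binned expression density with its two-Gaussian fit
#'
#' Base-graphics diagnostic plot: bin counts, the two fitted components, the
#' summed model curve, and the activity cutoff if supplied.
#'
#' @param density A `log_density`.
#' @param fit Optional `double_gaussian_fit` to overlay.
#' @param threshold Optional `activity_threshold` drawn as a vertical line.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_density_fit <- function(density, fit = NULL, threshold = NULL, ...) {
  stopifnot(inherits(density, "log_density"))
  graphics::plot(density$bin_centers, density$counts, type = "h",
                 col = "grey60", xlab = "log2 expression",
                 ylab = "genes per 0.1 bin", ...)
  if (!is.null(fit)) {
    xx <- seq(min(density$bin_centers), max(density$bin_centers),
              length.out = 400L)
    graphics::lines(xx, gauss_curve(fit$active, xx), col = "darkgreen")
    graphics::lines(xx, gauss_curve(fit$inactive, xx), col = "goldenrod")
    graphics::lines(xx, gauss_curve(fit$active, xx) +
                        gauss_curve(fit$inactive, xx), col = "darkorange")
  }
  if (!is.null(threshold)) {
    graphics::abline(v = threshold$cutoff_log2, lty = 2)
  }
  invisible(NULL)
}
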