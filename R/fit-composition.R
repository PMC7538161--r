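# Poisson plug-in weights for binned densities. Weights based on observed
# counts systematically overweight bins that fluctuated low (their weight is
# large exactly because their count is small), which biases scale parameters
# downward; weights are therefore refreshed from the EXPECTED counts of the
# current fit (iteratively reweighted least squares), with the observed
# counts only seeding the first pass.
poisson_weights <- function(expected_counts) 1 / pmax(expected_counts, 1)

# Weighted non-negative least squares of y on the columns of X, by
# enumeration of active sets (used with <= 3 components, where enumeration
# is exact and trivially cheap).
nnls_enum <- function(X, y, w) {
  p <- ncol(X)
  best <- NULL
  for (mask in 0:(2^p - 1)) {
    on <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    if (length(on) == 0) {
      beta <- numeric(p)
    } else {
      Xw <- X[, on, drop = FALSE] * sqrt(w)
      yw <- y * sqrt(w)
      b <- tryCatch(qr.solve(Xw, yw), error = function(e) NULL)
      if (is.null(b) || any(!is.finite(b)) || any(b < 0)) next
      beta <- numeric(p)
      beta[on] <- b
    }
    rss <- sum(w * (y - X %*% beta)^2)
    if (is.null(best) || rss < best$rss - 1e-15)
      best <- list(beta = beta, rss = rss,
                   clipped = length(on) < p)
  }
  best
}

# Detected-form component densities over histogram bins for the given sizes.
component_densities <- function(model, sizes, bin_edges, grid_step = NULL) {
  vapply(sizes, function(n) {
    pmf <- n_mer_distribution(model, n, grid_step = grid_step,
                              detected = TRUE)
    pmf_bin_density(pmf, bin_edges)
  }, numeric(length(bin_edges) - 1L))
}

#' Fit the low-intensity peak to a monomer + dimer mixture
#'
#' Estimates the log-normal parameters `(mu, sigma)` of the single bright
#' fluorophore, together with the monomer and dimer spot fractions, from the
#' low-intensity region of a spot histogram, holding the dark fraction
#' fixed. The fit is weighted least squares on binned densities with
#' Poisson weights (iteratively refreshed from the expected counts of the
#' current fit), using the detected (at-least-one-bright) forms of the
#' monomer and dimer distributions, solved by bounded quasi-Newton
#' optimization over `(mu, sigma)` with the two weights profiled out by
#' non-negative least squares; three deterministic starts guard against
#' local minima.
#'
#' @param hist An [intensity_histogram()].
#' @param nu Dark fraction, held fixed (default 0.3).
#' @param low_region Intensity interval `c(lo, hi)` to fit over; by default
#'   from 0 up to the smaller of the low/high split
#'   ([split_low_region()]) and three times the low-peak mode (the
#'   monomer/dimer peak region proper).
#' @return A list with `model` (a [monomer_model()]), `weights` (named
#'   monomer/dimer spot fractions), `objective`, and `low_region`.
#' @export
fit_monomer_dimer <- function(hist, nu = 0.3, low_region = NULL) {
  stopifnot(inherits(hist, "intensity_histogram"))
  if (is.null(low_region)) {
    # upper edge: the monomer/dimer peak region proper. The low/high split
    # bounds it, but 3x the low mode (monomer mode ~m, dimer mode ~2m plus
    # width) is tighter when intermediate oligomers leak below the split.
    split <- split_low_region(hist)
    s <- smooth_density(hist)
    xc <- hist_centers(hist)
    low_mode <- xc[xc < split][which.max(s[xc < split])]
    low_region <- c(0, min(split, 3 * low_mode))
  }
  x <- hist_centers(hist)
  sel <- x > low_region[1] & x <= low_region[2]
  if (sum(hist$counts[sel] > 0) < 10)
    stop("low_region contains fewer than 10 non-empty bins")
  y_all <- hist_density(hist)
  y <- y_all[sel]
  n_tot <- sum(hist$counts)
  widths <- hist_widths(hist)[sel]
  w <- poisson_weights(hist$counts[sel])
  edges <- hist$bin_edges[c(which(sel), max(which(sel)) + 1L)]
  xs <- x[sel]

  objective <- function(par) {
    model <- monomer_model(par[1], par[2], nu)
    X <- component_densities(model, c(1L, 2L), edges)
    fit <- nnls_enum(X, y, w)
    fit$rss
  }
  # deterministic starts: log of the low-region mode / median / mean
  mode_x <- xs[which.max(y)]
  counts <- hist$counts[sel]
  med_x <- xs[which(cumsum(counts) >= sum(counts) / 2)[1]]
  mean_x <- sum(xs * counts) / sum(counts)
  starts <- list(c(log(mode_x), 0.35),
                 c(log(med_x), 0.25),
                 c(log(max(mean_x / 1.3, min(xs))), 0.5))
  lower <- c(log(max(min(xs), 1e-6)), 0.05)
  upper <- c(log(max(xs)), 1.5)
  # density-scale objectives are ~1e-8; rescale so the optimizer's relative
  # convergence thresholds do not fire at the starting point
  ctrl <- list(maxit = 300, factr = 1e4, pgtol = 1e-14,
               parscale = c(0.2, 0.2),
               fnscale = max(objective(starts[[1]]), 1e-300))
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower), upper)
    opt <- tryCatch(
      stats::optim(s, objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = ctrl),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value))
      best <- opt
  }
  if (is.null(best))
    stop("monomer/dimer fit failed to converge from all starts")
  # refresh weights from the expected counts of the current fit and
  # re-optimize (two IRLS rounds suffice for stable weights)
  for (iter in 1:2) {
    model <- monomer_model(best$par[1], best$par[2], nu)
    X <- component_densities(model, c(1L, 2L), edges)
    fin <- nnls_enum(X, y, w)
    expected <- n_tot * widths * as.numeric(X %*% fin$beta)
    w <- poisson_weights(expected)
    opt <- tryCatch(
      stats::optim(best$par, objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = ctrl),
      error = function(e) NULL)
    if (!is.null(opt)) best <- opt
  }
  model <- monomer_model(best$par[1], best$par[2], nu)
  X <- component_densities(model, c(1L, 2L), edges)
  fin <- nnls_enum(X, y, w)
  wts <- fin$beta
  names(wts) <- c("monomer", "dimer")
  list(model = model, weights = wts, objective = fin$rss,
       low_region = low_region)
}

#' Estimate the dark fraction by dodecamer-peak alignment
#'
#' Auto-convolves the fitted monomeric distribution 12 times (or
#' `n_subunits` times) for each candidate dark fraction and picks the value
#' whose predicted oligomer distribution best aligns with the observed
#' high-intensity peak. Alignment centers the predicted peak on the data:
#' the objective is the squared distance between the predicted oligomer
#' mode (located to sub-grid precision) and the observed high-intensity
#' mode. The peak position carries the dark-fraction information (it sits
#' near `n (1 - nu) m1`) while remaining insensitive to intermediate
#' oligomer species shouldering the peak's low-intensity flank; the
#' estimator has no bearing on the predicted peak's width, which is fixed
#' by the underlying log-normal. After the grid scan the minimizer is
#' refined on a finer local grid; ties break toward smaller `nu`.
#'
#' @param hist An [intensity_histogram()] with a resolvable high-intensity
#'   peak.
#' @param model A [monomer_model()] carrying the fitted `(mu, sigma)`; its
#'   `nu` is ignored.
#' @param n_subunits Oligomer size of the high-intensity species
#'   (default 12).
#' @param nu_grid Candidate dark fractions (default 0 to 0.6 by 0.01).
#' @param refine Step of the local refinement grid (default 0.002); set to
#'   `NULL` to skip refinement.
#' @return The estimated dark fraction, with the objective profile in
#'   attribute `"profile"`.
#' @export
estimate_dark_fraction <- function(hist, model, n_subunits = 12L,
                                   nu_grid = seq(0, 0.6, by = 0.01),
                                   refine = 0.002) {
  stopifnot(inherits(hist, "intensity_histogram"),
            inherits(model, "monomer_model"))
  boundary <- split_low_region(hist)
  peak_x <- find_high_peak(hist, boundary)

  score <- function(nu) {
    m <- monomer_model(model$mu, model$sigma, nu)
    pmf <- n_mer_distribution(m, n_subunits, detected = TRUE)
    dens <- pmf$masses / pmf$grid_step
    g <- pmf_grid(pmf)
    pk <- which.max(dens)
    mode_pred <- if (pk > 1 && pk < length(dens)) {
      g[pk] + pmf$grid_step *
        quadratic_offset(dens[pk - 1], dens[pk], dens[pk + 1])
    } else g[pk]
    # centering objective: squared distance between the predicted and the
    # observed high-intensity mode. The peak position carries the
    # dark-fraction information (it sits near n (1 - nu) m1) and, unlike a
    # least-squares shape match over a window, it is insensitive to
    # intermediate-species shoulders on the peak's low-intensity flank.
    (mode_pred - peak_x)^2
  }

  obj <- vapply(nu_grid, score, numeric(1))
  nu_hat <- nu_grid[which.min(obj)]
  if (!is.null(refine)) {
    step <- if (length(nu_grid) > 1) min(diff(sort(nu_grid))) else 0.01
    local <- seq(max(0, nu_hat - step), min(0.999, nu_hat + step),
                 by = refine)
    obj_l <- vapply(local, score, numeric(1))
    nu_hat <- local[which.min(obj_l)]
  }
  structure(nu_hat, profile = data.frame(nu = nu_grid, objective = obj))
}

#' Fit the observed histogram to a monomer/dimer/dodecamer mixture
#'
#' With `(mu, sigma, nu)` fixed, fits non-negative weights for the detected
#' monomer, dimer and dodecamer distributions to the full observed density
#' by weighted least squares (Poisson weights). The per-bin signed residual
#' (observed minus fitted mixture) carries the species the three components
#' do not describe: intermediate oligomers between dimer and dodecamer, and
#' aggregates beyond the dodecamer.
#'
#' @param hist An [intensity_histogram()].
#' @param model A fitted [monomer_model()] (with its dark fraction).
#' @param component_sizes Subunit counts of the fitted components
#'   (default `c(1, 2, 12)`).
#' @return An object of class `oligomer_mixture_fit` with elements `model`,
#'   `component_sizes`, `weights`, `component_densities`, `fitted`,
#'   `residual`, and `hist`.
#' @export
three_component_fit <- function(hist, model,
                                component_sizes = c(1L, 2L, 12L)) {
  stopifnot(inherits(hist, "intensity_histogram"),
            inherits(model, "monomer_model"))
  y <- hist_density(hist)
  w <- poisson_weights(hist$counts)
  X <- component_densities(model, component_sizes, hist$bin_edges)
  fit <- nnls_enum(X, y, w)
  # one reweighting pass from expected counts (see poisson_weights)
  expected <- sum(hist$counts) * hist_widths(hist) * as.numeric(X %*% fit$beta)
  fit <- nnls_enum(X, y, poisson_weights(expected))
  if (fit$clipped)
    warning("negative component weight clipped to zero")
  fitted <- as.numeric(X %*% fit$beta)
  wts <- fit$beta
  names(wts) <- paste0("n", component_sizes)
  structure(list(model = model,
                 component_sizes = component_sizes,
                 weights = wts,
                 component_densities = X,
                 fitted = fitted,
                 residual = y - fitted,
                 objective = fit$rss,
                 hist = hist),
            class = "oligomer_mixture_fit")
}

#' @export
print.oligomer_mixture_fit <- function(x, ...) {
  cat("oligomer mixture fit\n")
  print(x$model)
  cat("  component weights:",
      paste(sprintf("%s = %.3f", names(x$weights), x$weights),
            collapse = ", "), "\n")
  invisible(x)
}

#' Species percentages from a mixture fit
#'
#' Partitions the sample into smaller (monomer + dimer), dodecameric,
#' intermediate and aggregate species. Smaller and dodecamer come from the
#' fitted weights; intermediate is the positive residual mass between the
#' dimer component's upper boundary and the dodecamer component's lower
#' boundary; aggregate is the positive residual mass above the dodecamer
#' component's upper boundary. Default boundaries: dimer 99th percentile,
#' dodecamer 1st percentile, and dodecamer 99.9th percentile of the
#' detected component distributions. The four categories are renormalized
#' to sum to 100; raw (un-normalized) masses are kept in `raw`.
#'
#' @param fit An `oligomer_mixture_fit`.
#' @param boundaries Optional list with `dimer_upper`, `dodecamer_band`
#'   (length-2), `aggregate_lower` (ADU), ordered increasingly.
#' @return A list with `percentages` (named smaller / intermediate /
#'   dodecamer / aggregate), `boundaries`, and `raw`.
#' @export
species_percentages <- function(fit, boundaries = NULL) {
  stopifnot(inherits(fit, "oligomer_mixture_fit"))
  model <- fit$model
  sizes <- fit$component_sizes
  if (is.null(boundaries)) {
    d2 <- n_mer_distribution(model, sizes[2], detected = TRUE)
    d12 <- n_mer_distribution(model, sizes[length(sizes)], detected = TRUE)
    dimer_upper <- pmf_quantile(d2, 0.99)
    band <- pmf_quantile(d12, c(0.01, 0.999))
    # with broad fitted components the dimer tail can reach past the
    # dodecamer's 1st percentile; clamp so the intermediate band is simply
    # empty rather than ill-defined
    band[1] <- max(band[1], dimer_upper)
    band[2] <- max(band[2], band[1])
    boundaries <- list(dimer_upper = dimer_upper,
                       dodecamer_band = band,
                       aggregate_lower = band[2])
  }
  b <- c(boundaries$dimer_upper, boundaries$dodecamer_band[1],
         boundaries$aggregate_lower)
  if (any(diff(b) < 0)) stop("species boundaries overlap or are unordered")
  x <- hist_centers(fit$hist)
  wbin <- hist_widths(fit$hist)
  pos_res <- pmax(fit$residual, 0) * wbin
  smaller <- sum(fit$weights[1:2])
  dodecamer <- fit$weights[length(fit$weights)]
  intermediate <- sum(pos_res[x > boundaries$dimer_upper &
                              x < boundaries$dodecamer_band[1]])
  aggregate <- sum(pos_res[x > boundaries$aggregate_lower])
  raw <- c(smaller = unname(smaller), intermediate = intermediate,
           dodecamer = unname(dodecamer), aggregate = aggregate)
  pct <- 100 * raw / sum(raw)
  list(percentages = pct, boundaries = boundaries, raw = raw)
}

#' Full oligomeric-composition analysis of spot intensities
#'
#' Orchestrates the complete inference: histogram the corrected spot
#' intensities, fit the low-intensity peak to a monomer/dimer mixture,
#' estimate (or accept) the dark fraction by 12-fold auto-convolution
#' alignment, refit the low peak at the chosen dark fraction, fit the
#' three-component mixture, and summarize the species percentages.
#'
#' @param intensities Corrected spot intensities (ADU), or an
#'   [intensity_histogram()].
#' @param nu `"auto"` to estimate the dark fraction, or a fixed value.
#' @param nu_init Dark fraction used for the initial low-peak fit when
#'   `nu = "auto"` (default 0.3).
#' @param bin_width Optional histogram bin width (ADU).
#' @param seed Recorded in the report for provenance; this routine itself is
#'   deterministic.
#' @return A list of class `composition_report` with the fitted model, the
#'   dark-fraction estimate, the mixture fit, and species percentages.
#' @export
fit_oligomer_composition <- function(intensities, nu = "auto",
                                     nu_init = 0.3, bin_width = NULL,
                                     seed = NULL) {
  hist <- if (inherits(intensities, "intensity_histogram")) intensities
          else build_histogram(intensities, bin_width)
  low <- fit_monomer_dimer(hist, nu = if (identical(nu, "auto")) nu_init
                                      else nu)
  if (identical(nu, "auto")) {
    nu_hat <- as.numeric(estimate_dark_fraction(hist, low$model))
    low <- fit_monomer_dimer(hist, nu = nu_hat,
                             low_region = low$low_region)
  } else {
    nu_hat <- nu
  }
  fit <- three_component_fit(hist, low$model)
  species <- species_percentages(fit)
  structure(list(hist = hist, model = low$model, nu = nu_hat,
                 low_fit = low, mixture_fit = fit,
                 percentages = species$percentages,
                 boundaries = species$boundaries, seed = seed),
            class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat("oligomeric composition report\n")
  print(x$model)
  cat(sprintf("  dark fraction used: %.3f\n", x$nu))
  p <- x$percentages
  cat(sprintf(
    "  species: smaller %.1f%%, intermediate %.1f%%, dodecamer %.1f%%, aggregate %.1f%%\n",
    p["smaller"], p["intermediate"], p["dodecamer"], p["aggregate"]))
  invisible(x)
}

#' Write a composition report to JSON (plus residual CSV)
#'
#' @param report A `composition_report`.
#' @param path Output JSON path; a sibling `<path>_residual.csv` with the
#'   per-bin residual is written alongside.
#' @export
write_fit_report <- function(report, path) {
  stopifnot(inherits(report, "composition_report"))
  out <- list(model = list(mu = report$model$mu, sigma = report$model$sigma,
                           nu = report$nu),
              weights = as.list(report$mixture_fit$weights),
              percentages = as.list(report$percentages),
              objective = report$mixture_fit$objective,
              seed = report$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  res <- data.frame(bin_left_edge = report$hist$bin_edges[-length(report$hist$bin_edges)],
                    count = report$hist$counts,
                    residual_density = report$mixture_fit$residual)
  utils::write.csv(res, sub("\\.json$", "_residual.csv", path),
                   row.names = FALSE)
  invisible(path)
}
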