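#' Discretized intensity distribution
#'
#' A probability mass function on the uniform grid `grid_step * k`,
#' `k = 1..K`, with an optional point mass at exactly zero intensity (the
#' all-dark atom). Total mass is always 1.
#'
#' @param grid_step Intensity per bin (ADU), positive.
#' @param masses Non-negative masses for bins centered at `grid_step * k`.
#' @param zero_mass Probability mass at exactly zero intensity.
#' @return An object of class `intensity_pmf`.
#' @export
intensity_pmf <- function(grid_step, masses, zero_mass = 0) {
  if (!is.numeric(grid_step) || length(grid_step) != 1L || grid_step <= 0)
    stop("'grid_step' must be a single positive number")
  if (any(masses < 0)) stop("all masses must be non-negative")
  if (zero_mass < 0 || zero_mass > 1) stop("'zero_mass' must lie in [0, 1]")
  total <- zero_mass + sum(masses)
  if (abs(total - 1) > 1e-9)
    stop(sprintf("pmf mass must sum to 1 (got %.12f)", total))
  structure(list(grid_step = grid_step, zero_mass = zero_mass,
                 masses = as.numeric(masses)),
            class = "intensity_pmf")
}

#' @export
print.intensity_pmf <- function(x, ...) {
  cat(sprintf(
    "intensity pmf: %d bins of %.4g ADU (support to %.4g ADU), zero-atom mass %.4g, mean %.4g ADU\n",
    length(x$masses), x$grid_step, length(x$masses) * x$grid_step,
    x$zero_mass, pmf_mean(x)))
  invisible(x)
}

#' Grid of bin-center intensities of a pmf
#' @param pmf An [intensity_pmf()].
#' @return Bin centers in ADU (excluding the zero atom).
#' @export
pmf_grid <- function(pmf) {
  pmf$grid_step * seq_along(pmf$masses)
}

#' Mean of an intensity pmf (including the zero atom)
#' @param pmf An [intensity_pmf()].
#' @export
pmf_mean <- function(pmf) {
  sum(pmf_grid(pmf) * pmf$masses)
}

#' Quantile of an intensity pmf
#'
#' Smallest grid intensity at which the cumulative mass (including the zero
#' atom) reaches `p`.
#'
#' @param pmf An [intensity_pmf()].
#' @param p Probabilities in `[0, 1]`.
#' @export
pmf_quantile <- function(pmf, p) {
  stopifnot(all(p >= 0), all(p <= 1))
  cum <- pmf$zero_mass + cumsum(pmf$masses)
  x <- pmf_grid(pmf)
  vapply(p, function(pp) {
    if (pp <= pmf$zero_mass) return(0)
    x[which(cum >= pp - 1e-12)[1]]
  }, numeric(1))
}

#' Discretize the bright-fluorophore density onto a uniform grid
#'
#' Samples the log-normal density finely by assigning to the bin centered at
#' `grid_step * k` the exact CDF mass of the interval
#' `[(k - 1/2) h, (k + 1/2) h]`, then renormalizes so the masses sum to 1.
#' The result has no zero atom; see [apply_dark_fraction()].
#'
#' @param model A [monomer_model()]; its `nu` is ignored here.
#' @param grid_step Bin width (ADU). Default: 99.9th percentile / 256, so
#'   the monomer density spans well over 200 bins.
#' @param x_max Upper end of the grid (ADU). Must cover essentially all of
#'   the density's mass. Default: 4 x the 99.9th percentile.
#' @param max_truncated Largest tolerated truncated tail mass before an
#'   error is raised (default `1e-4`).
#' @return An [intensity_pmf()] with `zero_mass = 0`.
#' @export
discretize <- function(model, grid_step = NULL, x_max = NULL,
                       max_truncated = 1e-4) {
  stopifnot(inherits(model, "monomer_model"))
  q999 <- stats::qlnorm(0.999, model$mu, model$sigma)
  if (is.null(grid_step)) grid_step <- q999 / 256
  if (is.null(x_max)) x_max <- 4 * q999
  if (grid_step <= 0) stop("'grid_step' must be positive")
  k_max <- floor(x_max / grid_step)
  if (k_max < 2)
    stop("grid_step too large relative to x_max: degenerate grid")
  upper <- (seq_len(k_max) + 0.5) * grid_step
  lower <- upper - grid_step
  cdf <- stats::plnorm(c(lower[1], upper), model$mu, model$sigma)
  masses <- diff(cdf)
  truncated <- 1 - cdf[length(cdf)] + cdf[1]
  if (truncated > max_truncated)
    stop(sprintf(
      "grid truncates %.3g of the density mass (tolerance %.3g); increase x_max or shrink grid_step",
      truncated, max_truncated))
  intensity_pmf(grid_step, masses / sum(masses), zero_mass = 0)
}

#' Insert the dark-fluorophore atom into a pmf
#'
#' Sets the mass at exactly zero intensity to the dark fraction `nu` and
#' rescales the positive bins by `1 - nu`, so the pmf stays normalized.
#' Convolving the result with itself then carries the effect of dark
#' fluorophores through to oligomer intensity distributions.
#'
#' @param pmf An [intensity_pmf()] with no zero atom.
#' @param nu Dark fraction in `[0, 1)`.
#' @return An [intensity_pmf()] with `zero_mass = nu`.
#' @export
apply_dark_fraction <- function(pmf, nu) {
  stopifnot(inherits(pmf, "intensity_pmf"))
  if (!is.numeric(nu) || length(nu) != 1L || nu < 0 || nu >= 1)
    stop("'nu' must lie in [0, 1)")
  if (pmf$zero_mass != 0)
    stop("input pmf already carries a zero atom")
  intensity_pmf(pmf$grid_step, pmf$masses * (1 - nu), zero_mass = nu)
}

# n-fold self-convolution of a mass vector (index 1 = mass at zero) by
# repeated squaring with FFT linear convolution. Exact support length is
# n * (length(v) - 1) + 1.
self_convolve <- function(v, n) {
  if (n == 1) return(v)
  conv <- function(a, b) {
    na <- length(a) + length(b) - 1L
    nfft <- stats::nextn(na, 2)
    fa <- stats::fft(c(a, numeric(nfft - length(a))))
    fb <- stats::fft(c(b, numeric(nfft - length(b))))
    out <- Re(stats::fft(fa * fb, inverse = TRUE)) / nfft
    out <- out[seq_len(na)]
    # clamp FFT round-off; anything sizeably negative is a real bug
    stopifnot(all(out > -1e-9))
    pmax(out, 0)
  }
  acc <- NULL
  base <- v
  m <- n
  while (m > 0) {
    if (m %% 2 == 1) acc <- if (is.null(acc)) base else conv(acc, base)
    m <- m %/% 2
    if (m > 0) base <- conv(base, base)
  }
  acc
}

#' Predicted intensity distribution of an n-subunit oligomer
#'
#' Convolves the dark-fraction-bearing monomer pmf with itself `n_subunits`
#' times. The zero atom of the result is `nu^n` (all subunits dark). The
#' `detected` form drops that atom and renormalizes by `1 - nu^n`, since a
#' spot with every fluorophore dark is never observed.
#'
#' @param model A [monomer_model()] (its `nu` supplies the dark fraction).
#' @param n_subunits Number of subunits, `>= 1`.
#' @param grid_step,x_max Grid controls; defaults are chosen so the monomer
#'   spans > 200 bins and `x_max = (n_subunits + 2)` x the monomer 99.9th
#'   percentile, which supports the n-fold convolution without truncation
#'   (14 x for the dodecamer).
#' @param detected If `TRUE`, return the distribution conditional on at
#'   least one bright subunit.
#' @param max_truncated Tolerated mass lost beyond `x_max` (default `1e-6`).
#' @return An [intensity_pmf()].
#' @export
n_mer_distribution <- function(model, n_subunits, grid_step = NULL,
                               x_max = NULL, detected = FALSE,
                               max_truncated = 1e-6) {
  stopifnot(inherits(model, "monomer_model"))
  if (n_subunits < 1 || n_subunits != round(n_subunits))
    stop("'n_subunits' must be a positive integer")
  q999 <- stats::qlnorm(0.999, model$mu, model$sigma)
  if (is.null(grid_step)) grid_step <- q999 / 256
  if (is.null(x_max)) x_max <- (n_subunits + 2) * q999
  mono <- discretize(model, grid_step = grid_step,
                     x_max = min(x_max, 4 * q999))
  dark <- apply_dark_fraction(mono, model$nu)
  v <- c(dark$zero_mass, dark$masses)
  full <- self_convolve(v, n_subunits)
  k_keep <- floor(x_max / grid_step)
  if (length(full) - 1L > k_keep) {
    tail_mass <- sum(full[(k_keep + 2L):length(full)])
    if (tail_mass > max_truncated)
      stop(sprintf(
        "x_max truncates %.3g of the %d-mer mass; increase x_max", tail_mass,
        n_subunits))
    full <- full[seq_len(k_keep + 1L)]
  }
  total <- sum(full)
  zero <- full[1] / total
  masses <- full[-1] / total
  if (detected) {
    out <- intensity_pmf(grid_step, masses / sum(masses), zero_mass = 0)
  } else {
    out <- intensity_pmf(grid_step, masses, zero_mass = zero)
  }
  out
}

# Density of a pmf integrated over arbitrary histogram bins, via linear
# interpolation of the cumulative mass at the bin edges. Returns density
# (1/ADU) per histogram bin; the zero atom is excluded (detected spots only).
pmf_bin_density <- function(pmf, bin_edges) {
  x <- pmf_grid(pmf)
  cum <- pmf$zero_mass + cumsum(pmf$masses)
  cdf_at <- stats::approx(c(0, x), c(pmf$zero_mass, cum), xout = bin_edges,
                          yleft = 0, yright = cum[length(cum)], rule = 2)$y
  diff(cdf_at) / diff(bin_edges)
}
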