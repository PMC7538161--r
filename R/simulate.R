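#' Specification of a synthetic oligomer mixture
#'
#' Describes the population of spots the generator emits: a set of oligomer
#' sizes with their fractions, the single-fluorophore intensity model
#' (including the dark fraction), and the number of spots.
#'
#' @param components `data.frame` with columns `n_subunits` and `fraction`;
#'   fractions must sum to 1.
#' @param model A [monomer_model()].
#' @param n_spots Number of molecules to simulate.
#' @param seed Integer seed for reproducibility, or `NULL`.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(components, model, n_spots, seed = NULL) {
  stopifnot(is.data.frame(components),
            all(c("n_subunits", "fraction") %in% names(components)),
            inherits(model, "monomer_model"))
  if (any(components$n_subunits < 1) ||
      any(components$n_subunits != round(components$n_subunits)))
    stop("'n_subunits' must be positive integers")
  if (abs(sum(components$fraction) - 1) > 1e-9)
    stop("component fractions must sum to 1")
  if (n_spots < 1) stop("'n_spots' must be positive")
  structure(list(components = components, model = model,
                 n_spots = as.integer(n_spots), seed = seed),
            class = "mixture_spec")
}

#' Paper-like synthetic scenario
#'
#' The default study condition used throughout the tests and the worked
#' analyses: single-fluorophore intensity `mu = ln 500`, `sigma = 0.35`,
#' dark fraction `nu = 0.3`, and a mixture of 25% monomers, 10% dimers,
#' 5% hexamers and 60% dodecamers, 20,000 molecules. This reproduces the
#' qualitative two-peak intensity histogram of mEGFP-tagged CaMKII-alpha
#' holoenzyme preparations; the values are scenario defaults, not
#' measurements.
#'
#' @param n_spots Number of molecules (default 20000).
#' @param seed Integer seed.
#' @param smaller_fraction Optionally override the combined monomer + dimer
#'   fraction (split 2.5:1 monomer:dimer, the default ratio); the
#'   dodecamer fraction absorbs the difference.
#' @return A [mixture_spec()].
#' @export
holoenzyme_scenario <- function(n_spots = 20000, seed = 1,
                                smaller_fraction = NULL) {
  frac <- c(monomer = 0.25, dimer = 0.10, hexamer = 0.05, dodecamer = 0.60)
  if (!is.null(smaller_fraction)) {
    stopifnot(smaller_fraction > 0, smaller_fraction < 0.95)
    frac["monomer"] <- smaller_fraction * (2.5 / 3.5)
    frac["dimer"] <- smaller_fraction * (1 / 3.5)
    frac["dodecamer"] <- 1 - frac["monomer"] - frac["dimer"] - frac["hexamer"]
  }
  mixture_spec(
    components = data.frame(n_subunits = c(1L, 2L, 6L, 12L),
                            fraction = unname(frac)),
    model = monomer_model(mu = log(500), sigma = 0.35, nu = 0.3),
    n_spots = n_spots, seed = seed)
}

#' Simulate a table of spot intensities with truth labels
#'
#' For each molecule: draw an oligomer size from the mixture, a bright
#' count `b ~ Binomial(n, 1 - nu)`, and, if `b > 0`, an intensity equal to
#' the sum of `b` independent log-normal draws. Molecules with `b = 0` are
#' recorded as undetectable (intensity 0, `detected = FALSE`): a spot whose
#' fluorophores are all dark never appears in an image.
#'
#' @param spec A [mixture_spec()].
#' @return A `data.frame` with columns `spot_id`, `n_subunits`, `n_bright`,
#'   `intensity`, `detected`.
#' @export
simulate_spot_table <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  m <- spec$model
  idx <- sample.int(nrow(spec$components), spec$n_spots, replace = TRUE,
                    prob = spec$components$fraction)
  n <- spec$components$n_subunits[idx]
  b <- stats::rbinom(spec$n_spots, size = n, prob = 1 - m$nu)
  intensity <- numeric(spec$n_spots)
  tot <- sum(b)
  if (tot > 0) {
    draws <- stats::rlnorm(tot, meanlog = m$mu, sdlog = m$sigma)
    owner <- rep.int(seq_len(spec$n_spots), b)
    sums <- rowsum(draws, owner)
    intensity[as.integer(rownames(sums))] <- sums[, 1]
  }
  data.frame(spot_id = seq_len(spec$n_spots),
             n_subunits = n, n_bright = b,
             intensity = intensity, detected = b > 0)
}

#' Camera and optics description for synthetic TIRF frames
#'
#' @param read_noise_sd Gaussian read-noise standard deviation (ADU).
#' @param gain Multiplicative gain applied to the optical signal.
#' @param offset Camera baseline (ADU).
#' @param psf_sigma_px Gaussian PSF standard deviation (pixels).
#' @param field_profile Unit-mean illumination profile: `NULL` (uniform), a
#'   matrix matching the frame, or a function `(nrow, ncol) -> matrix`.
#' @return An object of class `camera_spec`.
#' @export
camera_spec <- function(read_noise_sd = 6, gain = 1, offset = 100,
                        psf_sigma_px = 1.5, field_profile = NULL) {
  stopifnot(read_noise_sd >= 0, psf_sigma_px > 0, gain > 0)
  structure(list(read_noise_sd = read_noise_sd, gain = gain,
                 offset = offset, psf_sigma_px = psf_sigma_px,
                 field_profile = field_profile),
            class = "camera_spec")
}

#' Gaussian vignette illumination profile
#'
#' Radially symmetric Gaussian falloff, normalized to unit spatial mean, as
#' a stand-in for uneven TIRF illumination and fringe effects.
#'
#' @param nrow,ncol Frame dimensions (pixels).
#' @param strength Relative falloff at the frame corner (0 = uniform).
#' @return A unit-mean matrix.
#' @export
vignette_field <- function(nrow, ncol, strength = 0.4) {
  cy <- (nrow - 1) / 2; cx <- (ncol - 1) / 2
  r2 <- outer((seq_len(nrow) - 1 - cy)^2, (seq_len(ncol) - 1 - cx)^2, "+")
  w2 <- max(r2) / (2 * log(1 / (1 - strength)))
  f <- exp(-r2 / (2 * w2))
  f / mean(f)
}

resolve_field <- function(cam, nrow, ncol) {
  f <- cam$field_profile
  if (is.null(f)) return(matrix(1, nrow, ncol))
  if (is.function(f)) f <- f(nrow, ncol)
  stopifnot(is.matrix(f), nrow(f) == nrow, ncol(f) == ncol)
  f
}

# Add one Gaussian PSF of total (integrated) intensity `intensity` at
# (x0, y0) (0-based pixel-center coordinates) into `frame`, in place.
render_psf <- function(frame, x0, y0, intensity, sigma) {
  half <- ceiling(5 * sigma)
  ny <- nrow(frame); nx <- ncol(frame)
  rows <- max(1, round(y0) + 1 - half):min(ny, round(y0) + 1 + half)
  cols <- max(1, round(x0) + 1 - half):min(nx, round(x0) + 1 + half)
  gy <- exp(-((rows - 1 - y0)^2) / (2 * sigma^2))
  gx <- exp(-((cols - 1 - x0)^2) / (2 * sigma^2))
  patch <- outer(gy, gx) * (intensity / (2 * pi * sigma^2))
  frame[rows, cols] <- frame[rows, cols] + patch
  frame
}

#' Simulate TIRF image stacks from a spot table
#'
#' Distributes detected spots over frames at random positions (with a
#' minimum pairwise separation), renders each as an integrated Gaussian
#' PSF, multiplies by the illumination profile, and adds the camera
#' baseline and Gaussian read noise. Matching dark frames (baseline +
#' noise) and flat-field frames (uniform bright scene times the
#' illumination profile) are returned alongside, as acquired in a real
#' calibration.
#'
#' @param table Spot table from [simulate_spot_table()] (undetectable rows
#'   are skipped).
#' @param cam A [camera_spec()].
#' @param frame_shape `c(nrow, ncol)` in pixels.
#' @param spots_per_frame Target number of spots rendered per frame.
#' @param n_dark,n_flat Number of dark and flat calibration frames.
#' @param flat_level Mean optical level of the flat-field scene (ADU).
#' @param min_separation Minimum distance between spot centers (pixels).
#' @param margin Border (pixels) kept free of spot centers.
#' @param seed Integer seed, or `NULL`.
#' @return A list with `sample`, `dark`, `flat` (each an `image_stack`) and
#'   `truth` (data.frame `spot_id`, `frame`, `x_px`, `y_px`, `intensity`).
#' @export
simulate_image_stack <- function(table, cam = camera_spec(),
                                 frame_shape = c(512L, 512L),
                                 spots_per_frame = 50L,
                                 n_dark = 50L, n_flat = 20L,
                                 flat_level = 1000,
                                 min_separation = 12,
                                 margin = 10, seed = NULL) {
  stopifnot(inherits(cam, "camera_spec"))
  if (!is.null(seed)) set.seed(seed)
  det <- table[table$detected, , drop = FALSE]
  ny <- frame_shape[1]; nx <- frame_shape[2]
  n_frames <- max(1L, ceiling(nrow(det) / spots_per_frame))
  frame_of <- rep(seq_len(n_frames), each = spots_per_frame)[seq_len(nrow(det))]
  field <- resolve_field(cam, ny, nx)

  place_spots <- function(k) {
    # rejection-sample positions with a minimum pairwise separation
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0L
    while (length(xs) < k && tries < 200L * k) {
      x <- stats::runif(1, margin, nx - 1 - margin)
      y <- stats::runif(1, margin, ny - 1 - margin)
      if (!length(xs) ||
          min((xs - x)^2 + (ys - y)^2) >= min_separation^2) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
      tries <- tries + 1L
    }
    if (length(xs) < k) stop("could not place spots at the requested density")
    cbind(x = xs, y = ys)
  }

  frames <- array(0, dim = c(ny, nx, n_frames))
  truth <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    idx <- which(frame_of == f)
    pos <- place_spots(length(idx))
    signal <- matrix(0, ny, nx)
    for (j in seq_along(idx))
      signal <- render_psf(signal, pos[j, "x"], pos[j, "y"],
                           det$intensity[idx[j]], cam$psf_sigma_px)
    frames[, , f] <- cam$gain * signal * field + cam$offset +
      matrix(stats::rnorm(ny * nx, sd = cam$read_noise_sd), ny, nx)
    truth[[f]] <- data.frame(spot_id = det$spot_id[idx], frame = f,
                             x_px = pos[, "x"], y_px = pos[, "y"],
                             intensity = det$intensity[idx])
  }
  dark <- array(cam$offset + stats::rnorm(ny * nx * n_dark,
                                          sd = cam$read_noise_sd),
                dim = c(ny, nx, n_dark))
  flat <- array(0, dim = c(ny, nx, n_flat))
  for (f in seq_len(n_flat))
    flat[, , f] <- cam$gain * flat_level * field + cam$offset +
      matrix(stats::rnorm(ny * nx, sd = cam$read_noise_sd), ny, nx)
  list(sample = image_stack(frames),
       dark = image_stack(dark),
       flat = image_stack(flat),
       truth = do.call(rbind, truth))
}

#' Simulate a stepwise photobleaching trace
#'
#' Draws a bright-fluorophore count `b ~ Binomial(n, 1 - nu)`; each bright
#' fluorophore bleaches irreversibly at a geometric (per-frame exponential)
#' time, and the trace is `unit_intensity` times the surviving count plus
#' Gaussian noise.
#'
#' @param n_subunits Number of subunits in the complex.
#' @param nu Dark fraction.
#' @param unit_intensity Intensity contributed by one bright fluorophore.
#' @param bleach_rate_per_frame Per-frame bleaching probability.
#' @param n_frames Trace length (frames).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed, or `NULL`.
#' @return A [bleach_trace()] with attributes `true_steps` (number of
#'   distinct downward steps) and `n_bright`.
#' @export
simulate_bleach_trace <- function(n_subunits, nu = 0.3, unit_intensity = 100,
                                  bleach_rate_per_frame = 0.03,
                                  n_frames = 200L, noise_sd = 20,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- stats::rbinom(1, n_subunits, 1 - nu)
  bleach_frame <- if (b > 0) stats::rgeom(b, bleach_rate_per_frame) + 1L
                  else integer(0)
  survivors <- vapply(seq_len(n_frames) - 1L,
                      function(t) sum(bleach_frame > t), numeric(1))
  values <- unit_intensity * survivors +
    stats::rnorm(n_frames, sd = noise_sd)
  tr <- bleach_trace(values)
  # a bleach at frame k is visible as a step only if k is inside the trace
  attr(tr, "true_steps") <- length(unique(bleach_frame[bleach_frame <= n_frames - 1L]))
  attr(tr, "n_bright") <- b
  tr
}
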