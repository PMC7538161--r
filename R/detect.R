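# 1-D convolution of every column (axis = 1) or row (axis = 2) of a matrix
# with kernel `k` (odd length), replicate padding, via shift-and-add.
conv_sep1 <- function(img, k, axis) {
  half <- (length(k) - 1L) %/% 2L
  ny <- nrow(img); nx <- ncol(img)
  if (axis == 1L) {
    pad <- rbind(img[rep(1L, half), , drop = FALSE], img,
                 img[rep(ny, half), , drop = FALSE])
    out <- matrix(0, ny, nx)
    for (j in seq_along(k))
      out <- out + k[j] * pad[j:(ny + j - 1L), , drop = FALSE]
    out
  } else {
    t(conv_sep1(t(img), k, 1L))
  }
}

# Scale-normalized Laplacian-of-Gaussian response sigma^2 * (Gxx + Gyy) * I,
# computed as two separable passes. Bright blobs of matched size give a
# strongly negative response at their centers.
log_response <- function(img, sigma) {
  half <- ceiling(4 * sigma)
  t <- (-half):half
  g <- exp(-t^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  gxx <- (t^2 / sigma^4 - 1 / sigma^2) * g
  sigma^2 * (conv_sep1(conv_sep1(img, gxx, 2L), g, 1L) +
             conv_sep1(conv_sep1(img, g, 2L), gxx, 1L))
}

quadratic_offset <- function(fm, f0, fp) {
  den <- fm - 2 * f0 + fp
  if (abs(den) < .Machine$double.eps) return(0)
  off <- 0.5 * (fm - fp) / den
  max(-0.5, min(0.5, off))
}

#' Detect diffraction-limited spots with a Laplacian-of-Gaussian detector
#'
#' Filters the frame with a scale-normalized Laplacian of Gaussian matched
#' to the given spot diameter (`sigma = diameter / (2 sqrt(2))`), finds
#' local maxima of the negated response, refines each to sub-pixel accuracy
#' by quadratic interpolation, and scores it with
#' `quality = -LoG response x spot area`. Detections with quality at or
#' below `quality_threshold` are discarded; an empty result is valid.
#' Coordinates are 0-based with the pixel-center convention. Candidate
#' maxima closer together than one diameter are merged, keeping the higher
#' quality one.
#'
#' @param frame Matrix of corrected intensities (`NA` pixels are treated as
#'   the frame median).
#' @param diameter_px Expected spot diameter in pixels (default 6).
#' @param quality_threshold Minimum detector quality (default 300). The
#'   quality scale is tied to this detector's definition; thresholds from
#'   other software are not directly transferable.
#' @return A `data.frame` with columns `x_px`, `y_px`, `quality`.
#' @export
detect_spots <- function(frame, diameter_px = 6, quality_threshold = 300) {
  stopifnot(is.matrix(frame))
  if (anyNA(frame)) frame[is.na(frame)] <- stats::median(frame, na.rm = TRUE)
  sigma <- diameter_px / (2 * sqrt(2))
  resp <- -log_response(frame, sigma)
  area <- pi * (diameter_px / 2)^2
  ny <- nrow(resp); nx <- ncol(resp)
  if (ny < 3 || nx < 3) return(data.frame(x_px = numeric(0),
                                          y_px = numeric(0),
                                          quality = numeric(0)))
  core <- resp[2:(ny - 1), 2:(nx - 1)]
  is_max <- core > resp[1:(ny - 2), 2:(nx - 1)] &
            core >= resp[3:ny,       2:(nx - 1)] &
            core > resp[2:(ny - 1), 1:(nx - 2)] &
            core >= resp[2:(ny - 1), 3:nx] &
            core > resp[1:(ny - 2), 1:(nx - 2)] &
            core >= resp[1:(ny - 2), 3:nx] &
            core > resp[3:ny,       1:(nx - 2)] &
            core >= resp[3:ny,       3:nx] &
            (core * area) > quality_threshold
  hits <- which(is_max, arr.ind = TRUE)
  if (nrow(hits) == 0) return(data.frame(x_px = numeric(0),
                                         y_px = numeric(0),
                                         quality = numeric(0)))
  iy <- hits[, 1] + 1L; ix <- hits[, 2] + 1L
  qual <- resp[cbind(iy, ix)] * area
  dy <- vapply(seq_along(iy), function(k)
    quadratic_offset(resp[iy[k] - 1L, ix[k]], resp[iy[k], ix[k]],
                     resp[iy[k] + 1L, ix[k]]), numeric(1))
  dx <- vapply(seq_along(ix), function(k)
    quadratic_offset(resp[iy[k], ix[k] - 1L], resp[iy[k], ix[k]],
                     resp[iy[k], ix[k] + 1L]), numeric(1))
  out <- data.frame(x_px = ix - 1 + dx, y_px = iy - 1 + dy, quality = qual)
  # merge detections closer than one diameter, keeping the best
  out <- out[order(-out$quality), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) {
      later <- (i + 1):nrow(out)
      d2 <- (out$x_px[later] - out$x_px[i])^2 +
            (out$y_px[later] - out$y_px[i])^2
      keep[later][d2 < diameter_px^2] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep spots inside a centered rectangular region of interest
#'
#' Retains spots whose centroid lies in the half-open centered window
#' `[cx - w/2, cx + w/2) x [cy - h/2, cy + h/2)`, with
#' `cx = ncol/2`, `cy = nrow/2` in 0-based pixel coordinates. Used to
#' exclude the frame edges where TIRF illumination is heterogeneous.
#'
#' @param spots `data.frame` with `x_px`, `y_px`.
#' @param frame_shape `c(nrow, ncol)` of the source frame (pixels).
#' @param width,height ROI size in pixels (default 400 x 400).
#' @return The filtered `data.frame`.
#' @export
roi_filter <- function(spots, frame_shape, width = 400, height = 400) {
  ny <- frame_shape[1]; nx <- frame_shape[2]
  if (width > nx || height > ny)
    stop("ROI is larger than the frame")
  cx <- nx / 2; cy <- ny / 2
  keep <- spots$x_px >= cx - width / 2 & spots$x_px < cx + width / 2 &
          spots$y_px >= cy - height / 2 & spots$y_px < cy + height / 2
  out <- spots[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

disk_offsets <- function(radius) {
  r <- ceiling(radius)
  o <- expand.grid(dy = -r:r, dx = -r:r)
  o[o$dy^2 + o$dx^2 <= radius^2, , drop = FALSE]
}

annulus_offsets <- function(inner, outer) {
  r <- ceiling(outer)
  o <- expand.grid(dy = -r:r, dx = -r:r)
  d2 <- o$dy^2 + o$dx^2
  o[d2 > inner^2 & d2 <= outer^2, , drop = FALSE]
}

#' Measure background-corrected integrated spot intensities
#'
#' Sums the pixels in a disk footprint of the given diameter around each
#' spot and subtracts the local median background, estimated in an annulus
#' around the footprint and scaled by the footprint area:
#' `corrected = sum(footprint) - median(annulus) * area`. Annulus pixels
#' falling inside any other spot's footprint are excluded from the median.
#'
#' @param frame Matrix of corrected intensities.
#' @param spots `data.frame` with `x_px`, `y_px` (0-based centers).
#' @param diameter_px Footprint diameter (default 6 px; radius `r = 3`).
#' @param annulus_inner,annulus_outer Annulus radii; defaults `r + 1` and
#'   `r + 4`.
#' @return `spots` with columns `area_px2`, `raw_intensity`,
#'   `background_median`, `corrected_intensity` appended.
#' @export
measure_intensity <- function(frame, spots, diameter_px = 6,
                              annulus_inner = NULL, annulus_outer = NULL) {
  stopifnot(is.matrix(frame))
  r <- diameter_px / 2
  if (is.null(annulus_inner)) annulus_inner <- r + 1
  if (is.null(annulus_outer)) annulus_outer <- r + 4
  ny <- nrow(frame); nx <- ncol(frame)
  foot <- disk_offsets(r)
  ann <- annulus_offsets(annulus_inner, annulus_outer)
  # mark every pixel covered by any spot footprint
  covered <- matrix(FALSE, ny, nx)
  centers <- cbind(round(spots$y_px) + 1L, round(spots$x_px) + 1L)
  for (i in seq_len(nrow(spots))) {
    yy <- centers[i, 1] + foot$dy; xx <- centers[i, 2] + foot$dx
    ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
    covered[cbind(yy[ok], xx[ok])] <- TRUE
  }
  out <- spots
  out$area_px2 <- NA_real_; out$raw_intensity <- NA_real_
  out$background_median <- NA_real_; out$corrected_intensity <- NA_real_
  for (i in seq_len(nrow(spots))) {
    yy <- centers[i, 1] + foot$dy; xx <- centers[i, 2] + foot$dx
    ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
    vals <- frame[cbind(yy[ok], xx[ok])]
    area <- sum(ok)
    ay <- centers[i, 1] + ann$dy; ax <- centers[i, 2] + ann$dx
    aok <- ay >= 1 & ay <= ny & ax >= 1 & ax <= nx
    aidx <- cbind(ay[aok], ax[aok])
    free <- !covered[aidx]
    bg_vals <- frame[aidx][free]
    bg <- if (length(bg_vals)) stats::median(bg_vals, na.rm = TRUE) else 0
    out$area_px2[i] <- area
    out$raw_intensity[i] <- sum(vals, na.rm = TRUE)
    out$background_median[i] <- bg
    out$corrected_intensity[i] <- sum(vals, na.rm = TRUE) - bg * area
  }
  out
}

#' Run the full spot pipeline on simulated or acquired stacks
#'
#' Illumination-corrects the sample stack, then per frame: detects spots,
#' restricts to the central region of interest, and measures
#' background-corrected intensities.
#'
#' @param sample,dark,flat [image_stack()]s.
#' @param diameter_px,quality_threshold Passed to [detect_spots()].
#' @param roi `c(width, height)` of the central ROI, or `NULL` to skip.
#' @return A spot table `data.frame` with a `frame` column.
#' @export
process_stack <- function(sample, dark, flat, diameter_px = 6,
                          quality_threshold = 300, roi = c(400, 400)) {
  corrected <- correct_illumination(sample, dark, flat)
  shape <- dim(corrected$frames)[1:2]
  res <- lapply(seq_len(n_frames(corrected)), function(f) {
    fr <- get_frame(corrected, f)
    spots <- detect_spots(fr, diameter_px, quality_threshold)
    if (!is.null(roi)) spots <- roi_filter(spots, shape, roi[1], roi[2])
    if (nrow(spots) == 0) return(NULL)
    spots <- measure_intensity(fr, spots, diameter_px)
    spots$frame <- f
    spots
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      quality = numeric(0), area_px2 = numeric(0),
                      raw_intensity = numeric(0),
                      background_median = numeric(0),
                      corrected_intensity = numeric(0), frame = integer(0))
  out$spot_id <- seq_len(nrow(out))
  out
}
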