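#' TIRF image stack
#'
#' A stack of equally sized frames stored as a `nrow x ncol x n_frames`
#' array, with the acquisition frame interval in seconds.
#'
#' @param frames 3-D numeric array (or a single matrix).
#' @param frame_interval Seconds between frames (default 0.080 s, the
#'   standard 80 ms exposure).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_interval = 0.080) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (!all(is.finite(frames))) stop("frame intensities must be finite")
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image stack: %d frames of %d x %d px, %.0f ms interval\n",
              d[3], d[1], d[2], 1000 * x$frame_interval))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3]

get_frame <- function(stack, i) stack$frames[, , i]

as_stack <- function(x) {
  if (inherits(x, "image_stack")) x else image_stack(x)
}

#' Read / write multi-page TIFF stacks
#'
#' @param path TIFF file path.
#' @param frame_interval Frame interval (s) to attach on read.
#' @return `read_image_stack` returns an [image_stack()].
#' @export
read_image_stack <- function(path, frame_interval = 0.080) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  image_stack(frames, frame_interval)
}

#' @param stack An [image_stack()]; intensities are rescaled to `[0, 1]`
#'   float for storage and the scale recorded is lost, so round-trips are
#'   exact only up to that linear rescaling.
#' @rdname read_image_stack
#' @export
write_image_stack <- function(stack, path) {
  stack <- as_stack(stack)
  hi <- max(stack$frames); lo <- min(stack$frames)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(n_frames(stack)),
                  function(i) (get_frame(stack, i) - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Dark-frame and flat-field illumination correction
#'
#' Subtracts the mean dark frame (camera baseline) from every sample frame
#' and divides by the unit-mean normalized illumination field measured from
#' the flat-field (e.g. fluorescein) stack:
#' `corrected = (sample - mean(dark)) / normalize(mean(flat) - mean(dark))`.
#' Pixels where the normalized field falls below 0.05 are masked to `NA`
#' rather than amplified.
#'
#' @param sample,dark,flat [image_stack()]s (or arrays) of matching frame
#'   shape. Fewer than 50 dark frames, or a mismatched frame interval,
#'   raises a warning.
#' @return An [image_stack()] of corrected frames (possibly containing
#'   `NA` at masked pixels).
#' @export
correct_illumination <- function(sample, dark, flat) {
  sample <- as_stack(sample); dark <- as_stack(dark); flat <- as_stack(flat)
  ds <- dim(sample$frames)[1:2]
  if (!identical(ds, dim(dark$frames)[1:2]) ||
      !identical(ds, dim(flat$frames)[1:2]))
    stop("sample, dark and flat frames must share the same shape")
  if (n_frames(dark) < 50)
    warning("fewer than 50 dark frames; baseline estimate may be noisy")
  if (!isTRUE(all.equal(dark$frame_interval, sample$frame_interval)))
    warning("dark-frame exposure differs from sample exposure")
  mean_dark <- rowMeans(dark$frames, dims = 2)
  mean_flat <- rowMeans(flat$frames, dims = 2)
  if (mean(mean_flat) <= mean(mean_dark))
    stop("flat-field stack is not brighter than the dark stack")
  field <- mean_flat - mean_dark
  field <- field / mean(field)
  field[field < 0.05] <- NA
  out <- sample$frames
  for (i in seq_len(n_frames(sample)))
    out[, , i] <- (out[, , i] - mean_dark) / field
  stk <- sample
  stk$frames <- out
  # masked pixels are NA by design; bypass the finite check
  structure(list(frames = out, frame_interval = sample$frame_interval),
            class = "image_stack")
}
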