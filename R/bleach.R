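#' Photobleaching trace
#'
#' Per-frame maximum spot intensity over time, with an optional
#' classification into single-, two- or multi-step bleaching.
#'
#' @param values Per-frame intensities (ADU).
#' @param frame_interval Seconds between frames (default 0.080 s).
#' @return An object of class `bleach_trace`.
#' @export
bleach_trace <- function(values, frame_interval = 0.080) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  structure(list(values = as.numeric(values),
                 frame_interval = frame_interval),
            class = "bleach_trace")
}

#' @export
print.bleach_trace <- function(x, ...) {
  cat(sprintf("bleach trace: %d frames, start %.1f, end %.1f\n",
              length(x$values), x$values[1],
              x$values[length(x$values)]))
  invisible(x)
}

#' Extract a photobleaching trace for one spot
#'
#' Builds the trace as the maximum intensity inside the spot's disk
#' footprint in every frame, following the convention of plotting maximum
#' spot intensities as a function of time.
#'
#' @param stack An [image_stack()].
#' @param spot One-row `data.frame` (or list) with `x_px`, `y_px`.
#' @param diameter_px Footprint diameter (default 6 px).
#' @return A [bleach_trace()].
#' @export
extract_trace <- function(stack, spot, diameter_px = 6) {
  stack <- as_stack(stack)
  foot <- disk_offsets(diameter_px / 2)
  ny <- dim(stack$frames)[1]; nx <- dim(stack$frames)[2]
  yy <- round(spot$y_px[1]) + 1L + foot$dy
  xx <- round(spot$x_px[1]) + 1L + foot$dx
  ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
  idx <- cbind(yy[ok], xx[ok])
  vals <- vapply(seq_len(n_frames(stack)),
                 function(f) max(stack$frames[, , f][idx]), numeric(1))
  bleach_trace(vals, stack$frame_interval)
}

# Piecewise-constant fit by greedy change-point insertion: at each round,
# add the single breakpoint that lowers the RSS most, and keep it while the
# BIC improves. Returns breakpoints (index of last frame of each segment)
# and fitted levels.
greedy_steps <- function(y, max_steps = 12L) {
  n <- length(y)
  bic <- function(rss, k) n * log(max(rss, 1e-12) / n) + 2 * k * log(n)
  seg_rss <- function(lo, hi) {
    v <- y[lo:hi]
    sum((v - mean(v))^2)
  }
  # best single split of segment [lo, hi]; returns c(gain, split)
  best_split <- function(lo, hi) {
    if (hi - lo < 1) return(c(0, NA))
    v <- y[lo:hi]
    m <- length(v)
    cs <- cumsum(v); tot <- cs[m]
    k <- seq_len(m - 1)
    rss_l <- cumsum(v^2)[k] - cs[k]^2 / k
    rss_r <- (sum(v^2) - cumsum(v^2)[k]) - (tot - cs[k])^2 / (m - k)
    base <- seg_rss(lo, hi)
    gains <- base - (rss_l + rss_r)
    j <- which.max(gains)
    c(gains[j], lo + j - 1L)
  }
  breaks <- integer(0)
  rss <- seg_rss(1L, n)
  current_bic <- bic(rss, 0L)
  repeat {
    if (length(breaks) >= max_steps) break
    bounds <- c(0L, sort(breaks), n)
    cand <- t(vapply(seq_len(length(bounds) - 1L), function(s)
      best_split(bounds[s] + 1L, bounds[s + 1L]), numeric(2)))
    j <- which.max(cand[, 1])
    if (!is.finite(cand[j, 1]) || cand[j, 1] <= 0) break
    new_rss <- rss - cand[j, 1]
    new_bic <- bic(new_rss, length(breaks) + 1L)
    if (new_bic >= current_bic) break
    breaks <- sort(c(breaks, as.integer(cand[j, 2])))
    rss <- new_rss
    current_bic <- new_bic
  }
  bounds <- c(0L, breaks, n)
  levels <- vapply(seq_len(length(bounds) - 1L), function(s)
    mean(y[(bounds[s] + 1L):bounds[s + 1L]]), numeric(1))
  list(breaks = breaks, levels = levels, rss = rss)
}

#' Classify a photobleaching trace by its number of downward steps
#'
#' Fits a piecewise-constant model by greedy change-point insertion
#' (accepted while the BIC improves), discards level changes smaller than
#' `min_step` (default three times the trace noise, estimated as
#' `mad(diff(values)) / sqrt(2)`), counts the remaining downward steps, and
#' maps the count to a class: 1 step is `"single"`, 2 is `"double"`, and
#' anything else (including ambiguous or never-bleaching traces) is
#' `"multi"`. A trace with no accepted downward step whose level never
#' decays is flagged as never bleaching.
#'
#' @param trace A [bleach_trace()] (or numeric vector) of at least 20
#'   frames.
#' @param min_step Minimum accepted step height (ADU); default
#'   `3 x` the noise MAD.
#' @param max_steps Cap on inserted change points (default 12).
#' @return A character class, with attributes `n_steps`, `levels`,
#'   `breaks`, and `never_bleached`.
#' @export
classify_steps <- function(trace, min_step = NULL, max_steps = 12L) {
  y <- if (inherits(trace, "bleach_trace")) trace$values else as.numeric(trace)
  if (length(y) < 20) stop("trace must contain at least 20 frames")
  noise <- stats::mad(diff(y)) / sqrt(2)
  if (is.null(min_step)) min_step <- 3 * max(noise, 1e-12)
  fit <- greedy_steps(y, max_steps = max_steps)
  dlev <- diff(fit$levels)
  down <- sum(dlev <= -min_step)
  up <- sum(dlev >= min_step)
  never <- length(fit$levels) > 0 &&
    fit$levels[length(fit$levels)] > max(3 * noise, 0.5 * fit$levels[1]) &&
    down == 0
  cls <- if (never) "multi"
         else if (up > 0) "multi"            # non-monotone: ambiguous
         else if (down == 1) "single"
         else if (down == 2) "double"
         else "multi"
  structure(cls, n_steps = down, levels = fit$levels, breaks = fit$breaks,
            never_bleached = never)
}
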