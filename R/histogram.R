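#' Intensity histogram of detected spots
#'
#' @param bin_edges Strictly increasing bin edges (ADU).
#' @param counts Non-negative integer counts, one fewer than edges.
#' @return An object of class `intensity_histogram`.
#' @export
intensity_histogram <- function(bin_edges, counts) {
  if (any(diff(bin_edges) <= 0)) stop("'bin_edges' must be strictly increasing")
  if (length(counts) != length(bin_edges) - 1L)
    stop("length(counts) must equal length(bin_edges) - 1")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(bin_edges = as.numeric(bin_edges),
                 counts = as.numeric(counts)),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf(
    "intensity histogram: %d bins on [%.4g, %.4g] ADU, %d spots\n",
    length(x$counts), x$bin_edges[1], max(x$bin_edges), sum(x$counts)))
  invisible(x)
}

hist_centers <- function(hist) {
  (hist$bin_edges[-1] + hist$bin_edges[-length(hist$bin_edges)]) / 2
}

hist_widths <- function(hist) diff(hist$bin_edges)

# Observed probability density per bin (1/ADU).
hist_density <- function(hist) {
  n <- sum(hist$counts)
  if (n == 0) stop("histogram is empty")
  hist$counts / (n * hist_widths(hist))
}

#' Histogram a vector of spot intensities
#'
#' Builds a uniform-width intensity histogram. If `bin_width` is `NULL`, a
#' data-driven default is used: the first mode of a kernel density estimate
#' of the intensities (typically the monomer mode) divided by 25.
#'
#' @param x Spot intensities (ADU); non-positive values are dropped.
#' @param bin_width Bin width (ADU) or `NULL` for the default.
#' @return An [intensity_histogram()].
#' @export
build_histogram <- function(x, bin_width = NULL) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) < 10) stop("need at least 10 positive intensities")
  if (is.null(bin_width)) {
    d <- stats::density(x, n = 1024, from = 0, to = max(x))
    i <- which(diff(sign(diff(d$y))) < 0)[1] + 1L
    first_mode <- if (is.na(i)) d$x[which.max(d$y)] else d$x[i]
    bin_width <- max(first_mode / 25, diff(range(x)) / 2000)
  }
  edges <- seq(0, max(x) + bin_width, by = bin_width)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  intensity_histogram(edges, counts)
}

# Smoothed observed density: running mean over `k` bins (default scales
# with histogram resolution so broad peaks smooth out noise micro-modes).
smooth_density <- function(hist, k = NULL) {
  y <- hist_density(hist)
  if (is.null(k)) k <- max(7L, 2L * (length(y) %/% 40L) + 1L)
  s <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
  s[is.na(s)] <- y[is.na(s)]
  s
}

#' Split intensity axis into the low (monomer/dimer) region and the rest
#'
#' Separates the low-intensity (monomer/dimer) population from the
#' high-intensity (intact holoenzyme and larger) population by maximizing
#' the between-class variance of the log-intensities (Otsu's criterion on
#' the binned log-intensity distribution). This is robust to the noise
#' micro-modes that defeat naive valley detection on the smoothed density.
#'
#' @param hist An [intensity_histogram()].
#' @return The split intensity (ADU).
#' @export
split_low_region <- function(hist) {
  x <- hist_centers(hist)
  keep <- x > 0 & hist$counts >= 0
  l <- log(x[keep])
  cnt <- hist$counts[keep]
  n <- sum(cnt)
  if (n == 0) stop("histogram is empty")
  w1 <- cumsum(cnt)
  m1 <- cumsum(cnt * l)
  tot <- m1[length(m1)]
  w2 <- n - w1
  valid <- w1 > 0 & w2 > 0
  between <- rep(-Inf, length(l))
  between[valid] <- (m1[valid] - tot * w1[valid] / n)^2 /
    (w1[valid] * w2[valid])
  k <- which.max(between)
  exp((l[k] + l[min(k + 1, length(l))]) / 2)
}

# Dominant mode of the smoothed density above intensity `above` (ADU),
# refined by the vertex of a local quadratic fit around the argmax (the
# raw argmax bin is noisy even after smoothing). Distinguishes "no
# high-intensity population" (error) from quiet data.
find_high_peak <- function(hist, above) {
  s <- smooth_density(hist)
  x <- hist_centers(hist)
  sel <- which(x > above)
  if (!length(sel) || max(s[sel]) < 0.02 * max(s))
    stop("no resolvable high-intensity peak above the monomer/dimer region: ",
         "no dodecamer population detected")
  pk <- sel[which.max(s[sel])]
  # a genuine high-intensity population sits well above the split; a mode
  # hugging the split is just the shoulder of the low peak
  if (x[pk] < 1.5 * above)
    stop("no resolvable high-intensity peak above the monomer/dimer region: ",
         "no dodecamer population detected")
  win <- max(min(sel), pk - 10L):min(length(x), pk + 10L)
  if (length(win) >= 5) {
    q <- stats::lm.fit(cbind(1, x[win], x[win]^2), s[win])$coefficients
    if (is.finite(q[3]) && q[3] < 0) {
      vertex <- -q[2] / (2 * q[3])
      if (vertex > min(x[win]) && vertex < max(x[win])) return(vertex)
    }
  }
  x[pk]
}

#' Read / write spot tables
#'
#' Spot tables are CSV files with columns `spot_id, frame, x_px, y_px,
#' area_px2, raw_intensity, background_median, corrected_intensity`.
#'
#' @param path File path.
#' @return `read_spot_table` returns a `data.frame`.
#' @export
read_spot_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("spot_id", "corrected_intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("spot table lacks required columns: ", paste(miss, collapse = ", "))
  df
}

#' @param table A spot-table `data.frame`.
#' @rdname read_spot_table
#' @export
write_spot_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
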