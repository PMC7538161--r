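# Shared fixtures and small oracles used across the suite.

paper_model <- function() monomer_model(mu = log(500), sigma = 0.35, nu = 0.3)

# mixture used for clean three-component recovery checks (no intermediates)
three_comp_mixture <- function(n_spots = 20000, seed = 1) {
  mixture_spec(data.frame(n_subunits = c(1L, 2L, 12L),
                          fraction = c(0.3, 0.1, 0.6)),
               paper_model(), n_spots = n_spots, seed = seed)
}

# detected-spot component fractions implied by a mixture spec (closed form:
# each component's fraction times its detection probability 1 - nu^n)
detected_weights <- function(spec) {
  p_det <- 1 - spec$model$nu^spec$components$n_subunits
  w <- spec$components$fraction * p_det
  w / sum(w)
}

# greedy nearest matching of detections to ground-truth positions; returns
# recall and false-positive rate at a 1 px acceptance radius
match_detections <- function(spots, truth, radius = 1) {
  if (nrow(spots) == 0)
    return(c(recall = 0, fp_rate = 0))
  found <- 0; fp <- 0
  for (f in unique(spots$frame)) {
    s <- spots[spots$frame == f, ]
    tt <- truth[truth$frame == f, ]
    if (nrow(tt) == 0) { fp <- fp + nrow(s); next }
    d2 <- outer(s$x_px, tt$x_px, "-")^2 + outer(s$y_px, tt$y_px, "-")^2
    fp <- fp + sum(apply(d2, 1, min) > radius^2)
    found <- found + sum(apply(d2, 2, min) <= radius^2)
  }
  c(recall = found / nrow(truth), fp_rate = fp / nrow(spots))
}

# truth positions restricted to the central ROI, frame by frame
truth_in_roi <- function(sim) {
  shape <- dim(sim$sample$frames)[1:2]
  do.call(rbind, lapply(split(sim$truth, sim$truth$frame),
                        function(tf) roi_filter(tf, shape)))
}
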