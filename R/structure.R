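#' Multi-chain C-alpha coordinate set of an oligomeric hub ring
#'
#' Holds per-chain, per-residue C-alpha coordinates of a ring-shaped hub
#' assembly (two stacked hexameric rings in the dodecameric case), plus the
#' residue interval of the N-terminal alpha-A helix used for inter-subunit
#' angle measurements.
#'
#' @param coords Named list of per-chain numeric matrices (`n_res x 3`),
#'   with residue numbers as rownames.
#' @param helix_range Inclusive residue interval of the alpha-A helix
#'   (default `c(341, 363)`, author numbering).
#' @param min_helix_ca Minimum resolved helix C-alphas tolerated per chain
#'   (default 10).
#' @return An object of class `hub_ring`.
#' @export
hub_ring <- function(coords, helix_range = c(341, 363), min_helix_ca = 10L) {
  stopifnot(is.list(coords), length(coords) >= 1, !is.null(names(coords)))
  for (ch in names(coords)) {
    m <- coords[[ch]]
    if (!is.matrix(m) || ncol(m) != 3 || is.null(rownames(m)))
      stop("chain ", ch, ": coordinates must be an n x 3 matrix with residue rownames")
  }
  cover <- vapply(coords, function(m) {
    res <- as.integer(rownames(m))
    sum(res >= helix_range[1] & res <= helix_range[2])
  }, integer(1))
  bad <- names(cover)[cover < min_helix_ca]
  if (length(bad))
    stop("helix residues ", helix_range[1], "-", helix_range[2],
         " insufficiently resolved (< ", min_helix_ca, " C-alpha) in chain(s): ",
         paste(bad, collapse = ", "))
  structure(list(chains = names(coords), coords = coords,
                 helix_range = helix_range),
            class = "hub_ring")
}

#' @export
print.hub_ring <- function(x, ...) {
  cat(sprintf("hub ring: %d chains (%s), helix range %d-%d\n",
              length(x$chains), paste(x$chains, collapse = ""),
              x$helix_range[1], x$helix_range[2]))
  invisible(x)
}

#' Load a hub ring from a PDB or mmCIF file
#'
#' Extracts C-alpha coordinates per chain. Multi-model PDB files (e.g. a
#' conformational series) yield a list of `hub_ring`s, one per model,
#' unless `model_index` selects one.
#'
#' @param path Structure file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"cif"`.
#' @param model_index Model to extract from a multi-model file, or `NULL`
#'   for all.
#' @param helix_range,min_helix_ca Passed to [hub_ring()].
#' @return A `hub_ring`, or a list of them for a multi-model file.
#' @export
load_structure <- function(path, format = c("auto", "pdb", "cif"),
                           model_index = NULL, helix_range = c(341, 363),
                           min_helix_ca = 10L) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  pdb <- if (format == "cif") bio3d::read.cif(path)
         else bio3d::read.pdb(path, multi = TRUE)
  ca <- bio3d::atom.select(pdb, elety = "CA")
  atoms <- pdb$atom[ca$atom, , drop = FALSE]
  xyz <- pdb$xyz[, ca$xyz, drop = FALSE]
  n_models <- nrow(xyz)
  build_one <- function(mi) {
    coords <- list()
    for (ch in unique(atoms$chain)) {
      sel <- which(atoms$chain == ch)
      m <- matrix(xyz[mi, as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))],
                  ncol = 3, byrow = TRUE)
      rownames(m) <- atoms$resno[sel]
      coords[[ch]] <- m
    }
    hub_ring(coords, helix_range = helix_range, min_helix_ca = min_helix_ca)
  }
  if (!is.null(model_index)) return(build_one(model_index))
  if (n_models == 1) build_one(1) else lapply(seq_len(n_models), build_one)
}

#' Write a hub ring to a PDB file
#'
#' Serializes the C-alpha coordinates (one CA atom per residue) so that
#' synthetic rings can round-trip through the standard format.
#'
#' @param ring A [hub_ring()].
#' @param path Output PDB path.
#' @export
write_hub_ring <- function(ring, path) {
  stopifnot(inherits(ring, "hub_ring"))
  xyz <- do.call(rbind, ring$coords)
  chain <- rep(ring$chains, vapply(ring$coords, nrow, integer(1)))
  resno <- unlist(lapply(ring$coords, function(m) as.integer(rownames(m))),
                  use.names = FALSE)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                   type = rep("ATOM", length(resno)),
                   resno = resno, resid = rep("ALA", length(resno)),
                   chain = chain, elety = rep("CA", length(resno)))
  invisible(path)
}

chain_centroid <- function(ring, ch) colMeans(ring$coords[[ch]])

#' Lateral adjacency of chains within each hexameric ring
#'
#' Assigns chains to the two stacked rings geometrically (by projection of
#' the chain centroids onto the assembly's symmetry axis, the direction of
#' least centroid variance) and orders each ring by azimuthal angle; chains
#' consecutive in that cyclic order are laterally adjacent.
#'
#' @param ring A [hub_ring()].
#' @return `data.frame` with columns `chain_a`, `chain_b`, `ring`.
#' @export
ring_adjacency <- function(ring) {
  stopifnot(inherits(ring, "hub_ring"))
  cent <- t(vapply(ring$chains, function(ch) chain_centroid(ring, ch),
                   numeric(3)))
  cc <- scale(cent, scale = FALSE)
  ev <- eigen(crossprod(cc), symmetric = TRUE)
  axis <- ev$vectors[, 3]                      # least centroid variance
  z <- as.numeric(cc %*% axis)
  grp <- z > stats::median(z)
  # in-plane basis for azimuthal ordering
  u <- ev$vectors[, 1]; v <- ev$vectors[, 2]
  res <- list()
  for (g in unique(grp)) {
    members <- ring$chains[grp == g]
    if (length(members) < 2) next
    ang <- vapply(members, function(ch) {
      p <- cc[match(ch, ring$chains), ]
      atan2(sum(p * v), sum(p * u))
    }, numeric(1))
    ord <- members[order(ang)]
    k <- length(ord)
    res[[length(res) + 1]] <- data.frame(
      chain_a = ord, chain_b = ord[c(2:k, 1)],
      ring = if (g) "upper" else "lower")
  }
  do.call(rbind, res)
}

#' Helix axis by principal component analysis
#'
#' Fits the dominant principal axis of a set of ordered C-alpha
#' coordinates and orients it from the N-terminal toward the C-terminal
#' half of the helix.
#'
#' @param coords Ordered `n x 3` C-alpha coordinates (N- to C-terminal),
#'   `n >= 10`.
#' @return A list of class `helix_axis` with unit `direction` and
#'   `centroid`.
#' @export
helix_axis <- function(coords) {
  stopifnot(is.matrix(coords), ncol(coords) == 3)
  n <- nrow(coords)
  if (n < 10) stop("need at least 10 C-alpha positions to fit a helix axis")
  centroid <- colMeans(coords)
  cc <- sweep(coords, 2, centroid)
  sv <- svd(cc)
  if (sv$d[2] / sv$d[1] > 0.95)
    stop("degenerate helix: no dominant principal axis")
  dir <- sv$v[, 1]
  half <- floor(n / 2)
  nc <- colMeans(coords[(n - half + 1):n, , drop = FALSE]) -
        colMeans(coords[1:half, , drop = FALSE])
  if (sum(dir * nc) < 0) dir <- -dir
  structure(list(direction = dir / sqrt(sum(dir^2)), centroid = centroid),
            class = "helix_axis")
}

helix_coords <- function(ring, ch) {
  m <- ring$coords[[ch]]
  res <- as.integer(rownames(m))
  sel <- res >= ring$helix_range[1] & res <= ring$helix_range[2]
  m[sel, , drop = FALSE][order(res[sel]), , drop = FALSE]
}

#' Angle between two oriented helix axes
#'
#' `acos` of the dot product of the (N-to-C oriented) unit axis vectors, in
#' degrees on `[0, 180]`. Axes are deliberately not folded onto `[0, 90]`:
#' with unoriented axes, widely different inter-subunit geometries would
#' collapse onto the same angle.
#'
#' @param a,b [helix_axis()] objects.
#' @return Angle in degrees.
#' @export
interhelix_angle <- function(a, b) {
  stopifnot(inherits(a, "helix_axis"), inherits(b, "helix_axis"))
  d <- sum(a$direction * b$direction)
  acos(max(-1, min(1, d))) * 180 / pi
}

#' Inter-subunit alpha-A helix angles of all adjacent chain pairs
#'
#' @param ring A [hub_ring()].
#' @param adjacency Optional adjacency table (default
#'   [ring_adjacency()]).
#' @return `data.frame` with `chain_a`, `chain_b`, `ring`, `angle_deg`.
#' @export
adjacent_angles <- function(ring, adjacency = NULL) {
  stopifnot(inherits(ring, "hub_ring"))
  if (is.null(adjacency)) adjacency <- ring_adjacency(ring)
  axes <- lapply(ring$chains, function(ch) helix_axis(helix_coords(ring, ch)))
  names(axes) <- ring$chains
  adjacency$angle_deg <- mapply(function(a, b)
    interhelix_angle(axes[[a]], axes[[b]]),
    adjacency$chain_a, adjacency$chain_b)
  adjacency
}

#' Inter-helix angle series over a conformational ensemble
#'
#' @param models List of [hub_ring()]s (e.g. trajectory frames).
#' @param pair Character vector `c(chain_a, chain_b)`.
#' @return Numeric vector of angles (degrees), one per model.
#' @export
angle_series <- function(models, pair) {
  vapply(models, function(r) {
    a <- helix_axis(helix_coords(r, pair[1]))
    b <- helix_axis(helix_coords(r, pair[2]))
    interhelix_angle(a, b)
  }, numeric(1))
}

#' Centered moving average with shrunken edge windows
#'
#' Window is specified in frames; at the series edges the window shrinks to
#' the available samples. For an even window the extra sample is taken on
#' the trailing side.
#'
#' @param series Numeric vector.
#' @param window Window length in frames (`>= 1`).
#' @return Smoothed vector of the same length.
#' @export
moving_average <- function(series, window) {
  stopifnot(window >= 1, window == round(window))
  n <- length(series)
  lead <- floor((window - 1) / 2)
  trail <- floor(window / 2)
  cs <- c(0, cumsum(series))
  lo <- pmax(seq_len(n) - lead, 1)
  hi <- pmin(seq_len(n) + trail, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Closed-form least-squares rotation (Kabsch, SVD-based) mapping the
# centered point set B onto A, with a proper rotation (det = +1) enforced.
kabsch_rotation <- function(A, B) {
  H <- crossprod(B, A)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

#' Per-residue displacement field after single-chain superposition
#'
#' Rigidly superposes `fixed_chain` of the `alt` conformation onto the same
#' chain of `ref` (closed-form SVD least squares, proper rotation), applies
#' that transform to `moving_chain` of `alt`, and returns the per-C-alpha
#' displacement vectors of the moving chain relative to `ref`. This
#' isolates the change in orientation of one subunit relative to its
#' neighbor, discarding global rigid-body motion.
#'
#' @param ref,alt [hub_ring()]s of the two conformations.
#' @param fixed_chain Chain aligned between the conformations.
#' @param moving_chain Chain whose displacement is measured.
#' @return A list with `vectors` (`n x 3` matrix, Angstrom, residue
#'   rownames), `rmsd_fixed` (sanity value: RMSD of the aligned fixed
#'   chain), and `residues`.
#' @export
aligned_displacement_field <- function(ref, alt, fixed_chain, moving_chain) {
  stopifnot(inherits(ref, "hub_ring"), inherits(alt, "hub_ring"))
  grab <- function(ring, ch) {
    if (!ch %in% ring$chains) stop("chain ", ch, " absent from structure")
    ring$coords[[ch]]
  }
  match_residues <- function(a, b, ch) {
    ra <- rownames(a); rb <- rownames(b)
    if (!setequal(ra, rb)) {
      um <- c(setdiff(ra, rb), setdiff(rb, ra))
      stop("residue mismatch in chain ", ch, ": unmatched residue(s) ",
           paste(um, collapse = ", "))
    }
    list(a = a[ra, , drop = FALSE], b = b[ra, , drop = FALSE])
  }
  fx <- match_residues(grab(ref, fixed_chain), grab(alt, fixed_chain),
                       fixed_chain)
  mv <- match_residues(grab(ref, moving_chain), grab(alt, moving_chain),
                       moving_chain)
  ca_ref <- colMeans(fx$a); ca_alt <- colMeans(fx$b)
  R <- kabsch_rotation(sweep(fx$a, 2, ca_ref), sweep(fx$b, 2, ca_alt))
  transform <- function(x)
    sweep(sweep(x, 2, ca_alt) %*% t(R), 2, ca_ref, "+")
  fixed_fit <- transform(fx$b)
  rmsd_fixed <- sqrt(mean(rowSums((fixed_fit - fx$a)^2)))
  vectors <- transform(mv$b) - mv$a
  rownames(vectors) <- rownames(mv$a)
  list(vectors = vectors, rmsd_fixed = rmsd_fixed,
       residues = as.integer(rownames(mv$a)))
}

#' Ideal alpha-helix C-alpha coordinates
#'
#' Canonical alpha-helical geometry along +z: 1.5 Angstrom rise and 100
#' degrees of twist per residue on a 2.3 Angstrom radius.
#'
#' @param n_res Number of residues (default 23, the alpha-A helix length).
#' @param rise,radius,twist_deg Helical parameters.
#' @param first_resno Residue number of the first C-alpha (default 341).
#' @return `n_res x 3` coordinate matrix with residue rownames.
#' @export
ideal_helix <- function(n_res = 23, rise = 1.5, radius = 2.3,
                        twist_deg = 100, first_resno = 341) {
  i <- seq_len(n_res) - 1
  th <- i * twist_deg * pi / 180
  m <- cbind(radius * cos(th), radius * sin(th), i * rise)
  rownames(m) <- first_resno + i
  m
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

rot_x <- function(deg) {
  th <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
}

#' Synthetic perfectly symmetric dodecameric ring
#'
#' Places twelve copies of one subunit (an ideal alpha-A helix, tilted by
#' `tilt_deg` from the assembly axis) by exact 60-degree rotations in two
#' stacked hexameric rings (the lower ring flipped and offset by 30
#' degrees), so every laterally adjacent pair is related by the same
#' rotation. The adjacent-axis angle then has the closed form
#' `acos(sin^2(tilt) cos(60) + cos^2(tilt))`; see
#' [designed_adjacent_angle()]. Chains are labelled A-L.
#'
#' @param tilt_deg Tilt of each helix axis from the ring axis (degrees).
#' @param ring_radius Distance of each subunit centroid from the assembly
#'   axis (Angstrom).
#' @param ring_offset Vertical half-separation of the two rings (Angstrom).
#' @param helix A subunit C-alpha matrix (default [ideal_helix()]).
#' @return A [hub_ring()].
#' @export
build_symmetric_ring <- function(tilt_deg = 30, ring_radius = 60,
                                 ring_offset = 15, helix = ideal_helix()) {
  sub0 <- helix %*% t(rot_x(tilt_deg))               # tilt away from z
  sub0 <- sweep(sub0, 2, colMeans(sub0))
  sub0 <- sweep(sub0, 2, c(ring_radius, 0, ring_offset), "+")
  coords <- list()
  flip <- rot_x(180)
  for (k in 0:5) {
    up <- sub0 %*% t(rot_z(60 * k))
    rownames(up) <- rownames(helix)
    coords[[LETTERS[k + 1]]] <- up
  }
  for (k in 0:5) {
    dn <- sub0 %*% t(flip) %*% t(rot_z(60 * k + 30))
    rownames(dn) <- rownames(helix)
    coords[[LETTERS[k + 7]]] <- dn
  }
  hub_ring(coords)
}

#' Closed-form adjacent-axis angle of the symmetric ring
#'
#' For a unit axis tilted `tilt_deg` from the ring axis, the angle between
#' the axis and its copy rotated by `step_deg` about the ring axis is
#' `acos(sin^2(tilt) cos(step) + cos^2(tilt))`.
#'
#' @param tilt_deg Axis tilt from the ring axis (degrees).
#' @param step_deg In-ring rotation between adjacent subunits (default 60).
#' @return Angle in degrees.
#' @export
designed_adjacent_angle <- function(tilt_deg, step_deg = 60) {
  st <- sin(tilt_deg * pi / 180)^2
  acos(st * cos(step_deg * pi / 180) + (1 - st)) * 180 / pi
}

#' Tilt that produces a target adjacent-axis angle
#'
#' Inverse of [designed_adjacent_angle()]: the tilt (degrees) for which
#' adjacent subunits of the symmetric ring show the requested inter-helix
#' angle.
#'
#' @param angle_deg Target adjacent-axis angle (degrees).
#' @param step_deg In-ring rotation between adjacent subunits (default 60).
#' @export
tilt_for_adjacent_angle <- function(angle_deg, step_deg = 60) {
  s2 <- (1 - cos(angle_deg * pi / 180)) / (1 - cos(step_deg * pi / 180))
  if (s2 > 1) stop("target angle unreachable at this ring step")
  asin(sqrt(s2)) * 180 / pi
}
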