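test_that("helix axis recovers an ideal helix and respects orientation", {
  h <- ideal_helix()
  ax <- helix_axis(h)
  expect_gt(ax$direction[3], 0.999)
  expect_equal(sqrt(sum(ax$direction^2)), 1, tolerance = 1e-9)
  # reversing residue order flips the N-to-C orientation
  ax_rev <- helix_axis(h[rev(seq_len(nrow(h))), ])
  expect_equal(ax_rev$direction, -ax$direction, tolerance = 1e-9)
  # points on a perfect circle have no dominant axis
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  circle <- cbind(cos(th), sin(th), 0)
  expect_error(helix_axis(circle), "degenerate")
  expect_error(helix_axis(h[1:5, ]), "at least 10")
})

test_that("interhelix angle is a symmetric oriented-axis angle", {
  a <- helix_axis(ideal_helix())
  expect_equal(interhelix_angle(a, a), 0, tolerance = 1e-9)
  rot <- ideal_helix() %*% t(oligostate:::rot_x(90))
  b <- helix_axis(rot)
  expect_equal(interhelix_angle(a, b), 90, tolerance = 0.1)
  expect_equal(interhelix_angle(b, a), interhelix_angle(a, b))
  # oriented convention: antiparallel axes read 180, not 0
  c_ax <- helix_axis(ideal_helix() %*% diag(c(1, -1, -1)))
  expect_gt(interhelix_angle(a, c_ax), 170)
})

test_that("a symmetric dodecameric ring has exactly equal adjacent angles", {
  ring <- build_symmetric_ring(tilt_deg = 30)
  expect_length(ring$chains, 12)
  adj <- adjacent_angles(ring)
  expect_identical(nrow(adj), 12L)
  expect_lt(diff(range(adj$angle_deg)), 1e-9)
  # measured angle matches the closed-form design within the PCA-axis
  # approximation of a finite discrete helix (axis off-ideal by ~0.4 deg,
  # rotating with each subunit)
  expect_lt(abs(adj$angle_deg[1] - designed_adjacent_angle(30)), 0.8)
  # invariance under a global rigid motion
  R <- oligostate:::rot_z(17) %*% oligostate:::rot_x(43)
  moved <- ring
  for (ch in moved$chains)
    moved$coords[[ch]] <- sweep(moved$coords[[ch]] %*% t(R), 2,
                                c(5, -3, 11), "+")
  adj2 <- adjacent_angles(moved)
  expect_equal(adj2$angle_deg, adj$angle_deg, tolerance = 1e-9)
})

test_that("ring adjacency splits the stacked hexamers geometrically", {
  ring <- build_symmetric_ring(tilt_deg = 40)
  adj <- ring_adjacency(ring)
  expect_identical(sort(unique(adj$ring)), c("lower", "upper"))
  expect_identical(as.integer(table(adj$ring)), c(6L, 6L))
  # each chain appears exactly twice (two lateral neighbors)
  expect_true(all(table(c(adj$chain_a, adj$chain_b)) == 2))
})

test_that("hub rings round-trip through PDB and validate coverage", {
  ring <- build_symmetric_ring(tilt_deg = 35)
  path <- file.path(tempdir(), "ring.pdb")
  write_hub_ring(ring, path)
  back <- load_structure(path)
  expect_identical(sort(back$chains), sort(ring$chains))
  expect_equal(back$coords[["A"]], ring$coords[["A"]], tolerance = 1e-3)
  # a chain missing most helix residues is refused with a gap listing
  broken <- ring$coords
  broken[["C"]] <- broken[["C"]][1:5, , drop = FALSE]
  expect_error(hub_ring(broken), "chain\\(s\\): C")
})

test_that("multi-model files yield a conformational series of angles", {
  base <- build_symmetric_ring(tilt_deg = 30)
  open1 <- build_symmetric_ring(tilt_deg = 33)
  path <- file.path(tempdir(), "models.pdb")
  con <- file(path, "w")
  for (i in 1:2) {
    writeLines(sprintf("MODEL     %4d", i), con)
    tmp <- tempfile(fileext = ".pdb")
    write_hub_ring(if (i == 1) base else open1, tmp)
    lines <- readLines(tmp)
    writeLines(grep("^ATOM", lines, value = TRUE), con)
    writeLines("ENDMDL", con)
  }
  close(con)
  models <- load_structure(path)
  expect_length(models, 2)
  adj <- ring_adjacency(models[[1]])
  pair <- c(adj$chain_a[1], adj$chain_b[1])
  series <- angle_series(models, pair)
  expect_length(series, 2)
  expect_lt(abs(series[1] - designed_adjacent_angle(30)), 0.8)
  expect_lt(abs(series[2] - designed_adjacent_angle(33)), 0.8)
  expect_gt(series[2], series[1])
})

test_that("moving average shrinks windows at the edges", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_identical(moving_average(x, 1), x)
  expect_equal(moving_average(rep(2.5, 10), 5), rep(2.5, 10))
  alt <- rep(c(1, -1), 6)
  sm <- moving_average(alt, 2)
  expect_true(all(abs(sm[-length(sm)]) < 1e-12))
  # interior of an odd window is the plain centered mean
  expect_equal(moving_average(x, 3)[4], mean(x[3:5]))
})

test_that("displacement fields isolate relative subunit motion", {
  ref <- build_symmetric_ring(tilt_deg = 30)
  # identical conformations: zero field, zero fixed-chain RMSD
  d0 <- aligned_displacement_field(ref, ref, "A", "B")
  expect_lt(max(abs(d0$vectors)), 1e-9)
  expect_lt(d0$rmsd_fixed, 1e-9)
  # a global rigid motion of the whole assembly is absorbed by alignment
  R <- oligostate:::rot_z(25) %*% oligostate:::rot_x(10)
  moved <- ref
  for (ch in moved$chains)
    moved$coords[[ch]] <- sweep(moved$coords[[ch]] %*% t(R), 2, c(1, 2, 3), "+")
  dg <- aligned_displacement_field(ref, moved, "A", "B")
  expect_lt(max(abs(dg$vectors)), 1e-9)
  # translating only the moving chain appears verbatim in the field
  shifted <- ref
  shifted$coords[["B"]] <- sweep(shifted$coords[["B"]], 2, c(2, 0, 0), "+")
  ds <- aligned_displacement_field(ref, shifted, "A", "B")
  expect_equal(unname(colMeans(ds$vectors)), c(2, 0, 0), tolerance = 1e-9)
  expect_lt(max(abs(sweep(ds$vectors, 2, c(2, 0, 0)))), 1e-9)
  # residue mismatch is reported with the offending residues
  gappy <- ref
  gappy$coords[["B"]] <- gappy$coords[["B"]][-3, , drop = FALSE]
  expect_error(aligned_displacement_field(ref, gappy, "A", "B"),
               "unmatched residue")
})

test_that("superposition matches an independent reference implementation", {
  set.seed(37)
  A <- matrix(rnorm(45), ncol = 3)
  R <- oligostate:::rot_z(33) %*% oligostate:::rot_x(21)
  B <- sweep(A %*% t(R), 2, c(4, -2, 7), "+")
  fit <- oligostate:::kabsch_rotation(scale(A, scale = FALSE),
                                      scale(B, scale = FALSE))
  expect_equal(det(fit), 1, tolerance = 1e-9)
  # bio3d's least-squares fit as the independent oracle
  xyz_a <- as.numeric(t(A)); xyz_b <- as.numeric(t(B))
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = xyz_a, mobile = xyz_b))
  ours <- sweep(scale(B, scale = FALSE) %*% t(fit), 2,
                colMeans(A), "+")
  expect_equal(as.numeric(t(ours)), as.numeric(fitted), tolerance = 1e-6)
})
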