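test_that("symmetry-corrected RMSD absorbs equivalent relabelings", {
  sym <- make_symmetric_ligand()
  ref <- heavy_coords(sym)
  expect_equal(symmetry_corrected_rmsd(ref, sym), 0)
  # ring relabeled by the 180-degree graph automorphism, geometry unchanged
  perm <- c(4, 5, 6, 1, 2, 3, 8, 7)
  relabeled <- ref[order(perm), ]
  expect_gt(sqrt(mean(rowSums((relabeled - ref)^2))), 1)  # naive sees error
  expect_equal(symmetry_corrected_rmsd(relabeled, sym), 0)
})

test_that("symmetry-corrected RMSD equals the brute-force permutation minimum", {
  for (seed in 1:12) {
    lig <- random_tree_ligand(n = sample(5:8, 1), seed = seed)
    set.seed(seed + 500)
    pose <- heavy_coords(lig) + matrix(rnorm(3 * nrow(lig$atoms), sd = 0.5),
                                       ncol = 3)
    expect_equal(symmetry_corrected_rmsd(pose, lig),
                 oracle_sym_rmsd(pose, lig), tolerance = 1e-10)
  }
})

test_that("symmetry correction never exceeds the identity-mapping RMSD", {
  for (seed in 1:8) {
    sym <- make_symmetric_ligand()
    set.seed(seed)
    pose <- heavy_coords(sym) + matrix(rnorm(24, sd = 1), ncol = 3)
    naive <- sqrt(mean(rowSums((pose - heavy_coords(sym))^2)))
    expect_lte(symmetry_corrected_rmsd(pose, sym), naive + 1e-12)
  }
})

test_that("RMSD guards: shape mismatch errors, automorphism cap warns", {
  sym <- make_symmetric_ligand()
  expect_error(symmetry_corrected_rmsd(heavy_coords(sym)[1:3, ], sym))
  expect_warning(r <- symmetry_corrected_rmsd(heavy_coords(sym), sym, cap = 2),
                 "cap")
  expect_equal(r, 0)
})

test_that("centroid distance is the distance of heavy-atom means", {
  lig <- random_tree_ligand(7, seed = 3)
  ref <- heavy_coords(lig)
  expect_equal(centroid_distance(ref, lig), 0)
  expect_equal(centroid_distance(sweep(ref, 2, c(3, 4, 0), "+"), lig), 5)
  set.seed(4)
  pose <- ref + matrix(rnorm(21), ncol = 3)
  expect_equal(centroid_distance(pose, lig),
               sqrt(sum((colMeans(pose) - colMeans(ref))^2)))
})

test_that("both metrics are invariant under simultaneous rigid motion", {
  lig <- random_tree_ligand(7, seed = 5)
  ref <- heavy_coords(lig)
  set.seed(6)
  pose <- ref + matrix(rnorm(21, sd = 0.4), ncol = 3)
  R <- rotation_z(1.1); t_vec <- c(4, -2, 7)
  move <- function(x) sweep(x %*% R, 2, t_vec, "+")
  lig_m <- lig
  xyz <- move(as.matrix(lig$atoms[, c("x", "y", "z")]))
  lig_m$atoms$x <- xyz[, 1]; lig_m$atoms$y <- xyz[, 2]; lig_m$atoms$z <- xyz[, 3]
  expect_equal(symmetry_corrected_rmsd(move(pose), lig_m),
               symmetry_corrected_rmsd(pose, lig), tolerance = 1e-9)
  expect_equal(centroid_distance(move(pose), lig_m),
               centroid_distance(pose, lig), tolerance = 1e-9)
})

test_that("pose-set evaluation separates top-1 from best-of-any", {
  lig <- random_tree_ligand(6, seed = 7)
  ref <- heavy_coords(lig)
  # pose 1 is worse than pose 2 by construction
  p1 <- sweep(ref, 2, c(3, 0, 0), "+")
  p2 <- sweep(ref, 2, c(1, 0, 0), "+")
  rec <- evaluate_pose_set(pose_set("c1", list(p1, p2), lig), "III")
  expect_equal(rec$rmsd_top1, 3)
  expect_equal(rec$rmsd_best, 1)
  expect_equal(rec$centroid_top1, 3)
  expect_equal(rec$centroid_best, 1)
  # single pose: top1 equals best
  rec1 <- evaluate_pose_set(pose_set("c2", list(p1), lig))
  expect_equal(rec1$rmsd_top1, rec1$rmsd_best)
  # 10-pose fixture: best equals the elementwise minima over poses
  ps <- make_pose_set(lig, n_poses = 10, noise_sigma = 0.6, seed = 8)
  rec10 <- evaluate_pose_set(ps, "IV")
  per_pose <- vapply(ps$poses, symmetry_corrected_rmsd, reference = lig,
                     numeric(1))
  expect_equal(rec10$rmsd_best, min(per_pose))
  expect_equal(rec10$rmsd_top1, per_pose[1])
  expect_lte(rec10$rmsd_best, rec10$rmsd_top1)
})

test_that("Wilson interval matches the score-interval oracle everywhere", {
  expect_equal(unname(wilson_interval(0, 10, 0.95)), c(0, 0.2775),
               tolerance = 1e-3)
  set.seed(9)
  for (i in 1:300) {
    n <- sample(1:500, 1)
    k <- sample(0:n, 1)
    got <- wilson_interval(k, n, 0.95)
    ref <- suppressWarnings(stats::prop.test(k, n, correct = FALSE)$conf.int)
    expect_equal(unname(got), as.numeric(ref), tolerance = 1e-9)
    # interval always contains the point estimate, inside [0, 1]
    expect_lte(got["low"], k / n + 1e-12)
    expect_gte(got["high"], k / n - 1e-12)
    expect_gte(got["low"], 0)
    expect_lte(got["high"], 1)
  }
  expect_equal(unname(wilson_interval(10, 10)["high"]), 1)
  # width shrinks with n at fixed fraction
  w <- function(k, n) diff(unname(wilson_interval(k, n)))
  expect_gt(w(5, 10), w(50, 100))
  expect_gt(w(50, 100), w(500, 1000))
})

test_that("success summaries count strict sub-threshold values", {
  s <- success_summary(c(1.0, 3.0), threshold = 2)
  expect_equal(s$fraction, 0.5)
  s2 <- success_summary(c(1.9, 2.0, 2.1), threshold = 2)
  expect_equal(s2$k_success, 1L)  # exactly 2 A is a failure
  rec <- data.frame(rmsd_top1 = c(1, 1, 5), rmsd_best = c(1, 1, 1))
  expect_equal(success_summary(rec, "rmsd_best")$fraction, 1)
  expect_error(success_summary(numeric(0)), "no evaluation")
  expect_error(success_summary(rec, "bogus"), "unknown metric")
})

test_that("success comparison agrees with the pooled-test oracle", {
  mk <- function(k, n) success_summary(c(rep(1, k), rep(9, n - k)))
  same <- compare_success(mk(5, 10), mk(5, 10))
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  cmp <- compare_success(mk(50, 100), mk(10, 100))
  ref <- stats::prop.test(c(50, 10), c(100, 100), correct = FALSE)$p.value
  expect_equal(cmp$p_value, ref, tolerance = 1e-6)
  expect_true(cmp$significant)
  near <- compare_success(mk(5, 10), mk(6, 10))
  expect_false(near$significant)
  expect_equal(near$p_value, 2 * pnorm(-abs(near$z)))
  expect_gt(near$p_value, 0.6)
  # Fisher alternative
  f <- compare_success(mk(50, 100), mk(10, 100), method = "fisher")
  expect_true(f$significant)
  expect_error(compare_success(mk(5, 10),
                               success_summary(c(1, 9), threshold = 3)),
               "thresholds")
})

test_that("Kabsch superposition recovers rigid motions without reflections", {
  set.seed(10)
  P <- matrix(rnorm(45), ncol = 3)
  R <- rotation_z(0.8)
  Q <- sweep(P %*% R, 2, c(1, -2, 3), "+")
  fit <- kabsch_superpose(P, Q)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  expect_equal(t(fit$rotation) %*% fit$rotation, diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # mirrored target must still produce a proper rotation
  Qm <- Q %*% diag(c(-1, 1, 1))
  fitm <- kabsch_superpose(P, Qm)
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-8)
})

test_that("alignment + superposition recovers transforms and skips insertions", {
  ref <- receptor_from_seq("GAVLKDEFWY")
  al0 <- align_and_superimpose(ref, ref)
  expect_lt(al0$ca_rmsd, 1e-10)
  expect_equal(nrow(al0$mapping), 10)
  # rotated + translated copy
  moved <- ref
  xyz <- as.matrix(ref$atoms[, c("x", "y", "z")])
  xyz2 <- sweep(xyz %*% rotation_z(0.6), 2, c(5, 6, -7), "+")
  moved$atoms$x <- xyz2[, 1]; moved$atoms$y <- xyz2[, 2]; moved$atoms$z <- xyz2[, 3]
  al <- align_and_superimpose(moved, ref)
  expect_lt(al$ca_rmsd, 1e-6)
  # the recovered transform maps a ligand into the reference frame
  lig <- ligand_instance("L", data.frame(name = "C1", element = "C",
                                         charge = 0, x = 10, y = 2, z = 1))
  lig_moved <- lig
  p <- sweep(matrix(c(10, 2, 1), 1) %*% rotation_z(0.6), 2, c(5, 6, -7), "+")
  lig_moved$atoms$x <- p[1]; lig_moved$atoms$y <- p[2]; lig_moved$atoms$z <- p[3]
  back <- apply_transform(lig_moved, al)
  expect_equal(as.numeric(back$atoms[1, c("x", "y", "z")]), c(10, 2, 1),
               tolerance = 1e-6)
  # 3-residue insertion in the predicted sequence: mapping skips it
  pred <- receptor_from_seq("GAVPQWLKDEFWY")  # PQW inserted after GAV
  keep <- c(1:3, 7:13)
  coords <- matrix(0, 13, 3)
  coords[keep, ] <- cbind(3.8 * 1:10, sin(1:10), cos(1:10))
  coords[4:6, ] <- cbind(100 + 1:3, 0, 0)
  pred2 <- receptor_from_seq("GAVPQWLKDEFWY", coords = coords)
  al2 <- align_and_superimpose(pred2, ref)
  expect_equal(al2$mapping$predicted_resno, keep)
  expect_equal(al2$mapping$reference_resno, 1:10)
  expect_lt(al2$ca_rmsd, 1e-6)
  expect_error(align_and_superimpose(
    receptor_from_seq("GA"), receptor_from_seq("GA")), "3")
})
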