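test_that("Kabsch superposition is exact on rigid copies and matches a brute-force oracle", {
  set.seed(3)
  ref <- matrix(rnorm(18, sd = 3), 6, 3)
  expect_lt(kabsch_superpose(ref, ref)$rmsd, 1e-10)
  expect_all_close(kabsch_superpose(ref, ref)$rotation, diag(3), 1e-8)
  expect_lt(kabsch_superpose(sweep(ref, 2, c(5, 0, 0), "+"), ref)$rmsd, 1e-10)

  # rotated + noisy copy: minimum RMSD must match a rotation-grid search
  for (seed in 1:3) {
    set.seed(seed)
    r <- random_rotation()
    mob <- ref %*% t(r) + matrix(rnorm(18, sd = 0.3), 6, 3)
    ours <- kabsch_superpose(mob, ref)$rmsd
    expect_lt(abs(ours - oracle_min_rmsd(mob, ref)), 1e-3)
    # proper rotation always
    expect_equal(det(kabsch_superpose(mob, ref)$rotation), 1, tolerance = 1e-9)
  }

  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), ">= 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("RMSD series vanishes for rigid motion and matches the two-step oracle", {
  s <- md_structure(make_atoms(8, seed = 5))
  base <- coords(s)
  nf <- 6
  arr <- array(NA_real_, dim = c(nf, 8, 3))
  arr[1, , ] <- base
  for (f in 2:nf) {
    r <- random_rotation()
    arr[f, , ] <- sweep(base %*% t(r), 2, rnorm(3, sd = 4), "+")
  }
  traj <- md_trajectory(s, arr)
  expect_all_close(rmsd_series(traj), rep(0, nf), 1e-8)
  expect_identical(rmsd_series(traj, ref_frame = 3)[3], 0)

  # non-rigid frames: value equals rms residual after oracle superposition
  set.seed(9)
  arr[4, , ] <- arr[4, , ] + matrix(rnorm(24, sd = 0.5), 8, 3)
  traj2 <- md_trajectory(s, arr)
  v <- rmsd_series(traj2)[4]
  mob <- arr[4, , ]
  expect_lt(abs(v - oracle_min_rmsd(mob, base)), 2e-3)
})

test_that("RMSF is zero for static trajectories and matches closed forms", {
  s <- md_structure(make_atoms(5))
  base <- coords(s)
  arr <- array(rep(base, each = 10), dim = c(10, 5, 3))
  traj <- md_trajectory(s, arr)
  expect_all_close(rmsf_per_residue(traj)$rmsf, rep(0, 5), 1e-10)

  # one atom oscillating +/- a along x, superposition disabled
  a <- 0.7
  arr2 <- arr
  arr2[, 3, 1] <- base[3, 1] + a * rep(c(1, -1), 5)
  traj2 <- md_trajectory(s, arr2)
  r <- rmsf_per_residue(traj2, superpose = FALSE)$rmsf
  expect_equal(r[3], a, tolerance = 1e-12)
  expect_all_close(r[-3], rep(0, 4), 1e-12)

  # agreement with the direct two-pass formula on a random fixture
  set.seed(21)
  arr3 <- array(rnorm(20 * 5 * 3, sd = 1), dim = c(20, 5, 3)) +
    array(rep(base, each = 20), dim = c(20, 5, 3))
  traj3 <- md_trajectory(s, arr3)
  got <- rmsf_per_residue(traj3, superpose = FALSE)$rmsf
  want <- sapply(1:5, function(i) {
    d <- arr3[, i, ]
    sqrt(mean(rowSums(sweep(d, 2, colMeans(d))^2)))
  })
  expect_all_close(got, want, 1e-10)

  expect_error(rmsf_per_residue(md_trajectory(s, base)), ">= 2 frames")
})

test_that("radius of gyration and centroid obey their closed forms", {
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two, c(1, 1)), 1.0, tolerance = 1e-12)
  expect_equal(radius_of_gyration(matrix(c(3, 4, 5), 1)), 0)
  expect_equal(centroid(two), c(1, 0, 0))
  expect_equal(centroid(matrix(c(1, 2, 3), 1)), c(1, 2, 3))

  set.seed(12)
  xyz <- matrix(rnorm(150), 50, 3)
  m <- runif(50, 1, 16)
  cm <- colSums(xyz * m) / sum(m)
  direct <- sqrt(sum(m * rowSums(sweep(xyz, 2, cm)^2)) / sum(m))
  expect_lt(abs(radius_of_gyration(xyz, m) - direct), 1e-10)
  # mass-weighted centroid equals the center of mass
  expect_all_close(centroid(xyz, m), cm, 1e-12)
  # linear scaling r -> lambda r
  expect_equal(radius_of_gyration(xyz * 2.5, m),
               2.5 * radius_of_gyration(xyz, m), tolerance = 1e-10)
})

test_that("strand axes are oriented N->C and antisymmetric under reversal", {
  pts <- cbind(0, 0, seq(0, 13.2, by = 3.3))
  ax <- strand_axis(pts)
  expect_all_close(ax$direction, c(0, 0, 1), 1e-9)
  expect_all_close(strand_axis(pts[nrow(pts):1, ])$direction, c(0, 0, -1), 1e-9)

  # jittered builder strand: axis within 5 degrees of the rise direction
  set.seed(2)
  u <- c(1, 2, 2) / 3
  st <- build_strand(8, direction = u)
  noisy <- coords(st) + matrix(rnorm(24, sd = 0.3), 8, 3)
  ang <- acos(sum(strand_axis(noisy)$direction * u)) * 180 / pi
  expect_lt(ang, 5)

  expect_error(strand_axis(matrix(1, 4, 3)), "degenerate")
})

test_that("pocket descriptors H, alpha, theta reproduce constructed geometry", {
  # two 4-residue loops with centroids 16.1 A apart
  la <- make_atoms(4, "A", seed = 7); lb <- make_atoms(4, "A", seed = 8)
  lb$res_seq <- 5:8
  shift <- 16.1 - (mean(lb$x) - mean(la$x))
  lb$x <- lb$x + shift
  lb$y <- lb$y - (mean(lb$y) - mean(la$y))
  lb$z <- lb$z - (mean(lb$z) - mean(la$z))
  s <- md_structure(rbind(la, lb))
  traj <- md_trajectory(s, coords(s))
  expect_equal(metric_H(traj, 1:4, 5:8), 16.1, tolerance = 1e-9)
  expect_equal(metric_H(traj, 1:4, 1:4), 0)

  # alpha: strand along z, reference vector orthogonal / parallel
  base_cols <- c("name", "element", "res_name", "res_seq", "chain_id", "x", "y", "z")
  st <- rbind(build_strand(5, chain_id = "A")$atoms[, base_cols],
              data.frame(name = c("P1", "P2", "P3"), element = "C",
                         res_name = "GLY", res_seq = 6:8, chain_id = "A",
                         x = c(0, 4, 0), y = c(0, 0, 0), z = c(20, 20, 24),
                         stringsAsFactors = FALSE))
  s2 <- md_structure(st)
  t2 <- md_trajectory(s2, coords(s2))
  expect_equal(metric_alpha(t2, 1:5, 6, 7), 90, tolerance = 1e-9)
  expect_equal(metric_alpha(t2, 1:5, 6, 8), 0, tolerance = 1e-9)
  expect_error(metric_alpha(t2, 1:5, 6, 6), "coincide")

  # theta on constructed strands: 0 / 90 / 180
  mk2 <- function(dir2) {
    s1 <- build_strand(5, chain_id = "A")
    s2b <- build_strand(5, direction = dir2, origin = c(8, 0, 0),
                        chain_id = "B")
    st <- md_structure(rbind(s1$atoms, s2b$atoms))
    md_trajectory(st, coords(st))
  }
  expect_equal(metric_theta(mk2(c(0, 0, 1)), 1:5, 6:10), 0, tolerance = 1e-6)
  expect_equal(metric_theta(mk2(c(1, 0, 0)), 1:5, 6:10), 90, tolerance = 1e-6)
  expect_equal(metric_theta(mk2(c(0, 0, -1)), 1:5, 6:10), 180, tolerance = 1e-6)
  expect_equal(metric_theta(mk2(c(0, 0, -1)), 1:5, 6:10, oriented = FALSE), 0,
               tolerance = 1e-6)
})

test_that("geometry metrics are invariant under global rigid motion", {
  spec <- interface_spec()
  cx <- build_complex(spec)
  s <- cx
  base <- coords(s)
  ca_like <- 1:10
  set.seed(33)
  for (k in 1:25) {
    r <- random_rotation()
    t <- rnorm(3, sd = 20)
    moved <- sweep(base %*% t(r), 2, t, "+")
    s2 <- s
    s2$atoms$x <- moved[, 1]; s2$atoms$y <- moved[, 2]; s2$atoms$z <- moved[, 3]
    tr1 <- md_trajectory(s, base); tr2 <- md_trajectory(s2, moved)
    expect_equal(metric_H(tr2, 1:4, 7:10), metric_H(tr1, 1:4, 7:10),
                 tolerance = 1e-8)
    expect_equal(radius_of_gyration(moved, s$atoms$mass),
                 radius_of_gyration(base, s$atoms$mass), tolerance = 1e-8)
    expect_equal(metric_theta(tr2, 1:5, 6:10), metric_theta(tr1, 1:5, 6:10),
                 tolerance = 1e-6)
  }
})
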