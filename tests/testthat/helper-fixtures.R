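# Shared fixtures and independent oracles.  Oracles are deliberately written
# as plain double loops / dense sampling so they never share code with the
# implementation they check.

make_atoms <- function(n, chain = "A", seed = 1, spread = 10) {
  set.seed(seed)
  data.frame(name = paste0("C", seq_len(n)), element = "C", res_name = "ALA",
             res_seq = seq_len(n), chain_id = chain,
             x = runif(n, 0, spread), y = runif(n, 0, spread),
             z = runif(n, 0, spread), stringsAsFactors = FALSE)
}

make_two_chain_structure <- function(seed = 1) {
  a <- make_atoms(6, "A", seed)
  b <- make_atoms(6, "B", seed + 1)
  b$x <- b$x + 12
  md_structure(rbind(a, b))
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotmat_euler <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)), 3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(c)
}

# brute-force rigid-fit oracle: coarse Euler grid then Nelder-Mead refinement
oracle_min_rmsd <- function(mobile, ref, grid_deg = 20) {
  pm <- sweep(mobile, 2, colMeans(mobile))
  pr <- sweep(ref, 2, colMeans(ref))
  obj <- function(ang) {
    r <- rotmat_euler(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((pm %*% t(r) - pr)^2)))
  }
  g <- seq(0, 2 * pi, by = grid_deg * pi / 180)
  gb <- seq(0, pi, by = grid_deg * pi / 180)
  best <- c(0, 0, 0); bv <- obj(best)
  for (a in g) for (b in gb) for (cc in g) {
    v <- obj(c(a, b, cc))
    if (v < bv) { bv <- v; best <- c(a, b, cc) }
  }
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# dense-sampling SASA oracle, independent spherical point generation (random
# uniform points on each expanded sphere)
oracle_sasa <- function(xyz, radii, probe = 1.4, n_pts = 2e5, seed = 99) {
  set.seed(seed)
  n <- nrow(xyz)
  total <- 0
  for (i in seq_len(n)) {
    ri <- radii[i] + probe
    u <- matrix(rnorm(n_pts * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    p <- sweep(u * ri, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_pts)
    for (j in seq_len(n)[-i]) {
      rj <- radii[j] + probe
      acc <- acc & (rowSums(sweep(p, 2, xyz[j, ])^2) > rj^2)
    }
    total <- total + 4 * pi * ri^2 * mean(acc)
  }
  total
}

# exhaustive O(N^2) H-bond oracle: double loop, recomputing the criterion
# from scratch for every donor/acceptor combination
oracle_hbonds <- function(xyz, donors, acceptors, d_cut = 3.5, ang_cut = 30) {
  hits <- list()
  for (k in seq_len(nrow(donors))) {
    d <- donors$donor[k]; h <- donors$hydrogen[k]
    for (a in acceptors) {
      if (a == d) next
      dist <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
      if (dist > d_cut) next
      v1 <- xyz[d, ] - xyz[h, ]
      v2 <- xyz[a, ] - xyz[h, ]
      ang <- acos(min(1, max(-1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (180 - ang <= ang_cut) {
        hits[[length(hits) + 1L]] <- c(d, h, a)
      }
    }
  }
  if (!length(hits)) return(matrix(integer(0), 0, 3))
  do.call(rbind, hits)
}

# random frame carrying N/O/H chemistry for detector property tests
random_hbond_frame <- function(n_heavy = 20, seed = 1) {
  set.seed(seed)
  heavy <- data.frame(
    name = paste0("X", seq_len(n_heavy)),
    element = sample(c("N", "O"), n_heavy, replace = TRUE),
    res_name = "ALA", res_seq = seq_len(n_heavy),
    chain_id = sample(c("A", "B"), n_heavy, replace = TRUE),
    x = runif(n_heavy, 0, 12), y = runif(n_heavy, 0, 12),
    z = runif(n_heavy, 0, 12), stringsAsFactors = FALSE)
  # attach a hydrogen to every second heavy atom
  don <- seq(1, n_heavy, by = 2)
  hyd <- heavy[don, ]
  hyd$name <- paste0("H", seq_along(don))
  hyd$element <- "H"
  u <- matrix(rnorm(length(don) * 3), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  hyd[, c("x", "y", "z")] <- hyd[, c("x", "y", "z")] + u
  md_structure(rbind(heavy, hyd))
}

# hand-written minimal PDB text (independent of write_pdb)
pdb_fixture_lines <- function() {
  c("ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00  0.00           C",
    "ATOM      3  O   ALA A   1       3.200   1.000   3.000  1.00  0.00           O",
    "TER",
    "END")
}

expect_all_close <- function(x, y, tol) {
  expect_true(max(abs(x - y)) < tol,
              label = sprintf("max|diff| = %.3g < %.3g", max(abs(x - y)), tol))
}
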