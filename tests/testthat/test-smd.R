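two_strand_complex <- function(n_res = 8, sep = 5) {
  a <- build_strand(n_res, chain_id = "A")$atoms
  b <- build_strand(n_res, chain_id = "B", origin = c(sep, 0, 0))$atoms
  md_structure(rbind(a, b))
}

# zero-rest-length tether: two coincident beads, one fixed; each Cartesian
# coordinate of the free bead is then an independent harmonic dof
tether_model <- function(k = 1) {
  s <- md_structure(data.frame(name = c("CA", "CA"), element = "C",
                               res_name = "ALA", res_seq = 1:2,
                               chain_id = "A", x = 0, y = 0, z = 0,
                               stringsAsFactors = FALSE))
  build_enm(s, selection = "all", cutoff = 1, k_intra = k)
}

test_that("elastic networks are built by pair enumeration within the cutoff", {
  s <- two_strand_complex()
  expect_warning(build_enm(s, selection = "all", cutoff = 2), "isolated")

  two <- md_structure(make_atoms(2))
  two$atoms[, c("x", "y", "z")] <- rbind(c(0, 0, 0), c(5, 0, 0))
  m <- build_enm(two, selection = "all", cutoff = 10)
  expect_equal(nrow(m$springs), 1L)
  expect_equal(m$springs$r0, 5)

  set.seed(77)
  cloud <- md_structure(make_atoms(30, spread = 15))
  m2 <- build_enm(cloud, selection = "all", cutoff = 8)
  want <- 0
  xyz <- coords(cloud)
  for (i in 1:29) for (j in (i + 1):30) {
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= 8) want <- want + 1
  }
  expect_equal(nrow(m2$springs), want)
  # symmetric, no self springs
  expect_true(all(m2$springs$i < m2$springs$j))
})

test_that("loading modes fix anchors and set the pulling direction at t = 0", {
  at <- make_atoms(3)
  at[, c("x", "y", "z")] <- rbind(c(0, 0, 0), c(0, 0, 10), c(1, 0, 0))
  at2 <- at; at2$x[3] <- -1
  s <- md_structure(rbind(at, within(at2, res_seq <- res_seq + 3L))[c(1, 2, 3, 6), ])
  # beads: 1 at origin, 2 at (0,0,10), 3 at (1,0,0), 4 at (-1,0,0)
  m <- build_enm(s, selection = "all", cutoff = 20)
  expect_equal(set_loading(m, 1, fixed = 1L, steered = 2L)$direction, c(0, 0, 1))
  # mode 2 midpoint rule: anchors at (+/-1, 0, 0) -> direction (0,0,1)
  sys2 <- set_loading(m, 2, fixed = c(3L, 4L), steered = 2L)
  expect_equal(sys2$direction, c(0, 0, 1))
  expect_equal(sys2$anchor, c(0, 0, 0))
  expect_error(set_loading(m, 1, fixed = 2L, steered = 2L), "cannot be fixed")
  expect_error(set_loading(m, 2, fixed = 3L, steered = 2L), "two fixed")

  # direction is computed once and never recomputed during a run
  prot <- smd_protocol(mode = 1, ramp_ns = 0.01, seed = 2)
  run <- run_ramp(set_loading(m, 1, fixed = 1L, steered = 2L), prot)
  expect_equal(set_loading(m, 1, fixed = 1L, steered = 2L)$direction, c(0, 0, 1))
  # fixed beads never move
  expect_all_close(run$trajectory$coords[, 1, ],
                   matrix(rep(c(0, 0, 0), each = n_frames(run$trajectory)),
                          ncol = 3), 1e-300)
})

test_that("rigid-anchor ramp force grows exactly as k_spring * v_pull * t", {
  m <- tether_model()
  sys <- set_loading(m, 1, fixed = 1L, steered = 2L, direction = c(0, 0, 1))
  prot <- smd_protocol(mode = 1, ramp_ns = 1, seed = 1)
  run <- run_ramp(sys, prot, rigid_steered = TRUE)
  tr <- as.data.frame(run$trace)
  # 34.74 pN/nm * 0.5 nm/ns = 17.37 pN/ns
  expect_all_close(tr$force_pN, 17.37 * tr$time_ns, 1e-9)
})

test_that("zero-temperature dynamics match a reference ODE integrator", {
  skip_if_not_installed("deSolve")
  s <- md_structure(data.frame(name = c("CA", "CA"), element = "C",
                               res_name = "ALA", res_seq = 1:2, chain_id = "A",
                               x = 0, y = 0, z = c(0, 5), stringsAsFactors = FALSE))
  m <- build_enm(s, selection = "all", cutoff = 10, k_intra = 1)
  sys <- set_loading(m, 1, fixed = 1L, steered = 2L)
  prot <- smd_protocol(mode = 1, temperature_K = 0, dt_ns = 5e-8,
                       ramp_ns = 0.05, sample_every = 1000L, seed = 1)
  run <- run_ramp(sys, prot)
  z <- run$trajectory$coords[, 2, 3]
  ks <- spring_pN_nm_to_kcal(34.74)
  ode <- deSolve::lsoda(
    y = c(z = 5), times = run$trajectory$times,
    func = function(t, y, p) {
      list((-1 * (y - 5) + ks * (5 + 5 * t - y)) / 0.05)
    }, rtol = 1e-12, atol = 1e-12)
  expect_all_close(z, ode[, "z"], 1e-6)
})

test_that("thermal fluctuations satisfy equipartition on a harmonic tether", {
  k <- 5
  m <- tether_model(k)
  prot <- smd_protocol(ramp_ns = 100, dt_ns = 1e-5, sample_every = 100L,
                       temperature_K = 300, seed = 123)
  run <- run_free(m, prot, fixed = 1L)
  xyz <- run$trajectory$coords[, 2, ]
  burn <- seq_len(floor(nrow(xyz) * 0.05))
  v <- apply(xyz[-burn, ], 2, var)
  expect_lt(abs(mean(v) - kBT_kcal(300) / k) / (kBT_kcal(300) / k), 0.05)
})

test_that("clamp phase applies the setpoint exactly and obeys Hooke's law", {
  k <- 1
  m <- tether_model(k)
  sys <- set_loading(m, 1, fixed = 1L, steered = 2L, direction = c(0, 0, 1))
  prot <- smd_protocol(clamp_ns = 50, sample_every = 100L, seed = 9)
  run <- run_clamp(sys, prot)
  tr <- as.data.frame(run$trace)
  expect_true(all(tr$phase == "clamp"))
  expect_all_close(tr$force_pN, rep(25, nrow(tr)), 1e-9)

  z <- run$trajectory$coords[, 2, 3]
  burn <- seq_len(floor(length(z) * 0.1))
  z <- z[-burn]
  expect_ext <- force_pN_to_kcal(25) / k
  tau <- prot$friction / k
  n_eff <- (prot$clamp_ns * 0.9) / (2 * tau)
  se <- sqrt(kBT_kcal(300) / k / n_eff)
  expect_lt(abs(mean(z) - expect_ext), 3 * se)
})

test_that("the ramp-clamp switch happens at the first 25 pN crossing", {
  s <- two_strand_complex()
  m <- build_enm(s, selection = "all", cutoff = 7, k_intra = 1,
                 k_interface = 0.3)
  sys <- set_loading(m, 1, fixed = 1L, steered = 16L)
  prot <- smd_protocol(mode = 1, ramp_ns = 4, clamp_ns = 0.5, seed = 5)
  run <- run_ramp_clamp(sys, prot)
  expect_true(run$complete)
  tr <- as.data.frame(run$trace)
  ramp <- tr[tr$phase == "ramp", ]
  clamp <- tr[tr$phase == "clamp", ]
  # no sampled ramp force may exceed the setpoint except the trigger sample
  expect_true(all(ramp$force_pN[-nrow(ramp)] < 25))
  expect_all_close(clamp$force_pN, rep(25, nrow(clamp)), 1e-9)
  expect_true(all(diff(tr$time_ns) > 0))
  expect_lte(run$trigger_time, max(ramp$time_ns) + prot$dt_ns * prot$sample_every)

  # protocol-incomplete runs are reported, not raised
  prot0 <- smd_protocol(mode = 1, ramp_ns = 0.05, seed = 5)
  short <- run_ramp_clamp(sys, prot0)
  expect_false(short$complete)
  expect_true(is.na(short$trigger_time))
})

test_that("traces are bitwise reproducible under a fixed seed", {
  s <- two_strand_complex()
  m <- build_enm(s, selection = "all", cutoff = 7)
  sys <- set_loading(m, 1, fixed = 1L, steered = 16L)
  prot <- smd_protocol(mode = 1, ramp_ns = 0.2, clamp_ns = 0.1, seed = 42)
  r1 <- run_ramp_clamp(sys, prot)
  r2 <- run_ramp_clamp(sys, prot)
  expect_identical(as.data.frame(r1$trace), as.data.frame(r2$trace))
  prot$seed <- 43L
  r3 <- run_ramp_clamp(sys, prot)
  expect_false(identical(as.data.frame(r1$trace), as.data.frame(r3$trace)))
})

test_that("stiffer interfaces rupture at higher force", {
  s <- two_strand_complex()
  mean_rupture <- function(k_if) {
    m <- build_enm(s, selection = "all", cutoff = 7, k_intra = 2,
                   k_interface = k_if)
    sys <- set_loading(m, 1, fixed = 1L, steered = 16L)
    f <- vapply(1:3, function(r) {
      prot <- smd_protocol(mode = 1, ramp_ns = 5, seed = 100 + r)
      rupture_force(run_ramp(sys, prot)$trace)$rupture_force
    }, numeric(1))
    mean(f)
  }
  expect_gt(mean_rupture(0.6), mean_rupture(0.15))
})

test_that("rupture extraction finds peaks through noise", {
  tr <- make_force_trace(500, shape = "triangle")
  expect_equal(rupture_force(tr, smooth_window_ns = 0)$rupture_force, 500,
               tolerance = 1e-6)

  # noisy peak: smoothed max within 3 sigma/sqrt(w) of truth
  trn <- make_force_trace(500, shape = "triangle", noise_sd = 5, seed = 3)
  w <- 0.1 / 0.001
  got <- rupture_force(trn, smooth_window_ns = 0.1)$rupture_force
  expect_lt(abs(got - 500), 3 * 5 / sqrt(w) + 500 * 0.002)

  # monotone ramp peaks at the end
  mono <- force_trace(seq(0, 1, by = 0.01), seq(0, 100, by = 1),
                      dummy_A = seq(0, 1, by = 0.01) * 5,
                      steered_A = seq(0, 1, by = 0.01) * 5)
  rf <- rupture_force(mono, smooth_window_ns = 0)
  expect_equal(rf$rupture_force, 100)
  expect_equal(rf$rupture_time, 1)

  flat <- force_trace(0:9, rep(7, 10), 0:9, 0:9)
  expect_warning(rf2 <- rupture_force(flat), "constant")
  expect_equal(rf2$rupture_force, 7)

  expect_error(rupture_force(force_trace(0:3, 1:4, 0:3, 0:3,
                                         phase = rep("clamp", 4))), "no ramp")

  # dt-instability guard
  m <- tether_model(5)
  sys <- set_loading(m, 1, fixed = 1L, steered = 2L, direction = c(0, 0, 1))
  expect_error(run_ramp(sys, smd_protocol(dt_ns = 0.01, seed = 1)), "dt too large")
})
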