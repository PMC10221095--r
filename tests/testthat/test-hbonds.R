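test_that("detection applies the distance and linearity cutoffs exactly", {
  # donor at origin, hydrogen on the D->A line, acceptor along z
  mk <- function(d_da, dev_deg) {
    h <- rampclamp:::.h_for_deviation(dev_deg, d_da = d_da)
    rbind(D = c(0, 0, 0), H = h, A = c(0, 0, d_da))
  }
  donors <- data.frame(donor = 1L, hydrogen = 2L)
  hit <- detect_hbonds(mk(3.4, 10), donors, acceptors = 3L)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$dist, 3.4, tolerance = 1e-9)
  expect_equal(hit$deviation, 10, tolerance = 1e-6)
  expect_equal(nrow(detect_hbonds(mk(3.6, 0.001), donors, acceptors = 3L)), 0L)
  expect_equal(nrow(detect_hbonds(mk(3.4, 31), donors, acceptors = 3L)), 0L)

  expect_error(detect_hbonds(mk(3, 5), data.frame(donor = 1L, hydrogen = NA),
                             3L, mode = "angle"), "hydrogens")
})

test_that("detector equals exhaustive enumeration on random frames", {
  for (seed in 1:100) {
    s <- random_hbond_frame(20, seed = seed)
    da <- find_donors_acceptors(s)
    xyz <- coords(s)
    got <- detect_hbonds(xyz, da$donors, da$acceptors)
    want <- oracle_hbonds(xyz, da$donors, da$acceptors)
    got_keys <- sort(paste(got$donor, got$hydrogen, got$acceptor))
    want_keys <- if (nrow(want)) sort(paste(want[, 1], want[, 2], want[, 3])) else character(0)
    expect_identical(got_keys, want_keys)
  }
})

test_that("interfacial filter keeps only cross-chain bonds in both directions", {
  s <- random_hbond_frame(20, seed = 5)
  da <- find_donors_acceptors(s)
  bonds <- detect_hbonds(coords(s), da$donors, da$acceptors, d_cut = 8)
  kept <- interfacial_filter(bonds, s, "A", "B")
  ch <- s$atoms$chain_id
  expect_true(all(ch[kept$donor] != ch[kept$acceptor]))
  # manual enumeration
  manual <- sum(ch[bonds$donor] != ch[bonds$acceptor])
  expect_equal(nrow(kept), manual)
  expect_error(interfacial_filter(bonds, s, "A", "A"), "disjoint")

  # constructed fixture: one bond in each direction, one intra-chain decoy
  hx <- rampclamp:::.h_for_deviation(5)
  at <- data.frame(
    name = c("O1", "N1", "H1", "O2", "N2", "H2", "O3", "N3", "H3"),
    element = rep(c("O", "N", "H"), 3),
    res_name = "GLY", res_seq = 1:9,
    chain_id = c("A", "B", "B",  "B", "A", "A",  "A", "A", "A"),
    x = c(0, 0, hx[1],  10, 10, 10 + hx[1],  20, 20, 20 + hx[1]),
    y = 0,
    z = rep(c(0, 2.9, 2.9 - hx[3]), 3),
    stringsAsFactors = FALSE)
  sf <- md_structure(at)
  daf <- find_donors_acceptors(sf)
  bf <- detect_hbonds(coords(sf), daf$donors, daf$acceptors)
  keptf <- interfacial_filter(bf, sf, "A", "B")
  chf <- sf$atoms$chain_id
  # A-donor/B-acceptor and B-donor/A-acceptor both kept, intra-chain dropped
  expect_setequal(paste(chf[keptf$donor], chf[keptf$acceptor]), c("B A", "A B"))
  expect_equal(nrow(keptf), 2L)
})

test_that("N_HB series counts persistent and stochastic interfaces correctly", {
  # five always-on bonds -> constant 5
  spec5 <- interface_spec(pairs = reference_interface_pairs()[1:5, ],
                          occupancies = rep(1, 5), n_decoys = 2L)
  traj5 <- jitter_trajectory(build_complex(spec5), spec5, n_frames = 40, seed = 3)
  hbs5 <- hbond_series(traj5, chains_a = "A", chains_b = "B")
  expect_equal(nhb_series(hbs5), rep(5L, 40))

  # Bernoulli interface with expected count 9.8 over 12 bonds
  p <- rep(9.8 / 12, 12)
  spec <- interface_spec(occupancies = p)
  traj <- jitter_trajectory(build_complex(spec), spec, n_frames = 2000, seed = 8)
  hbs <- hbond_series(traj, chains_a = "A", chains_b = "B")
  nhb <- nhb_series(hbs)
  se <- sqrt(sum(p * (1 - p)) / 2000)
  expect_lt(abs(mean(nhb) - 9.8), 3 * se)

  # empty interface
  expect_equal(nhb_series(hbond_series(traj5, chains_a = "A", chains_b = "C",
                                       mode = "angle")),
               rep(0L, 40))
})

test_that("occupancy is the survival fraction, with residue-pair union semantics", {
  spec1 <- interface_spec(pairs = reference_interface_pairs()[10, , drop = FALSE],
                          occupancies = 0.52, n_decoys = 0L)
  cx <- build_complex(spec1)
  traj <- jitter_trajectory(cx, spec1, n_frames = 50, seed = 4)
  truth <- attr(traj, "presence")[, 1]
  hbs <- hbond_series(traj, chains_a = "A", chains_b = "B")
  occ <- occupancy(hbs, keep_absent = TRUE)
  key <- "B:SER66->A:PCA1"
  expect_equal(unname(occ[key]), mean(truth))

  # never / always present
  spec0 <- interface_spec(pairs = reference_interface_pairs()[1:2, ],
                          occupancies = c(0, 1), n_decoys = 0L)
  t0 <- jitter_trajectory(build_complex(spec0), spec0, n_frames = 30, seed = 1)
  occ0 <- occupancy(hbond_series(t0, chains_a = "A", chains_b = "B"),
                    keep_absent = TRUE)
  expect_equal(unname(occ0["B:LYS53->A:GLU106"]), 0)
  expect_equal(unname(occ0["B:LYS96->A:GLU104"]), 1)

  # Markov-correlated bond recovered within 3 effective-sample-size SEs
  specm <- interface_spec(pairs = reference_interface_pairs()[9, , drop = FALSE],
                          occupancies = 0.82, temporal = "markov",
                          p_stay = 0.9, n_decoys = 0L)
  n <- 2000
  tm <- jitter_trajectory(build_complex(specm), specm, n_frames = n, seed = 6)
  occm <- occupancy(hbond_series(tm, chains_a = "A", chains_b = "B"))
  ess <- n * (1 - 0.9) / (1 + 0.9)
  se <- sqrt(0.82 * 0.18 / ess)
  expect_lt(abs(unname(occm["B:ARG69->A:GLU35"]) - 0.82), 3 * se)
})

test_that("dissociation probability estimators behave and cross-validate", {
  expect_equal(dissociation_probability(c(b1 = 0.7)), 0.3)
  expect_equal(dissociation_probability(c(0.5, 0.5)), 0.25)
  expect_error(dissociation_probability(setNames(numeric(0), character(0))),
               "no bonds")

  # product bound and monotonicity
  occ <- c(0.3, 0.6, 0.8)
  expect_lte(dissociation_probability(occ), min(1 - occ))
  occ2 <- occ; occ2[1] <- 0.5
  expect_lt(dissociation_probability(occ2), dissociation_probability(occ))

  # empirical estimator matches the independence product for independent bonds
  spec <- interface_spec(pairs = reference_interface_pairs()[1:3, ],
                         occupancies = c(0.5, 0.6, 0.4), n_decoys = 0L)
  n <- 4000
  traj <- jitter_trajectory(build_complex(spec), spec, n_frames = n, seed = 12)
  hbs <- hbond_series(traj, chains_a = "A", chains_b = "B")
  emp <- as.numeric(dissociation_probability(hbs, "empirical_all_broken"))
  ind <- prod(1 - c(0.5, 0.6, 0.4))
  se <- sqrt(ind * (1 - ind) / n)
  expect_lt(abs(emp - ind), 3 * se)

  # rule-of-three upper bound when no all-broken frame is seen
  p <- dissociation_probability(rep(3L, 100), "empirical_all_broken")
  expect_equal(as.numeric(p), 0.03)
  expect_true(attr(p, "upper_bound"))
})

test_that("force-response typing follows the delta rule and is antisymmetric", {
  mk <- function(v) matrix(rep(v, 3), ncol = 3,
                           dimnames = list(names(v), NULL))
  st <- c(p1 = 0.50, p2 = 0.80, p3 = 0.66)
  fo <- c(p1 = 0.80, p2 = 0.50, p3 = 0.65)
  calls <- classify_force_response(mk(st), mk(fo))
  expect_equal(setNames(calls$type, calls$pair),
               c(p1 = "II", p2 = "III", p3 = "I"))

  # antisymmetry: swapping conditions maps II <-> III, fixes I
  sw <- classify_force_response(mk(fo), mk(st))
  expect_equal(sw$type, c("III", "II", "I")[match(sw$pair, calls$pair)])

  # welch gate demotes non-significant changes
  set.seed(44)
  a <- matrix(0.5 + rnorm(30, sd = 0.2), 1, 30, dimnames = list("q", NULL))
  b <- a + 0.06 + rnorm(30, sd = 0.2)
  g <- classify_force_response(a, b, test = "welch", alpha = 1e-12)
  expect_equal(g$type, "I")

  expect_error(classify_force_response(mk(st), mk(fo)[c(2, 1, 3), , drop = FALSE][1:2, ]),
               "match")
})
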