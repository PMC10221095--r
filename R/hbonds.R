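#' Donor/acceptor assignment
#'
#' Chemistry-light assignment used across the H-bond machinery: nitrogen and
#' oxygen atoms are acceptors; a nitrogen/oxygen with a hydrogen within
#' 1.2 A (in the topology frame) is a donor, one row per attached hydrogen.
#'
#' @param structure [md_structure] with explicit hydrogens for angle-mode
#'   detection (crystal structures usually lack them; see `mode` in
#'   [detect_hbonds]).
#' @return list: `donors` data frame (`donor`, `hydrogen` atom indices) and
#'   `acceptors` integer indices.
#' @export
find_donors_acceptors <- function(structure) {
  at <- structure$atoms
  xyz <- coords(structure)
  heavy <- which(toupper(at$element) %in% c("N", "O"))
  hyd <- which(toupper(at$element) == "H")
  donors <- data.frame(donor = integer(0), hydrogen = integer(0))
  if (length(hyd)) {
    for (h in hyd) {
      d2 <- rowSums(sweep(xyz[heavy, , drop = FALSE], 2, xyz[h, ])^2)
      j <- which(d2 < 1.2^2)
      if (length(j)) {
        donors <- rbind(donors, data.frame(donor = heavy[j[which.min(d2[j])]],
                                           hydrogen = h))
      }
    }
  }
  list(donors = donors, acceptors = heavy)
}

.hb_deviation_deg <- function(d_xyz, h_xyz, a_xyz) {
  # deviation of D-H-A from linearity: 180 deg minus the angle at H
  u <- d_xyz - h_xyz
  v <- a_xyz - h_xyz
  cu <- rowSums(u * v) / sqrt(rowSums(u * u) * rowSums(v * v))
  180 - acos(pmin(1, pmax(-1, cu))) * 180 / pi
}

#' Geometric hydrogen-bond detection in one frame
#'
#' A donor-hydrogen-acceptor triplet is a bond when the donor-acceptor
#' distance is at most `d_cut` (default 3.5 A) and the deviation of the
#' D-H-A angle from linearity is at most `ang_cut` (default 30 degrees, the
#' VMD convention: the cutoff is on 180 minus the angle at the hydrogen).
#' Structures without hydrogens can be screened with `mode = "distance"`,
#' which applies the distance criterion only and flags the output.
#'
#' @param xyz `n x 3` frame coordinates.
#' @param donors data frame (`donor`, `hydrogen`) as from
#'   [find_donors_acceptors]; `hydrogen` may be `NA` in distance mode.
#' @param acceptors integer acceptor indices.
#' @param d_cut donor-acceptor distance cutoff (A).
#' @param ang_cut linearity-deviation cutoff (degrees).
#' @param mode `"angle"` (default) or `"distance"` (no hydrogens needed).
#' @return data frame `donor, hydrogen, acceptor, dist, deviation` with
#'   attribute `mode`.
#' @export
detect_hbonds <- function(xyz, donors, acceptors, d_cut = 3.5, ang_cut = 30,
                          mode = c("angle", "distance")) {
  mode <- match.arg(mode)
  xyz <- as.matrix(xyz)
  if (mode == "angle" && (nrow(donors) == 0L || anyNA(donors$hydrogen))) {
    stop("detect_hbonds: angle mode requires donor hydrogens; use mode = 'distance'")
  }
  out <- data.frame(donor = integer(0), hydrogen = integer(0),
                    acceptor = integer(0), dist = numeric(0),
                    deviation = numeric(0))
  for (k in seq_len(nrow(donors))) {
    d <- donors$donor[k]
    acc <- acceptors[acceptors != d]
    if (!length(acc)) next
    dist <- sqrt(rowSums(sweep(xyz[acc, , drop = FALSE], 2, xyz[d, ])^2))
    ok <- dist <= d_cut
    if (mode == "angle") {
      h <- donors$hydrogen[k]
      dev <- .hb_deviation_deg(
        matrix(xyz[d, ], length(acc), 3, byrow = TRUE),
        matrix(xyz[h, ], length(acc), 3, byrow = TRUE),
        xyz[acc, , drop = FALSE])
      ok <- ok & dev <= ang_cut
    } else {
      dev <- rep(NA_real_, length(acc))
      h <- NA_integer_
    }
    if (any(ok)) {
      out <- rbind(out, data.frame(donor = d,
                                   hydrogen = if (mode == "angle") donors$hydrogen[k] else NA_integer_,
                                   acceptor = acc[ok], dist = dist[ok],
                                   deviation = dev[ok]))
    }
  }
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  out
}

#' Keep only bonds spanning the interface
#'
#' Retains triplets whose donor and acceptor lie on opposite sides of the
#' A/B chain partition (either direction).
#'
#' @param bonds output of [detect_hbonds].
#' @param structure the [md_structure] the indices refer to.
#' @param chains_a,chains_b disjoint chain-ID sets.
#' @export
interfacial_filter <- function(bonds, structure, chains_a, chains_b) {
  if (length(intersect(chains_a, chains_b))) {
    stop("interfacial_filter: chain sets must be disjoint")
  }
  ch <- structure$atoms$chain_id
  da <- ch[bonds$donor] %in% chains_a & ch[bonds$acceptor] %in% chains_b
  db <- ch[bonds$donor] %in% chains_b & ch[bonds$acceptor] %in% chains_a
  out <- bonds[da | db, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- attr(bonds, "mode")
  out
}

#' Trajectory-level H-bond bookkeeping
#'
#' Evaluates the detection criteria of [detect_hbonds] for every candidate
#' donor/acceptor triplet across all frames at once and returns the per-frame
#' presence matrix; the basis for occupancy, N_HB and dissociation
#' statistics.  With `chains_a`/`chains_b` given, only interfacial triplets
#' are kept.
#'
#' @inheritParams detect_hbonds
#' @param traj [md_trajectory].
#' @param chains_a,chains_b optional chain partition for interfacial
#'   filtering.
#' @return list of class `hbond_series`: `triplets` (data frame with donor,
#'   hydrogen, acceptor and residue labels), `presence` (frames x triplets
#'   logical matrix), `times`, `mode`.
#' @export
hbond_series <- function(traj, donors = NULL, acceptors = NULL,
                         chains_a = NULL, chains_b = NULL,
                         d_cut = 3.5, ang_cut = 30,
                         mode = c("angle", "distance")) {
  mode <- match.arg(mode)
  stopifnot(inherits(traj, "md_trajectory"))
  s <- traj$structure
  if (is.null(donors) || is.null(acceptors)) {
    da <- find_donors_acceptors(s)
    if (is.null(donors)) donors <- da$donors
    if (is.null(acceptors)) acceptors <- da$acceptors
  }
  if (mode == "angle" && (nrow(donors) == 0L || anyNA(donors$hydrogen))) {
    stop("hbond_series: angle mode requires donor hydrogens")
  }
  # candidate triplets
  trip <- do.call(rbind, lapply(seq_len(nrow(donors)), function(k) {
    acc <- acceptors[acceptors != donors$donor[k]]
    if (!length(acc)) return(NULL)
    data.frame(donor = donors$donor[k], hydrogen = donors$hydrogen[k],
               acceptor = acc)
  }))
  if (!is.null(chains_a) && !is.null(chains_b)) {
    ch <- s$atoms$chain_id
    keep <- (ch[trip$donor] %in% chains_a & ch[trip$acceptor] %in% chains_b) |
            (ch[trip$donor] %in% chains_b & ch[trip$acceptor] %in% chains_a)
    trip <- trip[keep, , drop = FALSE]
  }
  nf <- n_frames(traj)
  if (is.null(trip) || nrow(trip) == 0L) {
    return(structure(list(triplets = data.frame(),
                          presence = matrix(FALSE, nf, 0),
                          times = traj$times, mode = mode),
                     class = "hbond_series"))
  }
  pres <- matrix(FALSE, nf, nrow(trip))
  for (k in seq_len(nrow(trip))) {
    dxyz <- traj$coords[, trip$donor[k], , drop = FALSE];  dim(dxyz) <- c(nf, 3)
    axyz <- traj$coords[, trip$acceptor[k], , drop = FALSE]; dim(axyz) <- c(nf, 3)
    dist <- sqrt(rowSums((dxyz - axyz)^2))
    ok <- dist <= d_cut
    if (mode == "angle") {
      hxyz <- traj$coords[, trip$hydrogen[k], , drop = FALSE]; dim(hxyz) <- c(nf, 3)
      ok <- ok & .hb_deviation_deg(dxyz, hxyz, axyz) <= ang_cut
    }
    pres[, k] <- ok
  }
  lab <- function(i) paste0(s$atoms$chain_id[i], ":", s$atoms$res_name[i], s$atoms$res_seq[i])
  trip$donor_res <- lab(trip$donor)
  trip$acceptor_res <- lab(trip$acceptor)
  rownames(trip) <- NULL
  structure(list(triplets = trip, presence = pres, times = traj$times,
                 mode = mode),
            class = "hbond_series")
}

#' Per-frame interfacial bond count
#'
#' `N_HB`: the number of triplets present in each frame of an [hbond_series].
#' @param hbs [hbond_series].
#' @return integer vector per frame.
#' @export
nhb_series <- function(hbs) {
  stopifnot(inherits(hbs, "hbond_series"))
  if (ncol(hbs$presence) == 0L) return(rep(0L, nrow(hbs$presence)))
  as.integer(rowSums(hbs$presence))
}

#' H-bond occupancy (survival ratio)
#'
#' Fraction of frames in which a bond is present.  Triplets are aggregated to
#' the residue-pair level (the Table-1 convention: one row per CD47/CD172a
#' residue pair) by the per-frame union: the pair is "present" in a frame if
#' any of its atom-level triplets is.
#'
#' @param hbs [hbond_series].
#' @param keep_absent also report candidate pairs never observed (occupancy
#'   0); default drops them so tables list only bonded pairs.
#' @return named numeric vector in `[0, 1]`, names `donor_res->acceptor_res`
#'   aggregated per residue pair.
#' @export
occupancy <- function(hbs, keep_absent = FALSE) {
  stopifnot(inherits(hbs, "hbond_series"))
  if (ncol(hbs$presence) == 0L) return(setNames(numeric(0), character(0)))
  key <- paste0(hbs$triplets$donor_res, "->", hbs$triplets$acceptor_res)
  uk <- unique(key)
  out <- vapply(uk, function(k) {
    cols <- which(key == k)
    mean(rowSums(hbs$presence[, cols, drop = FALSE]) > 0)
  }, numeric(1))
  out <- setNames(out, uk)
  if (!keep_absent) out <- out[out > 0]
  out
}

#' Occupancy table across replicate runs
#'
#' Table-1-style summary: per residue pair, the per-run occupancies and their
#' mean and sample SD (n - 1 denominator) across runs.
#'
#' @param run_occupancies list of named occupancy vectors ([occupancy]), one
#'   per replicate run; pairs absent from a run count as occupancy 0.
#' @param condition optional condition label stored in the output.
#' @return data frame `pair, mean, sd, n_runs, condition` of class
#'   `occupancy_table`, one row per residue pair.
#' @export
occupancy_table <- function(run_occupancies, condition = NA_character_) {
  stopifnot(is.list(run_occupancies), length(run_occupancies) >= 1L)
  pairs <- unique(unlist(lapply(run_occupancies, names)))
  m <- vapply(run_occupancies, function(o) {
    v <- setNames(rep(0, length(pairs)), pairs)
    v[names(o)] <- o
    v
  }, numeric(length(pairs)))
  m <- matrix(m, nrow = length(pairs),
              dimnames = list(pairs, NULL))
  out <- data.frame(pair = pairs,
                    mean = apply(m, 1, mean),
                    sd = if (ncol(m) > 1L) apply(m, 1, stats::sd) else 0,
                    n_runs = ncol(m),
                    condition = condition,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("occupancy_table", "data.frame")
  attr(out, "per_run") <- m
  out
}

#' Dissociation probability of the bound complex
#'
#' Two estimators of the probability that every interfacial bond is broken
#' simultaneously (the dissociation-permissive state):
#' \describe{
#'   \item{independence_product}{`prod(1 - occ_i)` over the per-pair
#'     occupancies, exact if bonds fluctuate independently.}
#'   \item{empirical_all_broken}{fraction of frames with zero interfacial
#'     bonds; when no such frame is observed the rule-of-three upper bound
#'     `3 / n_frames` is reported (attribute `upper_bound = TRUE`).}
#' }
#' The two differ when bonds are correlated, and neither reproduces
#' kinetic-model dissociation rates; they order conditions by interface
#' persistence.
#'
#' @param x a named occupancy vector (independence product) or an
#'   [hbond_series]/integer N_HB series (empirical).
#' @param method `"independence_product"` or `"empirical_all_broken"`.
#' @return probability in `[0, 1]`.
#' @export
dissociation_probability <- function(x, method = c("independence_product",
                                                   "empirical_all_broken")) {
  method <- match.arg(method)
  if (method == "independence_product") {
    occ <- if (inherits(x, "hbond_series")) occupancy(x) else x
    if (length(occ) == 0L) stop("dissociation_probability: no bonds supplied")
    if (any(occ < 0 | occ > 1)) stop("dissociation_probability: occupancies must be in [0,1]")
    return(prod(1 - occ))
  }
  nhb <- if (inherits(x, "hbond_series")) nhb_series(x) else as.integer(x)
  if (length(nhb) == 0L) stop("dissociation_probability: empty N_HB series")
  p <- mean(nhb == 0L)
  if (p == 0) {
    p <- 3 / length(nhb)
    attr(p, "upper_bound") <- TRUE
  }
  p
}

#' Force-response typing of interfacial H-bonds
#'
#' Classifies each residue pair by the change in mean occupancy between the
#' static and force-loaded conditions: type II (force-enhanced) when
#' `delta >= delta_min`, type III (force-weakened) when `delta <= -delta_min`,
#' type I (force-insensitive) otherwise.  With `test = "welch"` a pair whose
#' change is not significant at `alpha` is demoted to type I regardless of
#' magnitude.  Swapping the two conditions maps II to III and leaves I fixed.
#'
#' @param occ_static,occ_force matrices (pairs x runs) of per-run occupancies
#'   with identical rownames (pair keys), >= 2 runs each when testing.
#' @param delta_min minimum absolute occupancy change to call II/III.
#' @param test `"none"` or `"welch"`.
#' @param alpha significance level for the Welch gate.
#' @return data frame `pair, occ_static, occ_force, delta, p_value, type`.
#' @export
classify_force_response <- function(occ_static, occ_force, delta_min = 0.05,
                                    test = c("none", "welch"), alpha = 0.05) {
  test <- match.arg(test)
  occ_static <- as.matrix(occ_static); occ_force <- as.matrix(occ_force)
  if (is.null(rownames(occ_static)) || is.null(rownames(occ_force)) ||
      !identical(sort(rownames(occ_static)), sort(rownames(occ_force)))) {
    stop("classify_force_response: pair keys (rownames) must match between conditions")
  }
  occ_force <- occ_force[rownames(occ_static), , drop = FALSE]
  if (test == "welch" && (ncol(occ_static) < 2L || ncol(occ_force) < 2L)) {
    stop("classify_force_response: welch gate needs >= 2 replicates per condition")
  }
  ms <- rowMeans(occ_static); mf <- rowMeans(occ_force)
  delta <- mf - ms
  p <- rep(NA_real_, length(delta))
  if (test == "welch") {
    for (i in seq_along(delta)) {
      a <- occ_static[i, ]; b <- occ_force[i, ]
      p[i] <- if (stats::var(a) + stats::var(b) == 0) {
        if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
      } else stats::t.test(b, a)$p.value
    }
  }
  type <- ifelse(delta >= delta_min, "II", ifelse(delta <= -delta_min, "III", "I"))
  if (test == "welch") type[p > alpha] <- "I"
  data.frame(pair = rownames(occ_static), occ_static = ms, occ_force = mf,
             delta = delta, p_value = p, type = type,
             row.names = NULL, stringsAsFactors = FALSE)
}
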