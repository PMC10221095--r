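#' Reference interfacial residue pairs
#'
#' Built-in catalogue of the twelve CD47/CD172a interfacial hydrogen-bonded
#' residue pairs used to scale synthetic fixtures, with static-state
#' occupancies for the pyroglutamate-modified (`wt`, PCA1 N-terminus) and
#' unmodified (`gt`, GLN1 N-terminus) complexes.  These serve as generator
#' targets with known ground truth; they are inputs, not results.
#'
#' @return data frame: `cd47_res, cd47_seq, cd172a_res, cd172a_seq, occ_wt,
#'   occ_gt`.
#' @export
reference_interface_pairs <- function() {
  data.frame(
    cd47_res    = c("GLU", "GLU", "GLU", "GLU", "GLU", "GLU", "ASP", "ASP",
                    "GLU", "PCA", "PCA", "PCA"),
    cd47_seq    = c(106L, 104L, 104L, 100L, 97L, 97L, 51L, 46L, 35L, 1L, 1L, 1L),
    cd172a_res  = c("LYS", "LYS", "GLN", "ARG", "LYS", "LYS", "ARG", "SER",
                    "ARG", "SER", "GLU", "GLN"),
    cd172a_seq  = c(53L, 96L, 52L, 69L, 96L, 53L, 95L, 98L, 69L, 66L, 54L, 52L),
    occ_wt      = c(0.54, 0.66, 0.60, 0.79, 0.66, 0.34, 0.07, 0.53, 0.82,
                    0.52, 0.00, 0.00),
    occ_gt      = c(0.48, 0.52, 0.22, 0.69, 0.30, 0.28, 0.77, 0.30, 0.81,
                    0.21, 0.08, 0.15),
    stringsAsFactors = FALSE)
}

#' Interface specification for the complex generator
#'
#' Describes a two-chain interface as a list of donor/acceptor residue pairs
#' with per-bond target occupancies and a temporal model, `"iid"` (each frame
#' an independent Bernoulli draw) or `"markov"` (sticky two-state chain: keep
#' the previous state with probability `p_stay`, else redraw Bernoulli, so
#' the stationary occupancy equals the target and the lag-k autocorrelation
#' is `p_stay^k`).
#'
#' @param pairs data frame as [reference_interface_pairs] (default), or any
#'   frame with those columns.
#' @param occupancies per-bond targets in `[0,1]`; default the `occ_wt`
#'   column.
#' @param temporal `"iid"` or `"markov"`.
#' @param p_stay persistence probability for the Markov model.
#' @param chain_a,chain_b chain IDs for the acceptor (CD47-like) and donor
#'   (CD172a-like) sides.
#' @param n_decoys donor/acceptor sites placed permanently outside the
#'   detection cutoffs.
#' @return list of class `interface_spec`.
#' @export
interface_spec <- function(pairs = reference_interface_pairs(),
                           occupancies = pairs$occ_wt,
                           temporal = c("iid", "markov"), p_stay = 0.9,
                           chain_a = "A", chain_b = "B", n_decoys = 3L) {
  temporal <- match.arg(temporal)
  stopifnot(nrow(pairs) >= 1L, length(occupancies) == nrow(pairs))
  if (any(occupancies < 0 | occupancies > 1)) {
    stop("interface_spec: occupancies must lie in [0, 1]")
  }
  stopifnot(p_stay >= 0, p_stay < 1)
  structure(list(pairs = pairs, occupancies = occupancies, temporal = temporal,
                 p_stay = p_stay, chain_a = chain_a, chain_b = chain_b,
                 n_decoys = as.integer(n_decoys)),
            class = "interface_spec")
}

#' Ideal beta-strand Ca trace
#'
#' Ordered Ca positions along a given direction at a constant rise (default
#' 3.3 A per residue, a beta-strand-like spacing); the ground-truth axis is
#' the direction itself.
#'
#' @param n_res number of residues (>= 3).
#' @param rise Ca-Ca rise (A).
#' @param direction axis 3-vector (normalised internally).
#' @param origin first Ca position.
#' @param chain_id,start_resseq,res_name residue labelling.
#' @return [md_structure] of Ca atoms with attribute `axis` (unit vector).
#' @export
build_strand <- function(n_res, rise = 3.3, direction = c(0, 0, 1),
                         origin = c(0, 0, 0), chain_id = "A",
                         start_resseq = 1L, res_name = "ALA") {
  if (n_res < 3L) stop("build_strand: need >= 3 residues")
  u <- direction / sqrt(sum(direction^2))
  pos <- sweep(outer(seq_len(n_res) - 1, u * rise), 2, origin, "+")
  s <- md_structure(data.frame(
    name = "CA", element = "C", res_name = res_name,
    res_seq = start_resseq + seq_len(n_res) - 1L, chain_id = chain_id,
    x = pos[, 1], y = pos[, 2], z = pos[, 3], stringsAsFactors = FALSE))
  attr(s, "axis") <- u
  s
}

# hydrogen placement giving an exact D-H-A linearity deviation (degrees) for
# donor at origin, acceptor at (0,0,d_da), N-H length d_nh
.h_for_deviation <- function(deviation_deg, d_da = 2.9, d_nh = 1.0) {
  dev_of <- function(tilt) {
    h <- c(sin(tilt), 0, cos(tilt)) * d_nh
    u <- -h                      # H -> D
    v <- c(0, 0, d_da) - h       # H -> A
    180 - acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  }
  if (deviation_deg == 0) return(c(0, 0, d_nh))
  tilt <- stats::uniroot(function(t) dev_of(t) - deviation_deg,
                         c(1e-10, pi / 3), tol = 1e-13)$root
  c(sin(tilt), 0, cos(tilt)) * d_nh
}

#' Synthetic two-chain complex with explicit D-H...A geometry
#'
#' Realizes every bond of an [interface_spec] as an explicit
#' donor-hydrogen-acceptor site: acceptor oxygens (chain A) on the y = z = 0
#' line at 6 A spacing, donor nitrogens (chain B) 2.9 A above, hydrogens
#' placed for an exact 5-degree linearity deviation, all well inside the
#' 3.5 A / 30-degree cutoffs.  Decoy donor/acceptor sites sit at 5.5 A
#' separation, permanently outside the distance cutoff.  Generation fails if
#' any non-bonded atom pair ends up closer than 1.5 A.
#'
#' @param spec [interface_spec].
#' @return [md_structure] with attribute `bond_atoms`, a data frame mapping
#'   each specified bond to its donor/hydrogen/acceptor atom indices.
#' @export
build_complex <- function(spec) {
  stopifnot(inherits(spec, "interface_spec"))
  nb <- nrow(spec$pairs)
  rows <- list(); bond_atoms <- list()
  add <- function(name, element, res_name, res_seq, chain, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, element = element, res_name = res_name,
      res_seq = res_seq, chain_id = chain,
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
    length(rows)
  }
  h_local <- .h_for_deviation(5)
  for (k in seq_len(nb)) {
    base <- c(6 * (k - 1), 0, 0)
    p <- spec$pairs[k, ]
    ai <- add(paste0("OA", k), "O", p$cd47_res, p$cd47_seq, spec$chain_a, base)
    di <- add(paste0("ND", k), "N", p$cd172a_res, p$cd172a_seq, spec$chain_b,
              base + c(0, 0, 2.9))
    # donor local frame points from N down to O: rotate local +z to -z
    hi <- add(paste0("HD", k), "H", p$cd172a_res, p$cd172a_seq, spec$chain_b,
              base + c(0, 0, 2.9) + c(h_local[1], h_local[2], -h_local[3]))
    bond_atoms[[k]] <- data.frame(bond = k, donor = di, hydrogen = hi,
                                  acceptor = ai)
  }
  for (k in seq_len(spec$n_decoys)) {
    base <- c(6 * (nb + k - 1), 0, 0)
    add(paste0("OX", k), "O", "GLY", 200L + k, spec$chain_a, base)
    di <- add(paste0("NX", k), "N", "GLY", 300L + k, spec$chain_b,
              base + c(0, 0, 5.5))
    add(paste0("HX", k), "H", "GLY", 300L + k, spec$chain_b,
        base + c(0, 0, 4.5))
  }
  atoms <- do.call(rbind, rows)
  s <- md_structure(atoms)
  xyz <- coords(s)
  d <- as.matrix(stats::dist(xyz)); diag(d) <- Inf
  bonded <- do.call(rbind, bond_atoms)
  for (r in seq_len(nrow(bonded))) {
    d[bonded$donor[r], bonded$hydrogen[r]] <- Inf
    d[bonded$hydrogen[r], bonded$donor[r]] <- Inf
  }
  # decoy N-H pairs are covalent too
  hx <- grep("^HX", atoms$name); nx <- grep("^NX", atoms$name)
  d[cbind(nx, hx)] <- Inf; d[cbind(hx, nx)] <- Inf
  if (min(d) < 1.5) stop("build_complex: geometric clash between non-bonded atoms")
  attr(s, "bond_atoms") <- bonded
  s
}

#' Toggled-bond trajectory with known ground truth
#'
#' Per frame, each specified bond is present or absent according to its
#' temporal model; an absent bond's acceptor is displaced radially (along the
#' donor-to-acceptor direction) by +1.5 A, taking the donor-acceptor distance
#' from 2.9 A to an unambiguous 4.4 A, outside the 3.5 A cutoff.  The
#' realized presence matrix is stored as ground truth.  Regeneration with the
#' same spec and seed is bitwise identical.
#'
#' @param complex [build_complex] output.
#' @param spec the same [interface_spec].
#' @param n_frames number of frames (>= 1).
#' @param seed RNG seed.
#' @param dt_ns frame spacing (ns).
#' @return [md_trajectory] with attributes `presence` (frames x bonds logical
#'   matrix) and `bond_atoms`.
#' @export
jitter_trajectory <- function(complex, spec, n_frames, seed, dt_ns = 0.01) {
  stopifnot(inherits(complex, "md_structure"), inherits(spec, "interface_spec"),
            n_frames >= 1L)
  bonds <- attr(complex, "bond_atoms")
  if (is.null(bonds)) stop("jitter_trajectory: complex lacks bond_atoms (not from build_complex?)")
  nb <- nrow(bonds)
  xyz0 <- coords(complex)
  set.seed(seed)
  presence <- matrix(FALSE, n_frames, nb)
  for (k in seq_len(nb)) {
    occ <- spec$occupancies[k]
    if (spec$temporal == "iid") {
      presence[, k] <- stats::runif(n_frames) < occ
    } else {
      x <- stats::runif(1) < occ
      presence[1, k] <- x
      if (n_frames > 1L) {
        stay <- stats::runif(n_frames - 1L) < spec$p_stay
        redraw <- stats::runif(n_frames - 1L) < occ
        for (f in 2:n_frames) {
          x <- if (stay[f - 1L]) x else redraw[f - 1L]
          presence[f, k] <- x
        }
      }
    }
  }
  arr <- array(rep(xyz0, each = n_frames), dim = c(n_frames, nrow(xyz0), 3))
  for (k in seq_len(nb)) {
    a <- bonds$acceptor[k]; dnr <- bonds$donor[k]
    u <- xyz0[a, ] - xyz0[dnr, ]
    u <- u / sqrt(sum(u^2))
    off <- which(!presence[, k])
    for (d in 1:3) arr[off, a, d] <- xyz0[a, d] + 1.5 * u[d]
  }
  traj <- md_trajectory(complex, arr, times = dt_ns * (seq_len(n_frames) - 1))
  attr(traj, "presence") <- presence
  attr(traj, "bond_atoms") <- bonds
  traj
}

#' Synthetic force-time traces
#'
#' Ground-truth traces for testing peak extraction: `"triangle"` ramps at
#' `slope_pN_ns` to `peak_pN` and back down; `"ramp_clamp"` ramps to
#' `plateau_pN` and holds it (phase switches to clamp at the crossing).
#' Optional iid Gaussian noise is added on top.
#'
#' @param peak_pN peak (triangle) force, > 0.
#' @param shape `"triangle"` or `"ramp_clamp"`.
#' @param noise_sd Gaussian noise SD (pN).
#' @param slope_pN_ns ramp slope (default 17.37 pN/ns, i.e. 34.74 pN/nm x
#'   0.5 nm/ns).
#' @param plateau_pN clamp level for `"ramp_clamp"` (default 25 pN).
#' @param plateau_ns clamp duration.
#' @param dt_ns sample spacing.
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return [force_trace] with attribute `ground_truth` (peak or plateau).
#' @export
make_force_trace <- function(peak_pN = 530, shape = c("triangle", "ramp_clamp"),
                             noise_sd = 0, slope_pN_ns = 34.74 * 0.5,
                             plateau_pN = 25, plateau_ns = 2, dt_ns = 0.001,
                             seed = 1L) {
  shape <- match.arg(shape)
  if (peak_pN <= 0) stop("make_force_trace: peak must be > 0")
  if (dt_ns <= 0) stop("make_force_trace: dt_ns must be > 0 (zero-length trace)")
  if (shape == "triangle") {
    t_up <- peak_pN / slope_pN_ns
    tm <- sort(unique(c(seq(0, 2 * t_up, by = dt_ns), t_up)))  # include the apex
    if (length(tm) < 2L) stop("make_force_trace: zero-length trace; decrease dt_ns")
    f <- ifelse(tm <= t_up, slope_pN_ns * tm, pmax(0, peak_pN - slope_pN_ns * (tm - t_up)))
    phase <- rep("ramp", length(tm))
    truth <- c(peak = peak_pN, peak_time = t_up)
  } else {
    t_up <- plateau_pN / slope_pN_ns
    tm <- sort(unique(c(seq(0, t_up + plateau_ns, by = dt_ns), t_up)))
    if (length(tm) < 2L) stop("make_force_trace: zero-length trace; decrease dt_ns")
    f <- pmin(slope_pN_ns * tm, plateau_pN)
    phase <- ifelse(tm < t_up, "ramp", "clamp")
    truth <- c(plateau = plateau_pN, switch_time = t_up)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    f <- f + stats::rnorm(length(f), sd = noise_sd)
  }
  k <- spring_pN_nm_to_kcal(34.74)
  dummy <- cumsum(c(0, rep(diff(tm)[1] * 5, length(tm) - 1)))
  tr <- force_trace(tm, f, dummy_A = dummy,
                    steered_A = dummy - force_pN_to_kcal(f) / k,
                    phase = phase)
  attr(tr, "ground_truth") <- truth
  tr
}
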