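#' Force-field parameter files
#'
#' Per-atom charges, Lennard-Jones parameters and intrinsic Born radii are
#' supplied as whitespace/comma-delimited text with header
#' `res_name atom_name charge_e lj_eps_kcal lj_rmin_A born_radius_A`.
#' Synthetic fixtures ship complete parameter sets so no force-field
#' distribution is needed.
#'
#' @param path parameter file path.
#' @return data frame with the six columns above.
#' @export
read_ff_params <- function(path) {
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                         sep = "", comment.char = "#")
  need <- c("res_name", "atom_name", "charge_e", "lj_eps_kcal", "lj_rmin_A",
            "born_radius_A")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("read_ff_params: missing columns: ", paste(miss, collapse = ", "))
  d
}

#' @rdname read_ff_params
#' @param structure [md_structure] to parameterize.
#' @param params parameter data frame as from `read_ff_params`.
#' @return the atom table with `charge`, `lj_eps`, `lj_rmin`, `born_radius`
#'   columns filled by (res_name, atom_name) lookup.
#' @export
assign_ff_params <- function(structure, params) {
  at <- structure$atoms
  key <- paste(at$res_name, at$name)
  pk <- paste(params$res_name, params$atom_name)
  idx <- match(key, pk)
  if (anyNA(idx)) {
    stop("assign_ff_params: no parameters for atom(s): ",
         paste(utils::head(unique(key[is.na(idx)]), 5), collapse = "; "))
  }
  at$charge <- params$charge_e[idx]
  at$lj_eps <- params$lj_eps_kcal[idx]
  at$lj_rmin <- params$lj_rmin_A[idx]
  at$born_radius <- params$born_radius_A[idx]
  at
}

#' Gas-phase pairwise energy (Coulomb + Lennard-Jones)
#'
#' `E = sum_{i<j} [ k_C q_i q_j / r_ij + eps_ij ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6) ]`
#' with Lorentz-Berthelot combination (`eps_ij = sqrt(eps_i eps_j)`,
#' `rmin_ij = (rmin_i + rmin_j)/2`) and no cutoff (desk-scale systems).
#' `groups` restricts the sum to pairs spanning two groups, which is the
#' cross-interface term used in the binding-energy difference.
#'
#' @param xyz `n x 3` coordinates (A).
#' @param charges elementary charges.
#' @param lj_eps,lj_rmin LJ well depth (kcal/mol) and rmin (A) per atom; zero
#'   epsilon switches LJ off for that atom.
#' @param groups optional integer vector (1/2) selecting cross-group pairs
#'   only.
#' @return energy in kcal/mol.
#' @export
coulomb_lj <- function(xyz, charges, lj_eps = NULL, lj_rmin = NULL,
                       groups = NULL) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (length(charges) != n) stop("coulomb_lj: one charge per atom required")
  if (n < 2L) return(0)
  if (is.null(lj_eps)) lj_eps <- rep(0, n)
  if (is.null(lj_rmin)) lj_rmin <- rep(0, n)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (!is.null(groups)) {
    keep <- groups[pr[, 1]] != groups[pr[, 2]]
    pr <- pr[keep, , drop = FALSE]
  }
  if (nrow(pr) == 0L) return(0)
  i <- pr[, 1]; j <- pr[, 2]
  r <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  if (any(r < 1e-9)) stop("coulomb_lj: coincident atoms")
  e <- sum(rc_constants()$coulomb_kcal * charges[i] * charges[j] / r)
  eps <- sqrt(lj_eps[i] * lj_eps[j])
  act <- eps > 0
  if (any(act)) {
    rm6 <- ((lj_rmin[i[act]] + lj_rmin[j[act]]) / 2 / r[act])^6
    e <- e + sum(eps[act] * (rm6^2 - 2 * rm6))
  }
  e
}

#' Effective Born radii (pairwise descreening)
#'
#' Hawkins-Cramer-Truhlar style effective radii: each atom's inverse radius
#' starts from its (offset-reduced) intrinsic radius and is descreened by the
#' scaled spheres of all other atoms via the standard pairwise integral.
#'
#' @param xyz `n x 3` coordinates (A).
#' @param rho intrinsic Born radii (A), > 0.
#' @param scale descreening scale factor applied to neighbour radii.
#' @param offset radius offset (A) subtracted before integration.
#' @return effective Born radii (A), all > 0 (error otherwise).
#' @export
born_radii <- function(xyz, rho, scale = 0.8, offset = 0.09) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (length(rho) != n || any(rho <= 0)) stop("born_radii: rho must be > 0, one per atom")
  rr <- rho - offset
  if (any(rr <= 0)) stop("born_radii: offset exceeds an intrinsic radius")
  inv <- 1 / rr
  if (n > 1L) {
    d <- as.matrix(stats::dist(xyz))
    for (i in seq_len(n)) {
      for (j in seq_len(n)[-i]) {
        r <- d[i, j]
        sj <- scale * rr[j]
        if (rr[i] >= r + sj) next  # j's sphere fully inside i's radius
        u <- r + sj
        l <- max(abs(r - sj), rr[i])
        inv[i] <- inv[i] - 0.5 * (1 / l - 1 / u +
          0.25 * (r - sj^2 / r) * (1 / u^2 - 1 / l^2) +
          0.5 / r * log(l / u))
      }
    }
  }
  if (any(inv <= 0)) stop("born_radii: non-positive effective radius (overlapping spheres)")
  1 / inv
}

#' Generalized-Born polar solvation energy
#'
#' Still-style GB:
#' `dG = -1/2 (1/eps_in - 1/eps_out) k_C sum_ij q_i q_j / f_GB(r_ij, R_i, R_j)`
#' with `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))`; the `i = j`
#' self terms give the Born ion limit `-1/2 (1 - 1/eps_out) k_C q^2 / R`.
#'
#' @param xyz `n x 3` coordinates (A).
#' @param charges elementary charges.
#' @param radii effective Born radii (A), e.g. from [born_radii].
#' @param eps_in,eps_out interior/solvent dielectric constants.
#' @return energy in kcal/mol.
#' @export
gb_polar <- function(xyz, charges, radii, eps_in = 1, eps_out = 78.5) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (length(charges) != n || length(radii) != n) stop("gb_polar: need charge and radius per atom")
  if (any(radii <= 0)) stop("gb_polar: non-positive Born radius")
  pref <- -0.5 * (1 / eps_in - 1 / eps_out) * rc_constants()$coulomb_kcal
  r2 <- as.matrix(stats::dist(xyz))^2
  rr <- outer(radii, radii)
  fgb <- sqrt(r2 + rr * exp(-r2 / (4 * rr)))
  qq <- outer(charges, charges)
  pref * sum(qq / fgb)
}

#' Nonpolar solvation energy from surface area
#'
#' Linear surface-area model `gamma * SASA + beta` with the standard
#' MM-GB/SA coefficients as defaults.
#'
#' @param sasa_total total SASA (A^2), >= 0.
#' @param gamma surface tension (kcal/mol/A^2).
#' @param beta offset (kcal/mol).
#' @return energy in kcal/mol.
#' @export
nonpolar_surface <- function(sasa_total, gamma = 0.00542, beta = 0.92) {
  if (any(sasa_total < 0)) stop("nonpolar_surface: SASA must be >= 0")
  gamma * sasa_total + beta
}

#' Decomposed binding energy (single-trajectory MM-GB/SA)
#'
#' Per-frame binding-energy estimate
#' `E_B = dE_gas + dG_polar + dG_nonpolar`, each term the complex value minus
#' the two separated-part values computed from the same complex geometry
#' (single-trajectory convention).  `dE_gas` is Coulomb + LJ, `dG_polar` the
#' generalized-Born term with per-state effective radii, `dG_nonpolar` the
#' surface-area term.  No entropy contribution is included.
#'
#' @param traj [md_trajectory] whose topology has been parameterized with
#'   [assign_ff_params] columns (or pass `params`).
#' @param chains_a,chains_b disjoint chain sets (receptor/ligand).
#' @param params optional parameter data frame applied to the topology first.
#' @param stride analyse every `stride`-th frame.
#' @param sasa_n_points sphere points for the SASA term.
#' @param eps_in,eps_out GB dielectrics.
#' @param gamma,beta nonpolar model coefficients.  In the three-state
#'   difference the constant offset does not cancel (one `beta` per state
#'   leaves `-beta` in the total), so `beta` defaults to 0 here, keeping the
#'   binding energy of two non-interacting chains at zero; [nonpolar_surface]
#'   keeps the conventional 0.92 kcal/mol default for absolute energies.
#' @return data frame of class `energy_breakdown`: one row per analysed frame
#'   with `frame, time_ns, e_gas, g_polar, g_nonpolar, e_binding`; attribute
#'   `summary` holds mean and SD of `e_binding`.
#' @export
binding_energy <- function(traj, chains_a, chains_b, params = NULL,
                           stride = 1L, sasa_n_points = 240L,
                           eps_in = 1, eps_out = 78.5,
                           gamma = 0.00542, beta = 0) {
  stopifnot(inherits(traj, "md_trajectory"))
  at <- if (is.null(params)) traj$structure$atoms else
    assign_ff_params(traj$structure, params)
  need <- c("charge", "lj_eps", "lj_rmin", "born_radius")
  if (!all(need %in% names(at)) || anyNA(at[need])) {
    stop("binding_energy: topology lacks charge/LJ/Born parameters; supply 'params'")
  }
  ia <- which(at$chain_id %in% chains_a)
  ib <- which(at$chain_id %in% chains_b)
  if (!length(ia) || !length(ib)) stop("binding_energy: both chain sets must be non-empty")
  if (length(intersect(chains_a, chains_b))) stop("binding_energy: chain sets must be disjoint")
  sel <- c(ia, ib)
  grp <- c(rep(1L, length(ia)), rep(2L, length(ib)))
  q <- at$charge[sel]; eps <- at$lj_eps[sel]; rmin <- at$lj_rmin[sel]
  rho <- at$born_radius[sel]; rvdw <- at$vdw_radius[sel]
  frames <- seq(1L, n_frames(traj), by = stride)

  one_state <- function(xyz, qq, ee, rr, rh, rv) {
    gb <- gb_polar(xyz, qq, born_radii(xyz, rh))
    np <- nonpolar_surface(shrake_rupley(xyz, rv, n_points = sasa_n_points)$total,
                           gamma, beta)
    c(gas = coulomb_lj(xyz, qq, ee, rr), polar = gb, nonpolar = np)
  }

  rows <- lapply(frames, function(f) {
    xyz <- frame_coords(traj, f)[sel, , drop = FALSE]
    ab <- one_state(xyz, q, eps, rmin, rho, rvdw)
    a <- one_state(xyz[grp == 1L, , drop = FALSE], q[grp == 1L], eps[grp == 1L],
                   rmin[grp == 1L], rho[grp == 1L], rvdw[grp == 1L])
    b <- one_state(xyz[grp == 2L, , drop = FALSE], q[grp == 2L], eps[grp == 2L],
                   rmin[grp == 2L], rho[grp == 2L], rvdw[grp == 2L])
    d <- ab - a - b
    data.frame(frame = f, time_ns = traj$times[f], e_gas = d[["gas"]],
               g_polar = d[["polar"]], g_nonpolar = d[["nonpolar"]],
               e_binding = sum(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("energy_breakdown", "data.frame")
  attr(out, "summary") <- c(mean = mean(out$e_binding),
                            sd = if (nrow(out) > 1L) stats::sd(out$e_binding) else 0)
  out
}
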