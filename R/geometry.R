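#' Kabsch superposition
#'
#' Least-squares rigid superposition of `mobile` onto `ref` via singular value
#' decomposition, with optional weights (e.g. masses).  The returned rotation
#' is always proper (det = +1); the RMSD is the minimum over all rigid
#' transforms.
#'
#' @param mobile,ref `n x 3` coordinate matrices, equal `n >= 3`.
#' @param weights optional non-negative weights, length `n`.
#' @return list with `rotation` (3x3), `translation` (length 3, applied as
#'   `coords %*% t(R) + translation`), `rmsd` (A) and `transform(x)` applying
#'   the fit to any `m x 3` matrix.
#' @export
kabsch_superpose <- function(mobile, ref, weights = NULL) {
  mobile <- as.matrix(mobile); ref <- as.matrix(ref)
  n <- nrow(mobile)
  if (n < 3L || nrow(ref) != n) {
    stop("kabsch_superpose: need >= 3 paired points")
  }
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(ref * w)
  pm <- sweep(mobile, 2, cm); pr <- sweep(ref, 2, cr)
  # collinearity guard: rank of the weighted point cloud
  if (qr(pm * sqrt(w))$rank < 2L) {
    stop("kabsch_superpose: degenerate geometry (collinear or coincident points)")
  }
  h <- t(pm * w) %*% pr
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- pm %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((fitted - pr)^2)))
  translation <- cr - as.numeric(rot %*% cm)
  list(rotation = rot, translation = translation, rmsd = rmsd,
       transform = function(x) sweep(as.matrix(x) %*% t(rot), 2, translation, "+"))
}

#' Per-frame RMSD series
#'
#' Time course of the (optionally superposed) root-mean-square deviation of a
#' selection from a reference frame; the standard Ca-RMSD when the selection
#' is the Ca atoms.
#'
#' @param traj [md_trajectory].
#' @param selection integer atom indices (e.g. from [select_atoms]); `NULL`
#'   means all atoms.
#' @param ref_frame reference frame index (maps to exactly 0).
#' @param fit superpose each frame onto the reference first (default TRUE).
#' @param weights optional per-atom weights over the selection.
#' @return numeric vector, A per frame.
#' @export
rmsd_series <- function(traj, selection = NULL, ref_frame = 1L, fit = TRUE,
                        weights = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.null(selection)) selection <- seq_len(nrow(traj$structure$atoms))
  if (length(selection) == 0L) stop("rmsd_series: empty selection")
  ref <- frame_coords(traj, ref_frame)[selection, , drop = FALSE]
  w <- if (is.null(weights)) rep(1, length(selection)) else weights
  w <- w / sum(w)
  vapply(seq_len(n_frames(traj)), function(f) {
    if (f == ref_frame) return(0)  # exact by definition
    m <- frame_coords(traj, f)[selection, , drop = FALSE]
    if (fit) {
      kabsch_superpose(m, ref, weights = w)$rmsd
    } else {
      sqrt(sum(w * rowSums((m - ref)^2)))
    }
  }, numeric(1))
}

#' Per-residue RMSF
#'
#' Root-mean-square fluctuation of each selected atom about its mean position,
#' after superposing every frame onto the iteratively refined mean structure
#' (two passes).  With a Ca selection this is the per-residue flexibility
#' profile.
#'
#' @inheritParams rmsd_series
#' @param superpose fit frames onto the mean structure first (default TRUE);
#'   set FALSE when frames are already aligned.
#' @param fit_selection indices used for the fit (default: the selection
#'   itself, i.e. the analysed sub-chain; pass all-Ca indices to fit on the
#'   whole complex instead).
#' @return data frame `chain_id, res_seq, rmsf` (A), one row per selected atom.
#' @export
rmsf_per_residue <- function(traj, selection = NULL, superpose = TRUE,
                             fit_selection = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  nf <- n_frames(traj)
  if (nf < 2L) stop("rmsf_per_residue: need >= 2 frames")
  if (is.null(selection)) selection <- seq_len(nrow(traj$structure$atoms))
  if (is.null(fit_selection)) fit_selection <- selection
  arr <- traj$coords
  if (superpose) {
    ref <- frame_coords(traj, 1L)[fit_selection, , drop = FALSE]
    for (pass in 1:2) {
      aligned <- array(NA_real_, dim = dim(arr))
      for (f in seq_len(nf)) {
        m <- arr[f, , ]
        fit <- kabsch_superpose(m[fit_selection, , drop = FALSE], ref)
        aligned[f, , ] <- fit$transform(m)
      }
      arr <- aligned
      ref <- apply(arr[, fit_selection, , drop = FALSE], c(2, 3), mean)
    }
  }
  sub <- arr[, selection, , drop = FALSE]
  mean_pos <- apply(sub, c(2, 3), mean)
  dev2 <- sweep(sub, c(2, 3), mean_pos)^2
  rmsf <- sqrt(apply(dev2, 2, sum) / nf)
  at <- traj$structure$atoms[selection, ]
  data.frame(chain_id = at$chain_id, res_seq = at$res_seq, rmsf = rmsf,
             stringsAsFactors = FALSE)
}

#' Radius of gyration
#'
#' Mass-weighted RMS distance from the centre of mass,
#' `Rgyr = sqrt(sum(m_i |r_i - r_cm|^2) / sum(m_i))`; the compactness measure
#' of a complex.
#'
#' @param xyz `n x 3` coordinates (A).
#' @param masses atomic masses (amu); uniform when `NULL`.
#' @return Rgyr in A.
#' @export
radius_of_gyration <- function(xyz, masses = NULL) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1L) stop("radius_of_gyration: need >= 1 atom")
  if (is.null(masses)) masses <- rep(1, nrow(xyz))
  if (any(masses <= 0)) stop("radius_of_gyration: masses must be > 0")
  w <- masses / sum(masses)
  cm <- colSums(xyz * w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, cm)^2)))
}

#' @rdname radius_of_gyration
#' @param traj [md_trajectory]; per-frame series using the topology masses.
#' @param selection optional atom indices.
#' @export
rgyr_series <- function(traj, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(traj$structure$atoms))
  m <- traj$structure$atoms$mass[selection]
  vapply(seq_len(n_frames(traj)), function(f) {
    radius_of_gyration(frame_coords(traj, f)[selection, , drop = FALSE], m)
  }, numeric(1))
}

#' Weighted centroid
#'
#' @param xyz `n x 3` coordinates.
#' @param weights optional weights (default uniform; pass masses for a centre
#'   of mass).
#' @return length-3 position.
#' @export
centroid <- function(xyz, weights = NULL) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1L) stop("centroid: need >= 1 point")
  if (is.null(weights)) weights <- rep(1, nrow(xyz))
  colSums(xyz * (weights / sum(weights)))
}

#' Axis of a beta-strand
#'
#' First principal component of ordered Ca coordinates, oriented N-terminus to
#' C-terminus: the sign is flipped if needed so that
#' `direction . (last - first) > 0`.  Listing the same residues in reverse
#' order therefore flips the axis.
#'
#' @param ca_xyz ordered `n x 3` Ca coordinates, `n >= 3`.
#' @return list `origin` (centroid) and `direction` (unit 3-vector).
#' @export
strand_axis <- function(ca_xyz) {
  ca_xyz <- as.matrix(ca_xyz)
  if (nrow(ca_xyz) < 3L) stop("strand_axis: need >= 3 ordered Ca positions")
  ctr <- colMeans(ca_xyz)
  dm <- sweep(ca_xyz, 2, ctr)
  cv <- crossprod(dm) / nrow(ca_xyz)
  if (max(abs(cv)) < 1e-12) stop("strand_axis: degenerate geometry (coincident points)")
  ev <- eigen(cv, symmetric = TRUE)
  dir <- ev$vectors[, 1]
  span <- ca_xyz[nrow(ca_xyz), ] - ca_xyz[1, ]
  if (sum(dir * span) < 0) dir <- -dir
  list(origin = ctr, direction = dir / sqrt(sum(dir^2)))
}

.angle_deg <- function(u, v) {
  cu <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cu))) * 180 / pi
}

#' Pocket-geometry descriptors H, alpha and theta
#'
#' Per-frame descriptors of the ligand binding pocket:
#' \describe{
#'   \item{H}{Euclidean distance between the Ca centroids of two loops, e.g.
#'     the CD and DE loops of the receptor's membrane-distal domain.}
#'   \item{alpha}{angle between a strand axis ([strand_axis]) and the line
#'     from one reference Ca to another (e.g. GLN52 to LYS53).}
#'   \item{theta}{angle between two oriented strand axes on opposite sides of
#'     the interface (e.g. the ligand G strand and receptor C strand).}
#' }
#' All angles are reported in degrees within `[0, 180]` using oriented (N to
#' C) axes; `oriented = FALSE` folds values into `[0, 90]`.
#'
#' @param traj [md_trajectory].
#' @param sel_a,sel_b atom index vectors for the two loops (H) or strands
#'   (theta), in residue order for strands.
#' @return numeric vector per frame (A for H, degrees for angles).
#' @export
metric_H <- function(traj, sel_a, sel_b) {
  if (length(sel_a) == 0L || length(sel_b) == 0L) stop("metric_H: empty selection")
  vapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_coords(traj, f)
    sqrt(sum((centroid(m[sel_a, , drop = FALSE]) -
              centroid(m[sel_b, , drop = FALSE]))^2))
  }, numeric(1))
}

#' @rdname metric_H
#' @param strand_sel ordered Ca indices of the strand.
#' @param atom_a,atom_b single atom indices defining the reference line (a to b).
#' @export
metric_alpha <- function(traj, strand_sel, atom_a, atom_b) {
  if (atom_a == atom_b) stop("metric_alpha: atom_a and atom_b coincide")
  vapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_coords(traj, f)
    ab <- m[atom_b, ] - m[atom_a, ]
    if (sum(ab^2) < 1e-20) stop("metric_alpha: coincident reference atoms")
    .angle_deg(strand_axis(m[strand_sel, , drop = FALSE])$direction, ab)
  }, numeric(1))
}

#' @rdname metric_H
#' @param oriented use oriented N-to-C axes (default); otherwise angles fold
#'   into `[0, 90]`.
#' @export
metric_theta <- function(traj, sel_a, sel_b, oriented = TRUE) {
  if (length(sel_a) < 3L || length(sel_b) < 3L) {
    stop("metric_theta: each strand needs >= 3 Ca atoms")
  }
  vapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_coords(traj, f)
    ang <- .angle_deg(strand_axis(m[sel_a, , drop = FALSE])$direction,
                      strand_axis(m[sel_b, , drop = FALSE])$direction)
    if (!oriented && ang > 90) ang <- 180 - ang
    ang
  }, numeric(1))
}
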