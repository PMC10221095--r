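#' Structure, trajectory and force-trace containers
#'
#' `md_structure()` builds the atom-table container used everywhere in the
#' package: a data frame of atoms (serial, name, element, res_name, res_seq,
#' chain_id, x, y, z, mass, charge, vdw_radius).  Non-standard residues such
#' as pyroglutamate (PCA) are carried like any other residue.
#'
#' @param atoms data frame with at least columns `name`, `element`,
#'   `res_name`, `res_seq`, `chain_id`, `x`, `y`, `z`.  `serial`, `mass`,
#'   `charge` and `vdw_radius` are filled with defaults when absent
#'   (mass/radius from the element table).
#' @return an object of class `md_structure`.
#' @export
md_structure <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  if (nrow(atoms) == 0L) stop("md_structure: a structure needs at least one atom")
  need <- c("name", "element", "res_name", "res_seq", "chain_id", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("md_structure: missing atom columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  if (is.null(atoms$vdw_radius)) atoms$vdw_radius <- element_vdw_radius(atoms$element)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("md_structure: non-finite coordinates")
  if (any(!is.na(atoms$mass) & atoms$mass <= 0)) stop("md_structure: mass must be > 0")
  key <- paste(atoms$chain_id, atoms$res_seq, atoms$name)
  if (anyDuplicated(key)) {
    stop("md_structure: duplicated (chain, res_seq, atom name): ",
         key[which(duplicated(key))[1L]])
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "md_structure")
}

#' @rdname md_structure
#' @param x an `md_structure` or `md_trajectory`.
#' @export
coords <- function(x) UseMethod("coords")

#' @export
coords.md_structure <- function(x) {
  m <- as.matrix(x$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' @export
coords.md_trajectory <- function(x) x$coords

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf("md_structure: %d atoms, chains %s\n", nrow(x$atoms),
              paste(sort(unique(x$atoms$chain_id)), collapse = ",")))
  invisible(x)
}

#' @rdname md_structure
#' @export
chain_ids <- function(x) sort(unique(x$atoms$chain_id))

#' Multi-frame coordinate trajectory
#'
#' A trajectory is a topology (`md_structure`) plus an `n_frames x n_atoms x 3`
#' coordinate array in A and a strictly increasing time vector in ns.
#'
#' @param structure an [md_structure] giving the shared atom table.
#' @param coords array `n_frames x n_atoms x 3` (A); a single `n_atoms x 3`
#'   matrix is promoted to one frame.
#' @param times frame times in ns; defaults to `0:(n_frames-1)`.
#' @return object of class `md_trajectory`.
#' @export
md_trajectory <- function(structure, coords, times = NULL) {
  stopifnot(inherits(structure, "md_structure"))
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, nrow(coords), 3L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  na <- nrow(structure$atoms)
  if (dim(coords)[2] != na) {
    stop(sprintf("md_trajectory: frames carry %d atoms but topology has %d",
                 dim(coords)[2], na))
  }
  nf <- dim(coords)[1]
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1L)
  if (length(times) != nf) stop("md_trajectory: times length != n_frames")
  if (nf > 1L && any(diff(times) <= 0)) stop("md_trajectory: times must be strictly increasing")
  structure(list(structure = structure, coords = coords, times = times),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames x %d atoms, t = %.4g..%.4g ns\n",
              n_frames(x), nrow(x$structure$atoms), min(x$times), max(x$times)))
  invisible(x)
}

#' @rdname md_trajectory
#' @param traj an `md_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname md_trajectory
#' @param i frame index.
#' @export
frame_coords <- function(traj, i) {
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  m
}

#' Applied-force time series from a pulling run
#'
#' Holds the spring force (signed projection on the pulling direction, pN),
#' the dummy-atom and steered-atom positions along the pulling axis (A) and a
#' per-sample protocol phase, `"ramp"` or `"clamp"`.  The phase may switch at
#' most once, ramp to clamp.
#'
#' @param time_ns,force_pN,dummy_A,steered_A numeric vectors of equal length.
#' @param phase character vector in `c("ramp","clamp")`.
#' @return data frame of class `force_trace`.
#' @export
force_trace <- function(time_ns, force_pN, dummy_A, steered_A,
                        phase = rep("ramp", length(time_ns))) {
  n <- length(time_ns)
  if (n == 0L) stop("force_trace: empty trace")
  stopifnot(length(force_pN) == n, length(dummy_A) == n,
            length(steered_A) == n, length(phase) == n)
  if (n > 1L && any(diff(time_ns) <= 0)) stop("force_trace: times must be strictly increasing")
  if (!all(phase %in% c("ramp", "clamp"))) stop("force_trace: phase must be 'ramp' or 'clamp'")
  sw <- which(phase[-1] != phase[-n])
  if (length(sw) > 1L || (length(sw) == 1L && phase[1] != "ramp")) {
    stop("force_trace: phase may change at most once, ramp -> clamp")
  }
  out <- data.frame(time_ns = time_ns, force_pN = force_pN, dummy_A = dummy_A,
                    steered_A = steered_A, phase = phase,
                    stringsAsFactors = FALSE)
  class(out) <- c("force_trace", "data.frame")
  out
}

#' @rdname force_trace
#' @param path CSV path with header `time_ns, force_pN, dummy_A, steered_A, phase`.
#' @export
read_force_trace <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_ns", "force_pN", "dummy_A", "steered_A", "phase")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("read_force_trace: missing columns: ", paste(miss, collapse = ", "))
  force_trace(d$time_ns, d$force_pN, d$dummy_A, d$steered_A, d$phase)
}

#' @rdname force_trace
#' @param trace a `force_trace`.
#' @export
write_force_trace <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- element tables ---------------------------------------------------------

.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                     P = 30.974, FE = 55.845, ZN = 65.38, NA. = 22.990,
                     MG = 24.305, CL = 35.45, K = 39.098, CA = 40.078)

# Bondi-style van der Waals radii (A); used for SASA when the atom table has
# no explicit radius.
.element_vdw <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                  FE = 1.80, ZN = 1.39, NA. = 2.27, MG = 1.73, CL = 1.75,
                  K = 2.75, CA = 2.31)

.norm_element <- function(element) {
  e <- toupper(trimws(element))
  e[e == "NA"] <- "NA."
  e
}

#' Element lookups
#'
#' Atomic mass (amu) and van der Waals radius (A) by element symbol; unknown
#' elements fall back to carbon values with a warning.
#' @param element character vector of element symbols.
#' @export
element_mass <- function(element) {
  e <- .norm_element(element)
  m <- .element_masses[e]
  if (anyNA(m)) {
    warning("element_mass: unknown element(s) ",
            paste(unique(element[is.na(m)]), collapse = ","), "; using carbon mass")
    m[is.na(m)] <- .element_masses[["C"]]
  }
  unname(m)
}

#' @rdname element_mass
#' @export
element_vdw_radius <- function(element) {
  e <- .norm_element(element)
  r <- .element_vdw[e]
  if (anyNA(r)) {
    warning("element_vdw_radius: unknown element(s) ",
            paste(unique(element[is.na(r)]), collapse = ","), "; using carbon radius")
    r[is.na(r)] <- .element_vdw[["C"]]
  }
  unname(r)
}
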