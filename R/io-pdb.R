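#' Read a PDB file
#'
#' Parses the ATOM/HETATM/MODEL/ENDMDL/TER subset of the fixed-width PDB
#' format.  Coordinates are returned in A.  A file with several MODEL blocks
#' becomes an [md_trajectory] (one frame per model, times 0,1,2,... ns unless
#' overridden downstream); a single-model file becomes an [md_structure].
#' Pyroglutamate (PCA) and other HETATM residues are parsed like standard
#' residues.  When the element columns (77-78) are blank the element is
#' inferred from the atom-name columns.
#'
#' @param path file path.
#' @param model_policy `"all"` (every MODEL becomes a frame, the default) or
#'   `"first"` (only the first model, returned as a structure).
#' @param altloc_policy `"first"` keeps altloc ' ' or 'A' records (default);
#'   `"all"` keeps every alternate location (may violate atom-key uniqueness).
#' @return [md_structure] or [md_trajectory].
#' @export
read_pdb <- function(path, model_policy = c("all", "first"),
                     altloc_policy = c("first", "all")) {
  model_policy <- match.arg(model_policy)
  altloc_policy <- match.arg(altloc_policy)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") | substr(rec, 1, 4) == "ATOM" |
    substr(rec, 1, 6) == "HETATM"
  is_model <- substr(rec, 1, 5) == "MODEL"
  is_endmdl <- substr(rec, 1, 6) == "ENDMDL"
  if (!any(is_atom)) stop("read_pdb: no ATOM/HETATM records in '", path, "'")

  model_of <- cumsum(is_model)
  has_models <- any(is_model)
  if (!has_models) model_of <- rep(1L, length(lines)) else model_of[model_of == 0L] <- 1L

  idx <- which(is_atom)
  if (model_policy == "first" && has_models) idx <- idx[model_of[idx] == min(model_of[idx])]

  fw <- function(i, a, b) substr(lines[i], a, b)
  serial <- suppressWarnings(as.integer(fw(idx, 7, 11)))
  name <- trimws(fw(idx, 13, 16))
  altloc <- fw(idx, 17, 17)
  res_name <- trimws(fw(idx, 18, 20))
  chain_id <- fw(idx, 22, 22)
  res_seq <- suppressWarnings(as.integer(fw(idx, 23, 26)))
  x <- suppressWarnings(as.numeric(fw(idx, 31, 38)))
  y <- suppressWarnings(as.numeric(fw(idx, 39, 46)))
  z <- suppressWarnings(as.numeric(fw(idx, 47, 54)))
  element <- trimws(fw(idx, 77, 78))

  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(res_seq) | !nzchar(name))
  if (length(bad)) {
    stop(sprintf("read_pdb: malformed fixed-width record at line %d of '%s'",
                 idx[bad[1]], path))
  }
  blank <- !nzchar(element)
  if (any(blank)) element[blank] <- .infer_element(fw(idx[blank], 13, 16))

  keep <- rep(TRUE, length(idx))
  if (altloc_policy == "first") keep <- altloc %in% c(" ", "", "A")
  atoms <- data.frame(serial = serial, name = name, element = element,
                      res_name = res_name, res_seq = res_seq,
                      chain_id = chain_id, x = x, y = y, z = z,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  model_id <- model_of[idx][keep]
  models <- unique(model_id)

  if (length(models) <= 1L) return(md_structure(atoms))

  first <- atoms[model_id == models[1], , drop = FALSE]
  topo <- md_structure(first)
  nf <- length(models)
  na <- nrow(first)
  arr <- array(NA_real_, dim = c(nf, na, 3L))
  for (k in seq_along(models)) {
    fa <- atoms[model_id == models[k], , drop = FALSE]
    if (nrow(fa) != na) {
      stop(sprintf("read_pdb: model %d has %d atoms, expected %d", k, nrow(fa), na))
    }
    arr[k, , ] <- as.matrix(fa[, c("x", "y", "z")])
  }
  md_trajectory(topo, arr, times = as.numeric(seq_len(nf) - 1L))
}

# PDB convention: element occupies name columns 13-14 right-justified; leading
# digits (e.g. "1HB1") mean hydrogen.
.infer_element <- function(name_field) {
  two <- toupper(substr(name_field, 1, 2))
  out <- character(length(name_field))
  known2 <- c("FE", "ZN", "MG", "NA", "CL")
  for (i in seq_along(name_field)) {
    f <- name_field[i]
    if (two[i] %in% known2 && substr(f, 1, 1) != " ") {
      out[i] <- two[i]
    } else {
      ch <- strsplit(gsub("[^A-Za-z]", "", f), "")[[1]]
      out[i] <- if (length(ch)) toupper(ch[1]) else "C"
    }
  }
  out
}

#' Write a PDB file
#'
#' Writes an [md_structure] as a single model or an [md_trajectory] as
#' MODEL/ENDMDL blocks, with TER records at chain boundaries.  Coordinates are
#' written at 3 decimals; a round trip through [read_pdb] preserves atom
#' count, names, chains and coordinates to that precision.
#'
#' @param x [md_structure] or [md_trajectory].
#' @param path output path.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "md_structure")) {
    writeLines(c(.pdb_block(x$atoms, coords(x)), "END"), path)
  } else if (inherits(x, "md_trajectory")) {
    out <- character(0)
    for (f in seq_len(n_frames(x))) {
      out <- c(out, sprintf("MODEL %8d", f),
               .pdb_block(x$structure$atoms, frame_coords(x, f)), "ENDMDL")
    }
    writeLines(c(out, "END"), path)
  } else stop("write_pdb: need an md_structure or md_trajectory")
  invisible(path)
}

.pdb_block <- function(atoms, xyz) {
  if (any(xyz > 9999.999 | xyz < -999.999)) {
    stop("write_pdb: coordinate overflow for fixed-width PDB fields")
  }
  name4 <- ifelse(nchar(atoms$name) >= 4L | nchar(atoms$element) >= 2L,
                  sprintf("%-4s", atoms$name), sprintf(" %-3s", atoms$name))
  lines <- sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   atoms$serial %% 100000L, name4, atoms$res_name, atoms$chain_id,
                   atoms$res_seq, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
                   sprintf("%2s", atoms$element))
  # TER after each chain's last atom
  n <- nrow(atoms)
  ter_after <- which(atoms$chain_id != c(atoms$chain_id[-1], NA_character_))
  ter_after <- c(ter_after[!is.na(ter_after)], n)
  out <- character(0)
  prev <- 0L
  for (t in unique(ter_after)) {
    out <- c(out, lines[(prev + 1L):t], "TER")
    prev <- t
  }
  out
}

#' Read/write multi-frame XYZ trajectories
#'
#' Standard XYZ blocks: an atom-count line, a comment line (`t= <ns>` is
#' recognised for frame times), then `element x y z` rows.  The atom table is
#' supplied separately since XYZ carries no residue/chain information.
#'
#' @param path file path.
#' @param structure [md_structure] topology whose atom count every frame must
#'   match.
#' @return [md_trajectory].
#' @export
read_xyz_traj <- function(path, structure) {
  stopifnot(inherits(structure, "md_structure"))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) == 0L) stop("read_xyz_traj: empty file '", path, "'")
  na <- nrow(structure$atoms)
  frames <- list()
  times <- numeric(0)
  i <- 1L
  while (i <= length(lines)) {
    cnt <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(cnt)) stop("read_xyz_traj: bad atom-count line at ", i)
    if (cnt != na) {
      stop(sprintf("read_xyz_traj: frame at line %d has %d atoms, topology has %d",
                   i, cnt, na))
    }
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexec("t=\\s*([-0-9.eE+]+)", comment))[[1]]
    times <- c(times, if (length(tm) == 2L) as.numeric(tm[2]) else length(frames))
    rows <- lines[(i + 2L):(i + 1L + cnt)]
    parts <- strsplit(trimws(rows), "[[:space:]]+")
    m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(m)) stop("read_xyz_traj: bad coordinate row near line ", i + 2L)
    frames[[length(frames) + 1L]] <- m
    i <- i + 2L + cnt
  }
  arr <- array(NA_real_, dim = c(length(frames), na, 3L))
  for (k in seq_along(frames)) arr[k, , ] <- frames[[k]]
  md_trajectory(structure, arr, times = times)
}

#' @rdname read_xyz_traj
#' @param traj [md_trajectory] to write.
#' @export
write_xyz_traj <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  el <- traj$structure$atoms$element
  out <- character(0)
  for (f in seq_len(n_frames(traj))) {
    m <- frame_coords(traj, f)
    out <- c(out, as.character(length(el)),
             sprintf("t= %.9g", traj$times[f]),
             sprintf("%-2s %14.6f %14.6f %14.6f", el, m[, 1], m[, 2], m[, 3]))
  }
  writeLines(out, path)
  invisible(path)
}
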