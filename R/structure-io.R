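# Structure input/output and atom bookkeeping.  PDB parsing, writing and
# rigid-body fitting are delegated to bio3d; this layer enforces the
# atom-pairing contract the path computation depends on: both end states
# must contain the same atoms in the same order.

#' Construct a molecular state
#'
#' A molecular state is one equilibrium well minimum: an ordered list of
#' atoms with Cartesian coordinates in Angstrom.  Atom identity is the
#' tuple (chain, residue number, residue name, atom name).
#'
#' @param coords numeric N x 3 matrix of coordinates (Angstrom).
#' @param chain,resno,resid,elety per-atom chain id, residue number,
#'   residue name and atom name (recycled if length 1).
#' @param label free-text label (e.g. `"Pre-TS"`).
#' @return an object of class `molecular_state` with elements `coords`,
#'   `atoms` (a data frame) and `label`.
#' @export
molecular_state <- function(coords, chain = "A", resno = seq_len(nrow(coords)),
                            resid = "GLY", elety = "CA", label = "") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  n <- nrow(coords)
  if (n < 2L) stop("a molecular state needs at least 2 atoms")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  atoms <- data.frame(
    chain = rep_len(as.character(chain), n),
    resno = rep_len(as.integer(resno), n),
    resid = rep_len(as.character(resid), n),
    elety = rep_len(as.character(elety), n),
    stringsAsFactors = FALSE
  )
  ids <- atom_ids_internal(atoms)
  if (anyDuplicated(ids)) {
    stop("duplicate atom identifiers: ", paste(ids[duplicated(ids)][1:min(3, sum(duplicated(ids)))], collapse = ", "))
  }
  structure(list(coords = coords, atoms = atoms, label = label),
            class = "molecular_state")
}

#' @export
print.molecular_state <- function(x, ...) {
  cat(sprintf("molecular_state: %d atoms%s\n", nrow(x$coords),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

# pairing key: (chain, residue number, atom name)
pairing_key <- function(atoms) paste(atoms$chain, atoms$resno, atoms$elety, sep = ":")

atom_ids_internal <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$resid, atoms$elety, sep = ":")
}

#' Atom identifiers of a state
#' @param state a `molecular_state`.
#' @return character vector `chain:resno:resid:elety`, in atom order.
#' @export
atom_ids <- function(state) atom_ids_internal(state$atoms)

#' Number of atoms in a state
#' @param state a `molecular_state`.
#' @return integer atom count.
#' @export
n_atoms <- function(state) nrow(state$coords)

is_hydrogen_row <- function(elety, elesy) {
  sy <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  ifelse(sy != "", sy == "H" | sy == "D",
         grepl("^[0-9]*[HD]", trimws(toupper(elety))))
}

#' Read a structure from a PDB file
#'
#' Parses the first model of a PDB file into a [molecular_state()].
#' Hydrogens are always discarded (the elastic network uses heavy atoms
#' only), and for atoms with alternate locations only the
#' highest-occupancy conformer is kept so the Hessian sees a single,
#' deterministic set of coordinates.
#'
#' @param file path to a PDB file.
#' @param atoms `"heavy"` (all non-hydrogen atoms, the default) or
#'   `"calpha"` (one CA atom per residue).
#' @param residue_range optional residue filter, either a string
#'   `"CHAIN:FIRST-LAST"` (e.g. `"A:703-788"`) or a list with elements
#'   `chain`, `first`, `last`.  `chain` may be `NA` to match any chain.
#' @param label label stored on the returned state (defaults to the file
#'   name).
#' @return a `molecular_state`.
#' @export
read_structure <- function(file, atoms = c("heavy", "calpha"),
                           residue_range = NULL, label = basename(file)) {
  atoms <- match.arg(atoms)
  pdb <- tryCatch(bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) stop("unreadable PDB source '", file, "': ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  # resolve alternate locations: keep the highest-occupancy conformer
  alt <- ifelse(is.na(at$alt) | at$alt == "", " ", at$alt)
  if (any(alt != " ")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = ":")
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      best <- idx[which.max(occ[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
    at <- at[keep, , drop = FALSE]
  }
  at <- at[!is_hydrogen_row(at$elety, at$elesy), , drop = FALSE]
  if (atoms == "calpha") {
    at <- at[at$type == "ATOM" & trimws(at$elety) == "CA", , drop = FALSE]
  }
  if (!is.null(residue_range)) {
    rr <- parse_residue_range(residue_range)
    sel <- at$resno >= rr$first & at$resno <= rr$last
    if (!is.na(rr$chain)) sel <- sel & at$chain == rr$chain
    at <- at[sel, , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("no atoms remain after filtering")
  if (atoms == "calpha") {
    per_res <- table(paste(at$chain, at$resno, at$insert, sep = ":"))
    if (any(per_res != 1L)) stop("calpha filter did not yield one atom per residue")
  }
  molecular_state(cbind(at$x, at$y, at$z), chain = at$chain, resno = at$resno,
                  resid = at$resid, elety = trimws(at$elety), label = label)
}

parse_residue_range <- function(residue_range) {
  if (is.character(residue_range)) {
    m <- regmatches(residue_range,
                    regexec("^(?:([A-Za-z0-9]):)?(-?[0-9]+)-(-?[0-9]+)$", residue_range))[[1]]
    if (length(m) == 0L) stop("residue_range must look like 'A:703-788' or '703-788'")
    list(chain = if (m[2] == "") NA_character_ else m[2],
         first = as.integer(m[3]), last = as.integer(m[4]))
  } else {
    list(chain = if (is.null(residue_range$chain)) NA_character_ else residue_range$chain,
         first = as.integer(residue_range$first), last = as.integer(residue_range$last))
  }
}

#' Write a state to a PDB file
#'
#' @param state a `molecular_state`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_structure <- function(state, file) {
  n <- n_atoms(state)
  bio3d::write.pdb(file = file, xyz = coords_to_vec(state$coords),
                   resno = state$atoms$resno, resid = state$atoms$resid,
                   elety = state$atoms$elety, chain = state$atoms$chain,
                   eleno = seq_len(n), o = rep(1, n), b = rep(0, n))
  invisible(file)
}

#' Pair the atoms of two states
#'
#' Pairing succeeds only when the two states contain the same atoms
#' (keyed by chain, residue number and atom name) in the same order; no
#' reordering is attempted, since silent reordering can hide genuinely
#' different atoms.  Failures are reported, never repaired.
#'
#' @param a,b `molecular_state` objects.
#' @return an `atom_pairing` object with `valid` (logical), `index_map`
#'   (identity map when valid), `mismatches` (character vector of
#'   unpaired/misordered atom ids) and `order_mismatch`.
#' @export
pair_atoms <- function(a, b) {
  ka <- pairing_key(a$atoms)
  kb <- pairing_key(b$atoms)
  mism <- character(0)
  order_mismatch <- FALSE
  only_a <- setdiff(ka, kb)
  only_b <- setdiff(kb, ka)
  if (length(only_a)) mism <- c(mism, paste0("only in A: ", only_a))
  if (length(only_b)) mism <- c(mism, paste0("only in B: ", only_b))
  if (!length(mism) && length(ka) == length(kb) && !all(ka == kb)) {
    order_mismatch <- TRUE
    bad <- which(ka != kb)
    mism <- paste0("order mismatch at position ", bad,
                   " (A: ", ka[bad], ", B: ", kb[bad], ")")
  }
  valid <- length(mism) == 0L && length(ka) == length(kb)
  structure(list(valid = valid,
                 index_map = if (valid) seq_along(ka) else integer(0),
                 mismatches = mism,
                 order_mismatch = order_mismatch),
            class = "atom_pairing")
}

#' @export
print.atom_pairing <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("atom_pairing: valid bijection over %d atoms\n", length(x$index_map)))
  } else {
    cat(sprintf("atom_pairing: INVALID (%d problems)\n", length(x$mismatches)))
    cat(paste0("  ", utils::head(x$mismatches, 10), collapse = "\n"), "\n")
  }
  invisible(x)
}

stop_if_unpaired <- function(a, b, stage = "computation") {
  p <- pair_atoms(a, b)
  if (!p$valid) {
    stop(stage, ": atom pairing failed; ",
         paste(utils::head(p$mismatches, 5), collapse = "; "), call. = FALSE)
  }
  invisible(p)
}

#' Least-squares rigid-body superposition
#'
#' Rotates and translates `mobile` onto `reference` minimizing the
#' coordinate RMSD over all paired atoms (Kabsch fit, via
#' [bio3d::fit.xyz()]).
#'
#' @param mobile,reference paired `molecular_state` objects.
#' @return a list with `state` (the fitted copy of `mobile`) and `rmsd`
#'   (Angstrom, over all paired atoms).
#' @export
superpose <- function(mobile, reference) {
  stop_if_unpaired(mobile, reference, "superpose")
  n <- n_atoms(mobile)
  if (n < 3L) warning("superposition of fewer than 3 atoms is rotationally degenerate")
  sv <- svd(stats::cov(mobile$coords) + diag(1e-12, 3))
  if (sv$d[2] / max(sv$d[1], .Machine$double.eps) < 1e-10) {
    warning("near-collinear configuration: superposition is degenerate about the axis")
  }
  fixed <- coords_to_vec(reference$coords)
  mob <- coords_to_vec(mobile$coords)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = fixed, mobile = mob,
                   fixed.inds = seq_along(fixed), mobile.inds = seq_along(mob))
  )
  out <- mobile
  out$coords <- vec_to_coords(as.numeric(fitted))
  list(state = out, rmsd = vec_rmsd(as.numeric(fitted), fixed))
}

#' Coordinate RMSD between two paired states
#'
#' @param a,b paired `molecular_state` objects.
#' @param fit superpose `b` onto `a` first?
#' @return RMSD in Angstrom.
#' @export
rmsd_states <- function(a, b, fit = FALSE) {
  stop_if_unpaired(a, b, "rmsd")
  if (fit) b <- superpose(b, a)$state
  vec_rmsd(coords_to_vec(a$coords), coords_to_vec(b$coords))
}

#' Write a trajectory as a multi-model PDB
#'
#' One `MODEL`/`ENDMDL` block per frame, in time order.  Coordinates
#' round-trip through the fixed-width PDB format at 1e-3 Angstrom.
#'
#' @param traj a `path_trajectory` (see [generate_trajectory()]).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  if (!inherits(traj, "path_trajectory")) stop("traj must be a path_trajectory")
  at <- traj$atoms
  n <- nrow(at)
  if (any(ncol(traj$frames) != 3 * n)) {
    stop("inconsistent frame atom sets: frames have ", ncol(traj$frames) / 3,
         " atoms, metadata has ", n)
  }
  bio3d::write.pdb(file = file, xyz = traj$frames,
                   resno = at$resno, resid = at$resid, elety = at$elety,
                   chain = at$chain, eleno = seq_len(n),
                   o = rep(1, n), b = rep(0, n))
  invisible(file)
}

#' Read a multi-model PDB as a frame matrix
#'
#' Reads every model of a (possibly external) trajectory file; frames are
#' returned in file order with nominal times `0, 1, ...` since external
#' trajectories carry no time stamps.
#'
#' @param file path to a multi-model PDB.
#' @param atoms filter passed to [read_structure()] semantics: `"heavy"`
#'   or `"calpha"`.
#' @return a `path_trajectory` whose `branch` labels are `NA`.
#' @export
read_trajectory <- function(file, atoms = c("heavy", "calpha")) {
  atoms <- match.arg(atoms)
  pdb <- bio3d::read.pdb(file, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  keep <- !is_hydrogen_row(at$elety, at$elesy)
  if (atoms == "calpha") keep <- keep & at$type == "ATOM" & trimws(at$elety) == "CA"
  xyz_idx <- as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1, 3 * which(keep)))
  frames <- pdb$xyz[, xyz_idx, drop = FALSE]
  at <- at[keep, , drop = FALSE]
  structure(list(
    times = seq_len(nrow(frames)) - 1,
    frames = unclass(frames),
    branch = rep(NA_character_, nrow(frames)),
    atoms = data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                       elety = trimws(at$elety), stringsAsFactors = FALSE),
    truncation = NULL
  ), class = "path_trajectory")
}

#' Extract one frame of a trajectory as a state
#' @param traj a `path_trajectory`.
#' @param i frame index.
#' @return a `molecular_state`.
#' @export
frame_state <- function(traj, i) {
  molecular_state(vec_to_coords(traj$frames[i, ]), chain = traj$atoms$chain,
                  resno = traj$atoms$resno, resid = traj$atoms$resid,
                  elety = traj$atoms$elety,
                  label = sprintf("frame %d (t = %.4g)", i, traj$times[i]))
}

#' @export
print.path_trajectory <- function(x, ...) {
  cat(sprintf("path_trajectory: %d frames, %d atoms, t in [%.4g, %.4g]\n",
              nrow(x$frames), nrow(x$atoms), min(x$times), max(x$times)))
  if (!is.null(x$truncation)) {
    cat(sprintf("  truncated at fraction %.3g: dropped t-spans %.4g (head), %.4g (tail)\n",
                x$truncation$fraction, x$truncation$head_span, x$truncation$tail_span))
  }
  invisible(x)
}
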