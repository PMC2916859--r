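# Structural-ensemble container, multi-model PDB I/O, atom selection and
# frame windows.  Coordinates are Angstrom throughout; frames are stored in
# the bio3d xyz convention (one row per frame, 3*natoms columns).

#' Construct a structural ensemble
#'
#' @param topology data.frame with columns `serial`, `atom_name`,
#'   `residue_name`, `residue_number`, `chain_id`, `element` (one row per
#'   atom, order defines coordinate order).
#' @param xyz numeric matrix, one row per frame and `3 * natoms` columns
#'   (`x1,y1,z1,x2,...`), or a single frame as a length-`3*natoms` vector.
#' @param time optional numeric vector of frame times (ns).
#' @return object of class `"ensemble"`.
#' @export
ensemble <- function(topology, xyz, time = NULL) {
  req <- c("serial", "atom_name", "residue_name", "residue_number",
           "chain_id", "element")
  missing_cols <- setdiff(req, names(topology))
  if (length(missing_cols) > 0)
    stop("topology lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(topology$serial))
    stop("topology serial numbers must be unique")
  if (any(!nzchar(topology$atom_name)))
    stop("topology atom names must be non-empty")
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * nrow(topology))
    stop(sprintf("coordinate width %d does not match 3 x %d atoms",
                 ncol(xyz), nrow(topology)))
  if (nrow(xyz) < 1L) stop("an ensemble needs at least one frame")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in ensemble")
  structure(list(topology = topology, xyz = xyz, time = time),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("structural ensemble: %d atoms, %d frame%s, chains %s\n",
              n_atoms(x), n_frames(x), if (n_frames(x) == 1) "" else "s",
              paste(sort(unique(x$topology$chain_id)), collapse = ",")))
  invisible(x)
}

#' Number of atoms / frames in an ensemble
#' @param ens an `ensemble`.
#' @return integer.
#' @export
n_atoms <- function(ens) nrow(ens$topology)

#' @rdname n_atoms
#' @export
n_frames <- function(ens) nrow(ens$xyz)

#' Extract one frame as an natoms x 3 coordinate matrix
#' @param ens an `ensemble`.
#' @param i frame index (1-based).
#' @return numeric matrix natoms x 3.
#' @export
frame_coords <- function(ens, i = 1L) {
  if (i < 1L || i > n_frames(ens))
    stop("frame index out of range: ", i)
  matrix(ens$xyz[i, ], ncol = 3, byrow = TRUE)
}

# xyz column indices for atom indices
.xyz_cols <- function(atom_idx) {
  as.vector(rbind(3 * atom_idx - 2, 3 * atom_idx - 1, 3 * atom_idx))
}

# Normalise atom-name prime spellings: C3', C3* and the unicode prime all
# mean the same atom in the wild.
.normalize_atom_name <- function(x) {
  gsub("[*′]", "'", x)
}

#' Select atoms from an ensemble topology
#'
#' Conjunction of the stated predicates; unstated predicates match
#' everything.  Atom names are compared after normalising prime spellings
#' (`'`, `*` and the unicode prime are equivalent).  The result is an
#' ordered (topology-order) integer index vector; empty selections are
#' legal.
#'
#' @param ens an `ensemble`.
#' @param chain_id,residue_number,residue_name,atom_name optional vectors
#'   of admissible values.
#' @return integer vector of atom indices (possibly empty).
#' @examples
#' # sel <- select_atoms(ens, residue_number = 120, atom_name = "NZ")
#' @export
select_atoms <- function(ens, chain_id = NULL, residue_number = NULL,
                         residue_name = NULL, atom_name = NULL) {
  top <- ens$topology
  keep <- rep(TRUE, nrow(top))
  if (!is.null(chain_id)) keep <- keep & top$chain_id %in% chain_id
  if (!is.null(residue_number))
    keep <- keep & top$residue_number %in% residue_number
  if (!is.null(residue_name))
    keep <- keep & top$residue_name %in% residue_name
  if (!is.null(atom_name))
    keep <- keep & .normalize_atom_name(top$atom_name) %in%
      .normalize_atom_name(atom_name)
  which(keep)
}

#' Resolve a frame window to frame indices
#'
#' A window is either a tail fraction of the trajectory (e.g. `2/3` for
#' "the last two thirds") or an explicit inclusive frame range
#' `c(start, end)`.  A fraction `f` resolves to frames
#' `ceil((1-f)*n) + 1 .. n` so that, e.g., `2/3` of 30 frames is frames
#' 11..30 (20 frames).
#'
#' @param ens an `ensemble` (or an integer frame count).
#' @param window numeric scalar in (0, 1] (tail fraction), or
#'   `list(fraction = f)`, or `list(range = c(start, end))` /
#'   length-2 integer vector (1-based inclusive range).
#' @return integer vector of frame indices.
#' @examples
#' resolve_window(30L, 2/3)   # 11:30
#' resolve_window(30L, 1/6)   # 26:30
#' @export
resolve_window <- function(ens, window = 1) {
  n <- if (inherits(ens, "ensemble")) n_frames(ens) else as.integer(ens)
  if (is.list(window)) {
    if (!is.null(window$fraction)) window <- window$fraction
    else if (!is.null(window$range)) window <- window$range
    else stop("window list needs a 'fraction' or 'range' element")
  }
  if (length(window) == 1L) {
    f <- as.numeric(window)
    if (!(f > 0 && f <= 1)) stop("window fraction must be in (0, 1]")
    # small tolerance so fractions like 2/3 of 30 are not pushed up a
    # frame by floating-point representation
    start <- as.integer(ceiling((1 - f) * n - 1e-9)) + 1L
    start <- max(1L, min(start, n))
    idx <- seq.int(start, n)
  } else if (length(window) == 2L) {
    start <- as.integer(window[1]); end <- as.integer(window[2])
    if (start < 1L || end > n || start > end)
      stop(sprintf("empty or out-of-bounds frame range [%d, %d] for %d frames",
                   start, end, n))
    idx <- seq.int(start, end)
  } else stop("window must be a fraction or a length-2 range")
  if (length(idx) == 0) stop("resolved frame window is empty")
  idx
}

# --- multi-model PDB -------------------------------------------------------

# Pre-scan a PDB file: per-model atom counts and identity strings, used to
# produce precise format errors before delegating to the bio3d reader.
.scan_models <- function(lines) {
  model_starts <- grep("^MODEL", lines)
  ids <- function(sel) {
    atom <- grep("^(ATOM  |HETATM)", sel, value = TRUE)
    paste(substr(atom, 13, 27))  # name, altloc, resname, chain, resno, icode
  }
  if (length(model_starts) == 0) return(list(ids(lines)))
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) < length(model_starts))
    model_ends <- c(model_ends, length(lines))
  lapply(seq_along(model_starts), function(i)
    ids(lines[model_starts[i]:model_ends[i]]))
}

#' Read a multi-model PDB file as an ensemble
#'
#' The topology is taken from the first model; every `MODEL`/`ENDMDL`
#' block becomes one frame (a file without `MODEL` records counts as a
#' single frame).  Atom order and identity must be identical across
#' models; a mismatch is reported with the offending model index.
#' Parsing itself is delegated to [bio3d::read.pdb()].
#'
#' @param path PDB file path.
#' @return an `ensemble`.
#' @export
read_multimodel_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  per_model <- .scan_models(lines)
  if (length(per_model) > 1) {
    ref <- per_model[[1]]
    for (i in seq_along(per_model)[-1]) {
      if (length(per_model[[i]]) != length(ref))
        stop(sprintf(
          "model %d has %d atoms but model 1 has %d in '%s'",
          i, length(per_model[[i]]), length(ref), path), call. = FALSE)
      if (!identical(per_model[[i]], ref))
        stop(sprintf("atom identity mismatch between model %d and model 1 in '%s'",
                     i, path), call. = FALSE)
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  top <- data.frame(
    serial = atom$eleno,
    atom_name = .normalize_atom_name(atom$elety),
    residue_name = atom$resid,
    residue_number = atom$resno,
    chain_id = ifelse(is.na(atom$chain), " ", atom$chain),
    element = ifelse(is.na(atom$elesy) | !nzchar(trimws(atom$elesy)),
                     substr(trimws(atom$elety), 1, 1), trimws(atom$elesy)),
    stringsAsFactors = FALSE
  )
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  ensemble(top, unclass(xyz))
}

#' Write an ensemble as a multi-model PDB file
#'
#' Standard fixed-column PDB records, coordinates to 3 decimal places,
#' `MODEL` records numbered from 1; chain identifiers and residue
#' numbering are preserved verbatim.  Delegates to [bio3d::write.pdb()].
#'
#' @param ens an `ensemble`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_multimodel_pdb <- function(ens, path) {
  stopifnot(inherits(ens, "ensemble"))
  top <- ens$topology
  bio3d::write.pdb(pdb = NULL, file = path, xyz = bio3d::as.xyz(ens$xyz),
                   type = rep("ATOM", nrow(top)),
                   eleno = top$serial, elety = top$atom_name,
                   resid = top$residue_name, chain = top$chain_id,
                   resno = top$residue_number,
                   o = rep(1, nrow(top)), b = rep(0, nrow(top)),
                   elesy = top$element)
  invisible(path)
}
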