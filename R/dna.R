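# Ideal B-DNA construction, base-pair reference frames, Watson-Crick
# major-groove acceptor spacing and the helical-axis bend angle.
#
# Base atoms use the standard base-pair reference-frame geometry (planar
# idealized bases, coordinates in the frame whose origin sits on the helix
# axis for an ideal straight duplex).  Backbone atoms (C3', P, O1P, O2P)
# are schematic: placed at B-DNA-like radii so that selections and
# phosphate contacts resolve, but not a full sugar-phosphate model.

# Standard base coordinates (Angstrom) in the base-pair reference frame;
# z = 0 for the planar idealized bases.
.STD_BASE <- list(
  A = rbind(
    "C1'" = c(-2.479, 5.346), N9 = c(-1.291, 4.498), C8 = c(0.024, 4.897),
    N7 = c(0.877, 3.902), C5 = c(0.071, 2.771), C6 = c(0.369, 1.398),
    N6 = c(1.611, 0.909), N1 = c(-0.668, 0.532), C2 = c(-1.912, 1.023),
    N3 = c(-2.320, 2.290), C4 = c(-1.267, 3.124)),
  G = rbind(
    "C1'" = c(-2.477, 5.399), N9 = c(-1.289, 4.551), C8 = c(0.023, 4.962),
    N7 = c(0.870, 3.969), C5 = c(0.071, 2.833), C6 = c(0.424, 1.460),
    O6 = c(1.554, 0.955), N1 = c(-0.700, 0.641), C2 = c(-1.999, 1.087),
    N2 = c(-2.949, 0.139), N3 = c(-2.342, 2.364), C4 = c(-1.265, 3.177)),
  C = rbind(
    "C1'" = c(-2.477, 5.402), N1 = c(-1.285, 4.542), C2 = c(-1.472, 3.158),
    O2 = c(-2.628, 2.709), N3 = c(-0.391, 2.344), C4 = c(0.837, 2.868),
    N4 = c(1.875, 2.027), C5 = c(1.056, 4.275), C6 = c(-0.023, 5.068)),
  T = rbind(
    "C1'" = c(-2.481, 5.354), N1 = c(-1.284, 4.500), C2 = c(-1.462, 3.135),
    O2 = c(-2.562, 2.608), N3 = c(-0.298, 2.407), C4 = c(0.994, 2.897),
    O4 = c(1.944, 2.119), C5 = c(1.106, 4.338), C7 = c(2.466, 4.961),
    C6 = c(-0.024, 5.057))
)

# Schematic backbone atom positions in the same per-base frame.
.STD_BACKBONE <- rbind(
  "C3'" = c(-3.50, 7.00, 1.00),
  P     = c(-3.30, 8.70, 2.00),
  O1P   = c(-4.30, 9.50, 2.30),
  O2P   = c(-2.40, 9.60, 1.40)
)

# Ring atoms used to fit base reference frames (exclude exocyclic
# substituents and C1').
.RING_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  T = c("N1", "C2", "N3", "C4", "C5", "C6")
)

.std_base_coords <- function(base) {
  m <- .STD_BASE[[toupper(base)]]
  cbind(m, z = 0)
}

.rotz <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}

#' Ideal B-form DNA duplex
#'
#' Builds a straight double helix from standard B-form helical parameters
#' (rise 3.38 Angstrom, twist 36 degrees per base pair) and standard
#' planar base geometries, with correct Watson-Crick pairing.  Reference
#' strand is chain `A`, residues 1..n in 5'->3' order; the complementary
#' strand is chain `B`, also numbered 1..n in its own 5'->3' order, so
#' chain B residue j pairs chain A residue n+1-j.  Residue names are
#' `DA/DC/DG/DT`.  Backbone atoms are schematic (see module notes).
#'
#' @param sequence reference-strand sequence (`A,C,G,T`).
#' @param rise,twist helical rise (Angstrom) and twist (degrees) per bp.
#' @return a one-frame `ensemble`.
#' @examples
#' helix <- ideal_bdna("GGGCATGCCC")
#' @export
ideal_bdna <- function(sequence, rise = 3.38, twist = 36) {
  bases <- .check_alphabet(sequence)
  n <- length(bases)
  rows <- list(); coords <- list(); serial <- 0L
  add_nt <- function(chain, resno, base, bp_index, flip) {
    std <- rbind(.std_base_coords(base), .STD_BACKBONE)
    if (flip) std[, 2:3] <- -std[, 2:3]     # complementary strand
    R <- .rotz(twist * (bp_index - 1))
    xyz <- std %*% t(R)
    xyz[, 3] <- xyz[, 3] + rise * (bp_index - 1)
    nm <- rownames(std)
    for (k in seq_along(nm)) {
      serial <<- serial + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        serial = serial, atom_name = nm[k],
        residue_name = paste0("D", base), residue_number = resno,
        chain_id = chain,
        element = substr(sub("^[0-9]*", "", nm[k]), 1, 1),
        stringsAsFactors = FALSE)
      coords[[length(coords) + 1L]] <<- xyz[k, ]
    }
  }
  for (i in seq_len(n)) add_nt("A", i, bases[i], i, flip = FALSE)
  for (j in seq_len(n)) {
    i <- n + 1L - j                      # paired reference residue
    add_nt("B", j, complement_base(bases[i]), i, flip = TRUE)
  }
  top <- do.call(rbind, rows)
  xyz <- matrix(as.numeric(t(do.call(rbind, coords))), nrow = 1)
  ens <- ensemble(top, xyz)
  attr(ens, "sequence") <- paste(bases, collapse = "")
  ens
}

# Fit the standard frame of one base to observed coordinates; returns the
# rotation (columns = frame axes in global coordinates) and origin.
.fit_base_frame <- function(coords, atom_names, base) {
  ring <- .RING_ATOMS[[toupper(base)]]
  std <- .std_base_coords(base)
  keep <- intersect(ring, intersect(rownames(std), atom_names))
  if (length(keep) < 3)
    stop("cannot fit base frame: too few ring atoms for base ", base)
  obs <- coords[match(keep, atom_names), , drop = FALSE]
  sp <- kabsch(std[keep, , drop = FALSE], obs)
  list(rotation = sp$rotation,
       origin = as.numeric(sp$translation), fit_rmsd = sp$rmsd)
}

#' Base-pair reference frames of a duplex frame
#'
#' Fits each paired base's standard geometry to the observed coordinates
#' (least squares over ring atoms), flips the complementary base's frame
#' (y and z axes negated), and averages the two into the base-pair frame:
#' mid-point origin and the rotation closest (in the least-squares sense)
#' to the mean of the two rotations.
#'
#' @param ens a (typically one-frame) `ensemble` containing the duplex.
#' @param frame frame index (default 1).
#' @param ref_chain,comp_chain chain ids (defaults `A`, `B`).
#' @return list per base pair: `origin` (length-3), `rotation` (3 x 3,
#'   columns x/y/z axes), `ref_resno`, `bases`.
#' @export
base_pair_frames <- function(ens, frame = 1L, ref_chain = "A",
                             comp_chain = "B") {
  fr <- frame_coords(ens, frame)
  top <- ens$topology
  ref_res <- sort(unique(top$residue_number[top$chain_id == ref_chain]))
  comp_res <- sort(unique(top$residue_number[top$chain_id == comp_chain]))
  n <- length(ref_res)
  if (length(comp_res) != n)
    stop("reference and complementary strands have different lengths")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    r_ref <- ref_res[i]; r_comp <- comp_res[n + 1L - i]
    fb <- function(chain, resno) {
      idx <- select_atoms(ens, chain_id = chain, residue_number = resno)
      base <- sub("^D", "", unique(top$residue_name[idx])[1])
      f <- .fit_base_frame(fr[idx, , drop = FALSE],
                           .normalize_atom_name(top$atom_name[idx]), base)
      f$base <- base
      f
    }
    f1 <- fb(ref_chain, r_ref)
    f2 <- fb(comp_chain, r_comp)
    R2f <- f2$rotation %*% diag(c(1, -1, -1))
    M <- (f1$rotation + R2f) / 2
    sv <- svd(M)
    R <- sv$u %*% t(sv$v)
    if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
    out[[i]] <- list(origin = (f1$origin + f2$origin) / 2, rotation = R,
                     ref_resno = r_ref, bases = c(f1$base, f2$base))
  }
  out
}

#' Helical twist between successive base pairs
#'
#' Extracts the rotation about the local helical axis between successive
#' base-pair frames.
#'
#' @param frames list from [base_pair_frames()].
#' @return numeric vector of length `n - 1` (degrees).
#' @export
helical_twist <- function(frames) {
  n <- length(frames)
  if (n < 2) stop("need at least two base-pair frames")
  vapply(seq_len(n - 1), function(i) {
    A <- t(frames[[i]]$rotation) %*% frames[[i + 1]]$rotation
    atan2(A[2, 1] - A[1, 2], A[1, 1] + A[2, 2]) * 180 / pi
  }, numeric(1))
}

#' Major-groove acceptor spacing of a Watson-Crick base pair
#'
#' Distance between the two major-groove hydrogen-bond acceptor atoms of
#' one base pair: for A-T, purine N7 and thymine O4 (the spacing that
#' prevents a single donor bridging both); for G-C, guanine O6 and N7
#' (same base, much closer, enabling the three-centered bond).
#'
#' @param ens duplex `ensemble` (e.g. from [ideal_bdna()]).
#' @param ref_resno reference-strand residue number of the pair.
#' @param frame frame index (default 1).
#' @param ref_chain,comp_chain chain ids.
#' @return distance in Angstrom.
#' @examples
#' d <- wc_acceptor_spacing(ideal_bdna("GGAGG"), ref_resno = 3)  # A.T pair
#' @export
wc_acceptor_spacing <- function(ens, ref_resno, frame = 1L,
                                ref_chain = "A", comp_chain = "B") {
  top <- ens$topology
  n <- length(unique(top$residue_number[top$chain_id == ref_chain]))
  comp_resno <- n + 1L - ref_resno
  ref_idx <- select_atoms(ens, chain_id = ref_chain,
                          residue_number = ref_resno)
  comp_idx <- select_atoms(ens, chain_id = comp_chain,
                           residue_number = comp_resno)
  if (length(ref_idx) == 0 || length(comp_idx) == 0)
    stop("base pair not found at reference residue ", ref_resno)
  base_of <- function(idx) sub("^D", "", unique(top$residue_name[idx])[1])
  b1 <- base_of(ref_idx); b2 <- base_of(comp_idx)
  fr <- frame_coords(ens, frame)
  atom_at <- function(idx, name) {
    j <- idx[.normalize_atom_name(top$atom_name[idx]) == name]
    if (length(j) == 0)
      stop("missing atom ", name, " in base ", base_of(idx))
    fr[j[1], ]
  }
  pair <- sort(c(b1, b2))
  if (identical(pair, c("A", "T"))) {
    pur_idx <- if (b1 == "A") ref_idx else comp_idx
    thy_idx <- if (b1 == "T") ref_idx else comp_idx
    p1 <- atom_at(pur_idx, "N7"); p2 <- atom_at(thy_idx, "O4")
  } else if (identical(pair, c("C", "G"))) {
    g_idx <- if (b1 == "G") ref_idx else comp_idx
    p1 <- atom_at(g_idx, "O6"); p2 <- atom_at(g_idx, "N7")
  } else stop("not a Watson-Crick pair: ", b1, "-", b2)
  sqrt(sum((p1 - p2)^2))
}

# Principal axis (first PC direction) of a set of points, oriented so it
# points from the first toward the last point.
.principal_axis <- function(pts) {
  pts <- as.matrix(pts)
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  sv <- svd(X)
  v <- sv$v[, 1]
  span <- pts[nrow(pts), ] - pts[1, ]
  if (sum(v * span) < 0) v <- -v
  list(axis = v, center = ctr, spread = sv$d)
}

#' DNA bend angle over a base-pair segment
#'
#' A transparent axis-segment bend metric (not the Curves curvilinear
#' axis): straight helical axes are fitted as the principal axis of the
#' base-pair origins of the first and last `ceil(n/3)` pairs of the
#' segment, both oriented 5'->3'; the bend is the angle between the two
#' axis vectors.  Degenerate (near-coincident-origin) terminal segments
#' are reported as 0 with a flag.
#'
#' @param ens duplex `ensemble`.
#' @param frame frame index (default 1).
#' @param segment optional integer vector of reference-strand residue
#'   numbers defining the segment (default: all pairs).
#' @param terminal_bp number of base pairs in each terminal fit segment;
#'   default `ceiling(n/3)`.
#' @param ref_chain,comp_chain chain ids.
#' @return list of class `"bend_result"`: `angle` (degrees, \[0, 180\]),
#'   `axis_5p`, `axis_3p`, `n_bp`, `degenerate`.
#' @export
bend_angle <- function(ens, frame = 1L, segment = NULL, terminal_bp = NULL,
                       ref_chain = "A", comp_chain = "B") {
  bpf <- base_pair_frames(ens, frame, ref_chain, comp_chain)
  resnos <- vapply(bpf, `[[`, numeric(1), "ref_resno")
  if (!is.null(segment)) bpf <- bpf[resnos %in% segment]
  n <- length(bpf)
  if (n < 8) stop("bend angle needs at least 8 base pairs, got ", n)
  if (is.null(terminal_bp)) terminal_bp <- ceiling(n / 3)
  origins <- t(vapply(bpf, `[[`, numeric(3), "origin"))
  a5 <- .principal_axis(origins[seq_len(terminal_bp), , drop = FALSE])
  a3 <- .principal_axis(origins[seq(n - terminal_bp + 1, n), , drop = FALSE])
  degenerate <- a5$spread[1] < 1e-6 || a3$spread[1] < 1e-6
  ang <- if (degenerate) 0 else {
    cs <- sum(a5$axis * a3$axis)
    acos(max(-1, min(1, cs))) * 180 / pi
  }
  structure(list(angle = ang, axis_5p = a5$axis, axis_3p = a3$axis,
                 n_bp = n, degenerate = degenerate),
            class = "bend_result")
}

#' Per-frame bend angles over a window
#'
#' @inheritParams bend_angle
#' @param window frame window (see [resolve_window()]).
#' @return data.frame with `frame` and `bend` (degrees).
#' @export
bend_series <- function(ens, window = 1, segment = NULL, terminal_bp = NULL,
                        ref_chain = "A", comp_chain = "B") {
  idx <- resolve_window(ens, window)
  vals <- vapply(idx, function(i)
    bend_angle(ens, i, segment, terminal_bp, ref_chain, comp_chain)$angle,
    numeric(1))
  data.frame(frame = idx, bend = vals)
}
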