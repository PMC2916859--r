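# Least-squares superposition (Kabsch), RMSD/RMSF, average structures and
# the organizational angle/dihedral descriptors.

#' Optimal least-squares superposition (Kabsch)
#'
#' Computes the rotation and translation minimising the (optionally
#' weighted) RMSD between paired coordinate sets, by singular value
#' decomposition of the covariance matrix with the standard determinant
#' correction so the result is a proper rotation (det = +1).
#'
#' The fitted transform maps mobile coordinates onto the reference as
#' `t(R %*% (x - mobile_center)) + reference_center`; use
#' [apply_superposition()] to apply it.
#'
#' @param mobile,reference n x 3 coordinate matrices (paired rows, n >= 3).
#' @param weights optional non-negative per-atom weights.
#' @return list of class `"superposition"` with `rotation` (3 x 3),
#'   `translation` (so that `x %*% t(rotation) + translation` maps mobile
#'   onto reference), `rmsd` (Angstrom, after transform) and the centers.
#' @examples
#' x <- matrix(rnorm(15), ncol = 3)
#' kabsch(x, x)$rmsd   # 0
#' @export
kabsch <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3 || ncol(reference) != 3 ||
      nrow(mobile) != nrow(reference))
    stop("superposition error: need paired n x 3 coordinate matrices")
  n <- nrow(mobile)
  if (n < 3) stop("superposition error: need at least 3 atom pairs")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0)
    stop("superposition error: invalid weights")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  X <- sweep(mobile, 2, cm)
  Y <- sweep(reference, 2, cr)
  H <- t(X * w) %*% Y
  sv <- svd(H)
  if (sv$d[2] < 1e-12)
    stop("superposition error: degenerate (collinear or coincident) geometry")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- X %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Y)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cr - (cm %*% t(R))),
                 rmsd = rmsd,
                 mobile_center = cm, reference_center = cr),
            class = "superposition")
}

#' Apply a fitted superposition to coordinates
#'
#' @param coords n x 3 matrix.
#' @param sp a `"superposition"` from [kabsch()].
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(coords, sp) {
  sweep(as.matrix(coords) %*% t(sp$rotation), 2, sp$translation, "+")
}

#' Root-mean-square deviation between paired coordinate sets
#'
#' Plain (un-superposed) RMSD; superpose first if a fit is wanted.
#'
#' @param a,b n x 3 matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd_coords <- function(a, b) {
  sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
}

#' Per-frame RMSD series after superposition
#'
#' For every frame: superpose onto the reference frame using the fit
#' selection, then report the un-weighted RMSD over the measure
#' selection.  This is the scheme used for side-chain deviation profiles
#' (fit on the monomer backbone, measure on a named side chain).
#'
#' @param ens an `ensemble`.
#' @param fit_sel,measure_sel integer atom-index vectors (see
#'   [select_atoms()]); `measure_sel` defaults to `fit_sel`.
#' @param reference_frame index of the reference frame (default 1).
#' @return data.frame with `frame` and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(ens, fit_sel, measure_sel = fit_sel,
                        reference_frame = 1L) {
  stopifnot(inherits(ens, "ensemble"))
  if (length(fit_sel) < 3) stop("superposition error: fit selection too small")
  if (length(measure_sel) < 1) stop("empty measure selection")
  ref <- frame_coords(ens, reference_frame)
  out <- numeric(n_frames(ens))
  for (i in seq_len(n_frames(ens))) {
    fr <- frame_coords(ens, i)
    sp <- kabsch(fr[fit_sel, , drop = FALSE], ref[fit_sel, , drop = FALSE])
    moved <- apply_superposition(fr[measure_sel, , drop = FALSE], sp)
    out[i] <- rmsd_coords(moved, ref[measure_sel, , drop = FALSE])
  }
  data.frame(frame = seq_len(n_frames(ens)), rmsd = out)
}

# Superpose every window frame of `ens` onto a reference frame using
# fit_sel; returns a list of natoms x 3 matrices (all atoms transformed).
.fitted_frames <- function(ens, fit_sel, window_idx, ref_coords = NULL) {
  if (is.null(ref_coords)) ref_coords <- frame_coords(ens, window_idx[1])
  lapply(window_idx, function(i) {
    fr <- frame_coords(ens, i)
    if (is.null(fit_sel)) return(fr)
    sp <- kabsch(fr[fit_sel, , drop = FALSE],
                 ref_coords[fit_sel, , drop = FALSE])
    apply_superposition(fr, sp)
  })
}

#' Average structure over a frame window
#'
#' Superposes each window frame onto the first window frame via the fit
#' selection, then takes the arithmetic mean of all coordinates.
#'
#' @param ens an `ensemble`.
#' @param window frame window (see [resolve_window()]); default whole
#'   trajectory.
#' @param fit_sel atom indices used for the superposition; `NULL` skips
#'   fitting (frames already share a common frame of reference).
#' @return natoms x 3 coordinate matrix.
#' @export
average_structure <- function(ens, window = 1, fit_sel = NULL) {
  idx <- resolve_window(ens, window)
  frames <- .fitted_frames(ens, fit_sel, idx)
  Reduce(`+`, frames) / length(frames)
}

#' Per-residue RMS fluctuation profile
#'
#' Superposes each window frame (fit selection) and computes, for every
#' selected atom, the root-mean-square deviation from the reference —
#' by default the windowed mean structure (the standard RMSF); a
#' deviation-from-initial-structure mode is available since published
#' fluctuation plots are sometimes computed that way.  Atom values are
#' averaged within residues.
#'
#' @param ens an `ensemble`.
#' @param sel atom indices to profile.
#' @param window frame window; default the trajectory tail sixth used for
#'   fluctuation analyses.
#' @param fit_sel atom indices for the superposition; defaults to `sel`;
#'   `NULL` skips fitting.
#' @param reference `"mean"` (default) or `"initial"` (first window
#'   frame).
#' @return data.frame: `chain_id`, `residue_number`, `rmsf` (Angstrom),
#'   with attribute `"atom_rmsf"` carrying the per-atom values.
#' @export
rmsf_profile <- function(ens, sel, window = 1 / 6, fit_sel = sel,
                         reference = c("mean", "initial")) {
  reference <- match.arg(reference)
  idx <- resolve_window(ens, window)
  frames <- .fitted_frames(ens, fit_sel, idx)
  stack <- lapply(frames, function(fr) fr[sel, , drop = FALSE])
  ref <- if (reference == "mean") Reduce(`+`, stack) / length(stack)
         else stack[[1]]
  msd <- Reduce(`+`, lapply(stack, function(fr) rowSums((fr - ref)^2))) /
    length(stack)
  atom_rmsf <- sqrt(msd)
  top <- ens$topology[sel, , drop = FALSE]
  key <- paste(top$chain_id, top$residue_number)
  agg <- tapply(atom_rmsf, key, mean)
  first <- !duplicated(key)
  out <- data.frame(chain_id = top$chain_id[first],
                    residue_number = top$residue_number[first],
                    stringsAsFactors = FALSE)
  out$rmsf <- as.numeric(agg[paste(out$chain_id, out$residue_number)])
  out <- out[order(out$chain_id, out$residue_number), ]
  rownames(out) <- NULL
  attr(out, "atom_rmsf") <- atom_rmsf
  out
}

# --- angles and dihedrals --------------------------------------------------

#' Angle defined by three points
#'
#' @param a,b,c numeric length-3 vectors; the angle is at vertex `b`.
#' @return angle in degrees, in \[0, 180\].
#' @export
vector_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  cs <- max(-1, min(1, cs))
  acos(cs) * 180 / pi
}

#' Dihedral angle defined by four points
#'
#' IUPAC sign convention: looking down the b->c axis, a clockwise rotation
#' of the far bond is positive; the cis arrangement is 0 degrees.
#'
#' @param a,b,c,d numeric length-3 vectors.
#' @return angle in degrees, in (-180, 180\].
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Organizational angle/dihedral descriptor for a quarter site
#'
#' The descriptor of core-domain orientation relative to the DNA: the
#' angle between Calpha(Ser269), Calpha(Gly112) and the DNA C3' atom at
#' quarter-site position 0 (the base pair 5'-adjacent to local position
#' 1), and the dihedral adding the C3' atom at position 4'.  Reported
#' per frame over the window, as window means, and as evaluated on the
#' window-average structure (the convention used when such descriptors
#' are tabulated for time-averaged structures).
#'
#' @param ens an `ensemble`.
#' @param map a `p53_mapping`.
#' @param quarter quarter-site name present in `map$quarters`.
#' @param window frame window; default the trajectory tail sixth.
#' @return list with `series` (data.frame: frame, angle, dihedral),
#'   `mean_angle`, `mean_dihedral`, `avg_structure_angle`,
#'   `avg_structure_dihedral` (all degrees).
#' @export
org_geometry <- function(ens, map, quarter, window = 1 / 6) {
  qmap <- map$quarters[[quarter]]
  if (is.null(qmap)) stop("quarter not present in mapping: ", quarter)
  i269 <- .resolve_residue(ens, qmap, qmap$residues$ser269, "CA",
                           paste0(quarter, " Ser269 CA"))
  i112 <- .resolve_residue(ens, qmap, qmap$residues$gly112, "CA",
                           paste0(quarter, " Gly112 CA"))
  i0 <- .resolve_site(ens, qmap$org_anchors$p0_c3, "C3'",
                      paste0(quarter, " position-0 C3'"))
  i4 <- .resolve_site(ens, qmap$org_anchors$p4prime_c3, "C3'",
                      paste0(quarter, " position-4' C3'"))
  idx <- resolve_window(ens, window)
  ang <- dih <- numeric(length(idx))
  for (j in seq_along(idx)) {
    fr <- frame_coords(ens, idx[j])
    ang[j] <- vector_angle(fr[i269, ], fr[i112, ], fr[i0, ])
    dih[j] <- dihedral_angle(fr[i269, ], fr[i112, ], fr[i0, ], fr[i4, ])
  }
  avg <- average_structure(ens, window = window, fit_sel = NULL)
  list(series = data.frame(frame = idx, angle = ang, dihedral = dih),
       mean_angle = mean(ang), mean_dihedral = mean(dih),
       avg_structure_angle = vector_angle(avg[i269, ], avg[i112, ], avg[i0, ]),
       avg_structure_dihedral = dihedral_angle(avg[i269, ], avg[i112, ],
                                               avg[i0, ], avg[i4, ]))
}
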