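# Normalized dynamic cross-correlation maps of Calpha displacement
# vectors: C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>) over a frame
# window, displacements taken about the windowed mean after per-frame
# superposition on a fit selection.

#' Dynamic cross-correlation (covariance) map
#'
#' @param ens an `ensemble`.
#' @param sel atom indices (typically Calpha) to correlate.
#' @param fit_sel atom indices for the per-frame superposition; `NULL`
#'   skips fitting (frames already share a common reference frame).
#' @param window frame window (see [resolve_window()]); needs >= 2 frames.
#' @param normalized if `FALSE`, return the raw 3x3-block-traced
#'   covariance `<dr_i . dr_j>` instead of the normalized correlation.
#' @return object of class `"covariance_map"`: list with `matrix`
#'   (symmetric; unit diagonal when normalized; `NA` rows/columns for
#'   zero-variance atoms), `labels` (chain/residue labels) and
#'   `residue_number`.
#' @export
covariance_map <- function(ens, sel, fit_sel = NULL, window = 1,
                           normalized = TRUE) {
  idx <- resolve_window(ens, window)
  if (length(idx) < 2) stop("covariance map needs at least 2 frames")
  if (length(sel) < 1) stop("empty atom selection")
  frames <- .fitted_frames(ens, fit_sel, idx)
  stack <- lapply(frames, function(fr) fr[sel, , drop = FALSE])
  mean_str <- Reduce(`+`, stack) / length(stack)
  # displacement matrix: frames x (3 * natoms)
  D <- t(vapply(stack, function(fr) as.numeric(t(fr - mean_str)),
                numeric(3 * length(sel))))
  n <- length(sel)
  C <- matrix(0, n, n)
  for (a in 1:3) {
    cols <- seq(a, 3 * n, by = 3)
    C <- C + crossprod(D[, cols, drop = FALSE]) / length(idx)
  }
  if (normalized) {
    v <- diag(C)
    zero <- v < 1e-12
    denom <- sqrt(outer(v, v))
    C <- C / denom
    C[zero, ] <- NA_real_
    C[, zero] <- NA_real_
    diag(C)[!zero] <- 1
  }
  top <- ens$topology[sel, , drop = FALSE]
  labels <- paste0(top$chain_id, ":", top$residue_number)
  dimnames(C) <- list(labels, labels)
  structure(list(matrix = C, labels = labels,
                 residue_number = top$residue_number,
                 chain_id = top$chain_id, normalized = normalized),
            class = "covariance_map")
}

#' @export
print.covariance_map <- function(x, ...) {
  cat(sprintf("%s cross-correlation map: %d atoms\n",
              if (x$normalized) "normalized" else "raw",
              length(x$labels)))
  invisible(x)
}

#' Extract a sub-map by residue-number ranges
#'
#' @param map a `covariance_map`.
#' @param rows,cols integer vectors of residue numbers to keep on each
#'   axis (default: all).
#' @param chain optional chain filter applied to both axes.
#' @return a `covariance_map` over the sub-matrix.
#' @export
submap <- function(map, rows = NULL, cols = rows, chain = NULL) {
  pick <- function(rng) {
    keep <- rep(TRUE, length(map$labels))
    if (!is.null(rng)) keep <- keep & map$residue_number %in% rng
    if (!is.null(chain)) keep <- keep & map$chain_id %in% chain
    if (!any(keep)) stop("sub-map range selects no residues")
    which(keep)
  }
  ri <- pick(rows); ci <- pick(cols)
  structure(list(matrix = map$matrix[ri, ci, drop = FALSE],
                 labels = map$labels[ri],
                 residue_number = map$residue_number[ri],
                 chain_id = map$chain_id[ri],
                 normalized = map$normalized),
            class = "covariance_map")
}

#' Write a covariance map as labelled TSV
#'
#' @param map a `covariance_map`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_covariance_tsv <- function(map, path) {
  df <- data.frame(label = rownames(map$matrix), map$matrix,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
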