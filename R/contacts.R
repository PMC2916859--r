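# Hydrogen-bond and salt-bridge machinery: per-frame minimum donor-acceptor
# distance series, percentage occupancies over a frame window, bond-mode
# classification and the Arg280-Glu281-Arg273 salt-bridge network.
#
# A hydrogen bond / salt bridge is defined purely by a heavy-atom distance
# cutoff (default 3.5 Angstrom); a frame whose minimum pairwise distance is
# exactly the cutoff counts as bonded (<=, configurable).

#' Define a contact between two atom sets
#'
#' @param label contact name.
#' @param donor,acceptor lists of selection arguments for
#'   [select_atoms()] (e.g. `list(chain_id="C", residue_number=120,
#'   atom_name="NZ")`), or plain integer atom-index vectors.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 3.5).
#' @return list of class `"contact_definition"`.
#' @export
contact_definition <- function(label, donor, acceptor, cutoff = 3.5) {
  if (cutoff <= 0) stop("contact cutoff must be positive")
  structure(list(label = label, donor = donor, acceptor = acceptor,
                 cutoff = cutoff),
            class = "contact_definition")
}

.resolve_contact_side <- function(ens, side, label, role) {
  idx <- if (is.numeric(side)) as.integer(side)
         else do.call(select_atoms, c(list(ens), side))
  if (length(idx) == 0)
    stop(sprintf("mapping error: contact '%s' %s atoms do not resolve",
                 label, role), call. = FALSE)
  idx
}

# Per-frame minimum pairwise Euclidean distance between two atom index
# sets, over the given frames.  Vectorised over frames for each pair.
.min_pair_series <- function(ens, donor_idx, acceptor_idx, frame_idx) {
  xyz <- ens$xyz[frame_idx, , drop = FALSE]
  best <- rep(Inf, length(frame_idx))
  for (i in donor_idx) {
    di <- .xyz_cols(i)
    for (j in acceptor_idx) {
      dj <- .xyz_cols(j)
      d2 <- rowSums((xyz[, di, drop = FALSE] - xyz[, dj, drop = FALSE])^2)
      best <- pmin(best, d2)
    }
  }
  sqrt(best)
}

#' Per-frame contact distance series
#'
#' The distance of a contact in a frame is the minimum over all
#' donor-acceptor atom pairs.
#'
#' @param ens an `ensemble`.
#' @param contact a [contact_definition()].
#' @param window frame window (see [resolve_window()]); default the
#'   trajectory tail two-thirds used for occupancy statistics.
#' @return object of class `"distance_series"`: data.frame with `frame`
#'   and `distance` (Angstrom), plus attributes `label` and `cutoff`.
#' @export
distance_series <- function(ens, contact, window = 2 / 3) {
  stopifnot(inherits(contact, "contact_definition"))
  don <- .resolve_contact_side(ens, contact$donor, contact$label, "donor")
  acc <- .resolve_contact_side(ens, contact$acceptor, contact$label, "acceptor")
  idx <- resolve_window(ens, window)
  d <- .min_pair_series(ens, don, acc, idx)
  out <- data.frame(frame = idx, distance = d)
  attr(out, "label") <- contact$label
  attr(out, "cutoff") <- contact$cutoff
  class(out) <- c("distance_series", "data.frame")
  out
}

#' Percentage occupancy of a distance series
#'
#' Fraction of frames (as a percentage) in which the contact distance is
#' within the cutoff.
#'
#' @param series a `distance_series` (or bare numeric distances).
#' @param cutoff Angstrom; defaults to the series' own cutoff, else 3.5.
#' @param boundary `"<="` (default: a distance exactly at the cutoff
#'   counts as bonded) or `"<"`.
#' @return occupancy percentage in \[0, 100\].
#' @export
occupancy <- function(series, cutoff = NULL,
                      boundary = c("<=", "<")) {
  boundary <- match.arg(boundary)
  d <- if (is.data.frame(series)) series$distance else as.numeric(series)
  if (length(d) == 0) stop("occupancy of an empty distance series")
  if (is.null(cutoff)) cutoff <- attr(series, "cutoff")
  if (is.null(cutoff)) cutoff <- 3.5
  bonded <- if (boundary == "<=") d <= cutoff else d < cutoff
  100 * mean(bonded)
}

#' Classify the hydrogen-bond mode of one frame
#'
#' G presents two major-groove acceptors (O6, N7): both within the cutoff
#' means a three-centered hydrogen bond; one acceptor within the cutoff
#' (any base) is a two-centered bond; otherwise none.
#'
#' @param distances named numeric vector of donor-acceptor distances,
#'   names being acceptor atom names (e.g. `c(O6 = 2.8, N7 = 3.1)`).
#' @param base the base identity (`A`, `C`, `G`, `T`).
#' @param cutoff Angstrom (default 3.5).
#' @return one of `"three_centered"`, `"two_centered"`, `"none"`.
#' @examples
#' classify_mode(c(O6 = 2.8, N7 = 3.1), "G")   # three_centered
#' classify_mode(c(O4 = 3.0), "T")             # two_centered
#' @export
classify_mode <- function(distances, base, cutoff = 3.5) {
  base <- toupper(base)
  if (!base %in% c("A", "C", "G", "T")) stop("unknown base: ", base)
  within <- distances <= cutoff
  if (base == "G" && all(c("O6", "N7") %in% names(distances)) &&
      within["O6"] && within["N7"]) return("three_centered")
  if (any(within)) return("two_centered")
  "none"
}

# One occupancy-table row
.occ_row <- function(quarter, contact, strand, base, occ, n, note = "") {
  data.frame(quarter = quarter, contact = contact, strand = strand,
             base = base, occupancy = occ, n_frames = n, note = note,
             stringsAsFactors = FALSE)
}

#' Lys120 hydrogen-bond occupancy fingerprint
#'
#' For every quarter site in the mapping: the Lys120 NZ donor against the
#' major-groove acceptors of the base pairs at local positions 1-3, two
#' rows per position (the local-strand base and its primed partner on the
#' opposite strand), occupancies over the window.  A cytosine carries no
#' major-groove acceptor; its row is emitted with occupancy 0 and an
#' annotation.
#'
#' @param ens an `ensemble`.
#' @param map a `p53_mapping` (positions carry `local` and `partner`
#'   entries with `chain`, `resno`, `base`).
#' @param window frame window; default tail two-thirds.
#' @param cutoff Angstrom (default 3.5).
#' @return data.frame occupancy table (one row per quarter x position x
#'   strand) with a `series` attribute holding the distance series list.
#' @export
lys120_fingerprint <- function(ens, map, window = 2 / 3, cutoff = 3.5) {
  rows <- list(); series <- list()
  for (q in names(map$quarters)) {
    qmap <- map$quarters[[q]]
    nz <- .resolve_residue(ens, qmap, qmap$residues$lys120, "NZ",
                           paste0(q, " Lys120 NZ"))
    for (k in 1:3) {
      pos <- qmap$positions[[paste0("p", k)]]
      for (role in c("local", "partner")) {
        site <- pos[[role]]
        base <- toupper(site$base)
        # cross-check the registered base against the topology residue name
        resid <- unique(ens$topology$residue_name[
          select_atoms(ens, chain_id = site$chain,
                       residue_number = site$resno)])
        if (length(resid) == 1) {
          topo_base <- sub("^D", "", resid)
          if (topo_base %in% c("A", "C", "G", "T") && topo_base != base)
            stop(sprintf(
              "registration error: %s position %d (%s) is %s in the mapping but %s in the topology",
              q, k, role, base, topo_base), call. = FALSE)
        }
        label <- sprintf("%s_K120_pos%d_%s", q, k, role)
        acc_names <- major_groove_acceptors(base)
        if (length(acc_names) == 0) {
          idx <- resolve_window(ens, window)
          rows[[label]] <- .occ_row(q, sprintf("K120-pos%d-%s", k, role),
                                    role, base, 0, length(idx),
                                    "C has no major-groove acceptor")
          next
        }
        cd <- contact_definition(label, donor = nz,
                                 acceptor = .resolve_site(ens, site,
                                                          acc_names, label),
                                 cutoff = cutoff)
        ds <- distance_series(ens, cd, window)
        series[[label]] <- ds
        rows[[label]] <- .occ_row(q, sprintf("K120-pos%d-%s", k, role),
                                  role, base, occupancy(ds, cutoff),
                                  nrow(ds))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "series") <- series
  out
}

#' Arg280 contact with the conserved G at position 4'
#'
#' Per-pair distance series NH1-O6 and NH2-N7 (the named monitored
#' pairs), their per-frame average, and the min-pair aggregate, together
#' with occupancies for each.  When the registered 4' base is not G the
#' acceptors fall back to that base's major-groove set (annotated).
#'
#' @inheritParams lys120_fingerprint
#' @return list with `table` (occupancy rows) and `series` (named list:
#'   `NH1_O6`, `NH2_N7`, `pair_average`, `min_pair` per quarter).
#' @export
arg280_contact <- function(ens, map, window = 2 / 3, cutoff = 3.5) {
  rows <- list(); series <- list()
  for (q in names(map$quarters)) {
    qmap <- map$quarters[[q]]
    site <- qmap$positions$p4prime
    base <- toupper(site$base)
    nh1 <- .resolve_residue(ens, qmap, qmap$residues$arg280, "NH1",
                            paste0(q, " Arg280 NH1"))
    nh2 <- .resolve_residue(ens, qmap, qmap$residues$arg280, "NH2",
                            paste0(q, " Arg280 NH2"))
    note <- ""
    if (base == "G") {
      o6 <- .resolve_site(ens, site, "O6", paste0(q, " G4' O6"))
      n7 <- .resolve_site(ens, site, "N7", paste0(q, " G4' N7"))
      pairs <- list(NH1_O6 = list(nh1, o6), NH2_N7 = list(nh2, n7))
    } else {
      acc_names <- major_groove_acceptors(base)
      if (length(acc_names) == 0)
        stop(sprintf("mapping error: %s position 4' base %s has no acceptor",
                     q, base), call. = FALSE)
      acc <- .resolve_site(ens, site, acc_names, paste0(q, " 4' acceptor"))
      pairs <- list(NH1_acc = list(nh1, acc), NH2_acc = list(nh2, acc))
      note <- sprintf("non-consensus 4' base %s", base)
    }
    idx <- resolve_window(ens, window)
    per_pair <- lapply(names(pairs), function(pn) {
      cd <- contact_definition(sprintf("%s_R280_%s", q, pn),
                               donor = pairs[[pn]][[1]],
                               acceptor = pairs[[pn]][[2]], cutoff = cutoff)
      distance_series(ens, cd, window)
    })
    names(per_pair) <- names(pairs)
    avg <- data.frame(frame = idx,
                      distance = rowMeans(sapply(per_pair, `[[`, "distance")))
    attr(avg, "cutoff") <- cutoff
    minp <- data.frame(frame = idx,
                       distance = do.call(pmin,
                                          lapply(per_pair, `[[`, "distance")))
    attr(minp, "cutoff") <- cutoff
    series[[q]] <- c(per_pair, list(pair_average = avg, min_pair = minp))
    for (pn in names(pairs))
      rows[[paste(q, pn)]] <- .occ_row(q, paste0("R280-", pn), "complementary",
                                       base, occupancy(per_pair[[pn]], cutoff),
                                       length(idx), note)
    rows[[paste(q, "min")]] <- .occ_row(q, "R280-min_pair", "complementary",
                                        base, occupancy(minp, cutoff),
                                        length(idx), note)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(table = out, series = series)
}

# Default atom sets for the salt-bridge network.
.ARG_N <- c("NE", "NH1", "NH2")
.GLU_O <- c("OE1", "OE2")

#' Salt-bridge network occupancies A-D
#'
#' The four-link chain stabilising the specific interface: A DNA-Arg280,
#' B Arg280-Glu281, C Glu281-Arg273, D Arg273-DNA; min-pair distance
#' rule, occupancy at the cutoff, per quarter site.  DNA partners are
#' backbone phosphate oxygens (default `O1P`/`O2P`) of the residues
#' registered in the mapping; the mapping may narrow the protein donor
#' set per link (`donor_atoms`).
#'
#' @inheritParams lys120_fingerprint
#' @param dna_atoms DNA backbone atom set (default `c("O1P","O2P")`).
#' @return data.frame: quarter, link (A-D), partners, occupancy, n_frames;
#'   `series` attribute carries the distance series.
#' @export
saltbridge_network <- function(ens, map, window = 2 / 3, cutoff = 3.5,
                               dna_atoms = c("O1P", "O2P")) {
  rows <- list(); series <- list()
  for (q in names(map$quarters)) {
    qmap <- map$quarters[[q]]
    sb <- qmap$saltbridge
    if (is.null(sb)) stop("mapping lacks saltbridge entries for ", q)
    r280 <- function(at) .resolve_residue(ens, qmap, qmap$residues$arg280,
                                          at, paste0(q, " Arg280"))
    r273 <- function(at) .resolve_residue(ens, qmap, qmap$residues$arg273,
                                          at, paste0(q, " Arg273"))
    e281 <- function(at) .resolve_residue(ens, qmap, qmap$residues$glu281,
                                          at, paste0(q, " Glu281"))
    atoms_or <- function(entry, default) {
      if (!is.null(entry$donor_atoms)) unlist(entry$donor_atoms) else default
    }
    defs <- list(
      A = contact_definition(
        paste0(q, "_SB_A"),
        donor = r280(atoms_or(sb$A, .ARG_N)),
        acceptor = .resolve_site(ens, sb$A$dna, dna_atoms,
                                 paste0(q, " salt bridge A DNA")),
        cutoff = cutoff),
      B = contact_definition(
        paste0(q, "_SB_B"),
        donor = r280(atoms_or(sb$B, .ARG_N)),
        acceptor = e281(.GLU_O), cutoff = cutoff),
      C = contact_definition(
        paste0(q, "_SB_C"),
        donor = r273(atoms_or(sb$C, .ARG_N)),
        acceptor = e281(.GLU_O), cutoff = cutoff),
      D = contact_definition(
        paste0(q, "_SB_D"),
        donor = r273(atoms_or(sb$D, .ARG_N)),
        acceptor = .resolve_site(ens, sb$D$dna, dna_atoms,
                                 paste0(q, " salt bridge D DNA")),
        cutoff = cutoff)
    )
    partner <- c(A = "DNA-R280", B = "R280-E281", C = "E281-R273",
                 D = "R273-DNA")
    for (lk in names(defs)) {
      ds <- distance_series(ens, defs[[lk]], window)
      series[[paste0(q, "_", lk)]] <- ds
      rows[[paste0(q, "_", lk)]] <- data.frame(
        quarter = q, link = lk, partners = partner[[lk]],
        occupancy = occupancy(ds, cutoff), n_frames = nrow(ds),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "series") <- series
  out
}

#' Arg248 backbone-contact distance series
#'
#' The two monitored minor-groove-side distances between the Arg248
#' guanidinium and DNA backbone phosphate oxygens at quarter-site
#' positions 4 and 5, as registered in the mapping (`arg248$m1`,
#' `arg248$m2`, each with a `donor_atom` and a `dna` site).
#'
#' @inheritParams lys120_fingerprint
#' @param dna_atoms DNA backbone atom set (default `c("O1P","O2P")`).
#' @return named list per quarter of two `distance_series` (`m1`, `m2`).
#' @export
arg248_distances <- function(ens, map, window = 2 / 3, cutoff = 3.5,
                             dna_atoms = c("O1P", "O2P")) {
  out <- list()
  for (q in names(map$quarters)) {
    qmap <- map$quarters[[q]]
    a248 <- qmap$arg248
    if (is.null(a248)) stop("mapping lacks arg248 entries for ", q)
    out[[q]] <- lapply(setNames(nm = c("m1", "m2")), function(m) {
      spec <- a248[[m]]
      don <- .resolve_residue(ens, qmap, qmap$residues$arg248,
                              if (!is.null(spec$donor_atom)) spec$donor_atom
                              else .ARG_N,
                              paste0(q, " Arg248"))
      acc_atoms <- if (!is.null(spec$acceptor_atoms))
        unlist(spec$acceptor_atoms) else dna_atoms
      cd <- contact_definition(
        paste0(q, "_R248_", m), donor = don,
        acceptor = .resolve_site(ens, spec$dna, acc_atoms,
                                 paste0(q, " Arg248 ", m, " DNA")),
        cutoff = cutoff)
      distance_series(ens, cd, window)
    })
  }
  out
}

#' Correlation and co-disruption of two contact distance series
#'
#' Pearson correlation of the two per-frame distance series, plus the
#' fraction of frames in which both contacts are simultaneously broken
#' (distance above the cutoff) — the co-disruption fraction.  A
#' zero-variance series yields `NA` correlation (undefined); the
#' fraction is still computed.
#'
#' @param a,b equal-length `distance_series` (or numeric vectors).
#' @param cutoff Angstrom (default 3.5).
#' @return list with `pearson_r` and `co_disruption_fraction`.
#' @export
cooccupancy_correlation <- function(a, b, cutoff = 3.5) {
  da <- if (is.data.frame(a)) a$distance else as.numeric(a)
  db <- if (is.data.frame(b)) b$distance else as.numeric(b)
  if (length(da) != length(db))
    stop("distance series must have equal length")
  r <- if (stats::sd(da) == 0 || stats::sd(db) == 0) NA_real_
       else stats::cor(da, db)
  list(pearson_r = r,
       co_disruption_fraction = mean(da > cutoff & db > cutoff))
}
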