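# Synthetic p53-DNA-like ensembles with planted, recorded ground truth.
#
# The template is a schematic contact rig, not a physical model: ideal
# B-DNA for one half site plus flanking caps, and minimal pseudo-protein
# monomers (one per quarter site) holding exactly the atoms the analysis
# stages select - Lys120 NZ, the Arg248/Arg273/Arg280 guanidinium
# nitrogens, Glu281 carboxylate oxygens, and Calpha anchors including the
# organizational-descriptor residues 112 and 269.  Each planted contact
# owns one mobile atom group that is translated per frame so the
# controlled donor-acceptor distance equals a draw from the bonded or
# unbonded distance distribution; everything else only jitters.

.CAP5 <- "ATAATT"
.CAP3 <- "ATTAA"
.EXTRA_CA <- c(96, 130, 140, 175, 180, 185, 225, 244)

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) c(1, 0, 0) else v / n
}

.radial <- function(p) .unit(c(p[1], p[2], 0))

# Place X with |X-p1| = r, angle(X,p1,p2) = theta, dihedral(X,p1,p2,p3)
# = phi (degrees); standard internal-coordinate (NeRF) construction.
.place_internal <- function(p1, p2, p3, r, theta_deg, phi_deg) {
  th <- theta_deg * pi / 180; ph <- phi_deg * pi / 180
  b1 <- p1 - p2
  b2 <- p2 - p3
  u1 <- .unit(b1)
  nv <- .unit(c(b2[2] * b1[3] - b2[3] * b1[2],
                b2[3] * b1[1] - b2[1] * b1[3],
                b2[1] * b1[2] - b2[2] * b1[1]))
  m <- c(nv[2] * u1[3] - nv[3] * u1[2],
         nv[3] * u1[1] - nv[1] * u1[3],
         nv[1] * u1[2] - nv[2] * u1[1])
  p1 + (-r * cos(th)) * u1 + (r * sin(th) * cos(ph)) * m +
    (r * sin(th) * sin(ph)) * nv
}

#' Planted ground truth for the synthetic generator
#'
#' Defaults describe a consensus-conforming quarter site: Lys120 bonded
#' mainly to the central (position-2) base, Arg280 holding the conserved
#' G4' contact, a partially formed salt-bridge network, a moderate DNA
#' bend and one planted anti-correlated Calpha pair.  Bonded distances
#' draw from Normal(2.9, 0.15) truncated above 2.4 Angstrom, unbonded
#' from Normal(5.5, 0.5) truncated above cutoff + 0.2, so the 3.5
#' Angstrom rule separates the states with negligible leakage.
#'
#' @param n_frames number of frames.
#' @param lys120 length-3 probabilities for positions 1-3 (applied to
#'   every quarter), or a named list per quarter.
#' @param arg280 probability (scalar or named list per quarter).
#' @param saltbridge length-4 probabilities A-D (or named list per
#'   quarter).
#' @param arg248 length-2 probabilities for the two monitored contacts.
#' @param sigma isotropic per-coordinate Gaussian jitter (Angstrom).
#' @param bend planted DNA bend angle (degrees) applied at the half-site
#'   midpoint.
#' @param corr_amplitude,corr_sign amplitude (Angstrom) and sign of the
#'   planted correlated displacement of the Calpha pair.
#' @param corr_pair list of two selection lists naming the correlated
#'   atoms (default Calpha 120 and Calpha 180 of the first monomer).
#' @param cutoff hydrogen-bond cutoff the distributions are built around.
#' @param bonded_mean,bonded_sd,bonded_min,unbonded_mean,unbonded_sd
#'   distance-distribution parameters (Angstrom).
#' @param seed integer RNG seed.
#' @return list of class `"planted_truth"`.
#' @export
planted_truth <- function(n_frames = 2000,
                          lys120 = c(0, 0.9, 0),
                          arg280 = 0.9,
                          saltbridge = c(A = 0.9, B = 0.6, C = 0.5, D = 0.4),
                          arg248 = c(0.8, 0.3),
                          sigma = 0.3,
                          bend = 15,
                          corr_amplitude = 2.0,
                          corr_sign = -1,
                          corr_pair = NULL,
                          cutoff = 3.5,
                          bonded_mean = 2.9, bonded_sd = 0.15,
                          bonded_min = 2.4,
                          unbonded_mean = 5.5, unbonded_sd = 0.5,
                          seed = 1L) {
  truth <- list(n_frames = as.integer(n_frames), lys120 = lys120,
                arg280 = arg280, saltbridge = saltbridge, arg248 = arg248,
                sigma = sigma, bend = bend,
                corr_amplitude = corr_amplitude, corr_sign = corr_sign,
                corr_pair = corr_pair, cutoff = cutoff,
                bonded_mean = bonded_mean, bonded_sd = bonded_sd,
                bonded_min = bonded_min,
                unbonded_mean = unbonded_mean, unbonded_sd = unbonded_sd,
                unbonded_min = cutoff + 0.2,
                seed = as.integer(seed))
  validate_truth(truth)
}

#' Validate a planted-truth record
#' @param truth a list of generator parameters.
#' @return the truth, classed `"planted_truth"`.
#' @export
validate_truth <- function(truth) {
  probs <- c(unlist(truth$lys120), unlist(truth$arg280),
             unlist(truth$saltbridge), unlist(truth$arg248))
  if (any(probs < 0 | probs > 1))
    stop("invalid truth: probabilities must lie in [0, 1]")
  if (truth$sigma <= 0) stop("invalid truth: sigma must be positive")
  if (!(truth$bonded_mean < truth$cutoff &&
        truth$cutoff < truth$unbonded_mean))
    stop("invalid truth: need bonded mean < cutoff < unbonded mean")
  if (truth$n_frames < 1) stop("invalid truth: need at least one frame")
  class(truth) <- c("planted_truth", "list")
  truth
}

# Per-quarter probability lookup (scalar/vector recycled across quarters,
# or a named per-quarter list).
.quarter_prob <- function(spec, quarter) {
  if (is.list(spec) && !is.null(spec[[quarter]])) spec[[quarter]] else spec
}

# ---------------------------------------------------------------------------

.coord_of <- function(ens, fr, chain, resno, atom) {
  idx <- select_atoms(ens, chain_id = chain, residue_number = resno,
                      atom_name = atom)
  if (length(idx) == 0)
    stop(sprintf("template atom missing: %s/%s/%s", chain, resno, atom))
  fr[idx[1], ]
}

.base_unit_idx <- function(ens, chain, resno) {
  idx <- select_atoms(ens, chain_id = chain, residue_number = resno)
  nm <- .normalize_atom_name(ens$topology$atom_name[idx])
  idx[!nm %in% c("C3'", "P", "O1P", "O2P")]
}

.phosphate_idx <- function(ens, chain, resno) {
  select_atoms(ens, chain_id = chain, residue_number = resno,
               atom_name = c("P", "O1P", "O2P"))
}

#' Build a synthetic p53 dimer-half-site template
#'
#' Constructs ideal B-DNA for the supplied 10-bp half site flanked by the
#' default cap sequences, adds one pseudo-protein monomer per quarter
#' site (chains `C` and `D` on DNA chains `A`/`B`), placed at
#' crystal-like contact distances: Lys120 NZ 2.9 Angstrom from the
#' position-2 acceptor, Arg280 NH1/NH2 2.9 Angstrom from the G4' O6/N7,
#' and organizational anchors arranged so the angle descriptor starts
#' near 105 degrees with a dihedral near 25 degrees.  Returns the
#' template ensemble, the quarter-site mapping, and the planted-contact
#' rig used by [generate_ensemble()].
#'
#' @param half_site 10-base half-site sequence (reference strand).
#' @param cap5,cap3 flanking cap sequences.
#' @return list of class `"p53_template"` with `ensemble`, `map`,
#'   `contacts`, `bend_unit`, `z_junction`, `re_half`.
#' @export
build_template <- function(half_site = "GGGCATGCCC",
                           cap5 = .CAP5, cap3 = .CAP3) {
  bases <- .check_alphabet(half_site, "half site")
  if (length(bases) != 10)
    stop("half site must have exactly 10 bases, got ", length(bases))
  ref_seq <- paste0(toupper(cap5), paste(bases, collapse = ""), toupper(cap3))
  n <- nchar(ref_seq)
  pos1 <- nchar(cap5) + 1L
  dna <- ideal_bdna(ref_seq)
  ref_chars <- strsplit(ref_seq, "")[[1]]
  comp_of <- function(r) n + 1L - r

  # --- per-quarter registration -------------------------------------------
  quarter_sites <- function(q) {
    if (q == "Q1") {
      local_site <- function(k) list(chain = "A", resno = pos1 + k - 1L,
                                     base = ref_chars[pos1 + k - 1L])
      partner_site <- function(k) {
        r <- pos1 + k - 1L
        list(chain = "B", resno = comp_of(r), base = complement_base(ref_chars[r]))
      }
    } else {
      local_site <- function(k) {
        r <- pos1 + 10L - k
        list(chain = "B", resno = comp_of(r), base = complement_base(ref_chars[r]))
      }
      partner_site <- function(k) {
        r <- pos1 + 10L - k
        list(chain = "A", resno = r, base = ref_chars[r])
      }
    }
    list(local = local_site, partner = partner_site)
  }

  quarters <- list()
  protein_rows <- list(); protein_xyz <- list(); serial <- max(dna$topology$serial)
  contacts <- list()
  fr0 <- frame_coords(dna, 1)

  add_atom <- function(chain, resno, resname, atom, elem, pos) {
    serial <<- serial + 1L
    protein_rows[[length(protein_rows) + 1L]] <<- data.frame(
      serial = serial, atom_name = atom, residue_name = resname,
      residue_number = resno, chain_id = chain, element = elem,
      stringsAsFactors = FALSE)
    protein_xyz[[length(protein_xyz) + 1L]] <<- pos
  }

  for (qi in 1:2) {
    q <- paste0("Q", qi)
    chain <- c("C", "D")[qi]
    qs <- quarter_sites(q)
    pos_entries <- lapply(1:3, function(k)
      list(local = qs$local(k), partner = qs$partner(k)))
    names(pos_entries) <- paste0("p", 1:3)
    p4 <- qs$partner(4)
    # contacted site per position: local strand if it has an acceptor,
    # else the primed partner
    contact_site <- lapply(1:3, function(k) {
      s <- pos_entries[[k]]$local
      if (length(major_groove_acceptors(s$base)) > 0) c(s, role = "local")
      else c(pos_entries[[k]]$partner, role = "partner")
    })

    site_coord <- function(site, atom) .coord_of(dna, fr0, site$chain,
                                                 site$resno, atom)
    acc2_names <- major_groove_acceptors(contact_site[[2]]$base)
    if (length(acc2_names) == 0)
      stop("template half site has no contactable base at position 2 of ", q)
    a2 <- site_coord(contact_site[[2]], acc2_names[1])

    # Aim the NZ placement direction to keep the flanking position-1/3
    # acceptors well beyond the cutoff at rest (deterministic grid
    # search over tilts of the outward radial direction).
    flank <- do.call(rbind, lapply(c(1, 3), function(k) {
      s <- contact_site[[k]]
      t(vapply(major_groove_acceptors(s$base),
               function(at) site_coord(s, at), numeric(3)))
    }))
    u0 <- .radial(a2)
    tang <- .unit(c(-u0[2], u0[1], 0))
    best_u <- u0; best_min <- -Inf
    for (az in seq(-0.9, 0.9, by = 0.3)) for (at in seq(-0.9, 0.9, by = 0.3)) {
      cand <- .unit(u0 + az * c(0, 0, 1) + at * tang)
      nz_c <- a2 + 2.9 * cand
      m <- min(sqrt(rowSums(sweep(flank, 2, nz_c)^2)))
      if (m > best_min) { best_min <- m; best_u <- cand }
    }
    u <- best_u
    nz <- a2 + 2.9 * u
    add_atom(chain, 120L, "LYS", "NZ", "N", nz)
    add_atom(chain, 120L, "LYS", "CA", "C", a2 + 7.4 * u)

    if (toupper(p4$base) != "G")
      stop("template expects the conserved G at position 4' of ", q,
           " (got ", p4$base, "); choose a consensus-like half site")
    o6 <- site_coord(p4, "O6"); n7 <- site_coord(p4, "N7")
    u6 <- .radial(o6); u7 <- .radial(n7)
    nh1 <- o6 + 2.9 * u6; nh2 <- n7 + 2.9 * u7
    ne280 <- (nh1 + nh2) / 2 + 1.5 * .unit(u6 + u7)
    add_atom(chain, 280L, "ARG", "NH1", "N", nh1)
    add_atom(chain, 280L, "ARG", "NH2", "N", nh2)
    add_atom(chain, 280L, "ARG", "NE", "N", ne280)
    add_atom(chain, 280L, "ARG", "CA", "C", ne280 + 4 * u6)

    # Glu281 carboxylate direction: tangential, signed away from the
    # Arg280 guanidinium, lifted out of the base plane so the B link does
    # not thread through the NH atoms.
    vt <- .unit(c(u6[2], -u6[1], 0))
    if (sum(vt * (nh2 - ne280)) > 0) vt <- -vt
    v <- .unit(vt + c(0, 0, 0.6))
    oe1 <- ne280 + 2.9 * v; oe2 <- oe1 + 1.2 * v
    add_atom(chain, 281L, "GLU", "OE1", "O", oe1)
    add_atom(chain, 281L, "GLU", "OE2", "O", oe2)
    add_atom(chain, 281L, "GLU", "CA", "C", oe1 + 3 * u6)

    nh1_273 <- oe2 + 2.9 * v; nh2_273 <- nh1_273 + 1.2 * v
    ne_273 <- nh1_273 + 2.0 * u6
    add_atom(chain, 273L, "ARG", "NH1", "N", nh1_273)
    add_atom(chain, 273L, "ARG", "NH2", "N", nh2_273)
    add_atom(chain, 273L, "ARG", "NE", "N", ne_273)
    add_atom(chain, 273L, "ARG", "CA", "C", nh1_273 + 4 * u6)

    sb_dna <- if (q == "Q1")
      list(A = list(chain = "A", resno = pos1 + 1L),
           D = list(chain = "A", resno = pos1 + 2L))
    else
      list(A = list(chain = "B", resno = comp_of(pos1 + 8L)),
           D = list(chain = "B", resno = comp_of(pos1 + 7L)))
    a248_dna <- if (q == "Q1")
      list(m1 = list(chain = "A", resno = pos1 + 3L),
           m2 = list(chain = "A", resno = pos1 + 4L))
    else
      list(m1 = list(chain = "B", resno = comp_of(pos1 + 6L)),
           m2 = list(chain = "B", resno = comp_of(pos1 + 5L)))

    o1p4 <- .coord_of(dna, fr0, a248_dna$m1$chain, a248_dna$m1$resno, "O1P")
    o1p5 <- .coord_of(dna, fr0, a248_dna$m2$chain, a248_dna$m2$resno, "O1P")
    nh1_248 <- o1p4 + 2.9 * .radial(o1p4)
    nh2_248 <- o1p5 + 2.9 * .radial(o1p5)
    ne_248 <- (nh1_248 + nh2_248) / 2 + 1.5 * .radial(nh1_248 + nh2_248)
    add_atom(chain, 248L, "ARG", "NH1", "N", nh1_248)
    add_atom(chain, 248L, "ARG", "NH2", "N", nh2_248)
    add_atom(chain, 248L, "ARG", "NE", "N", ne_248)
    add_atom(chain, 248L, "ARG", "CA", "C", ne_248 + 3 * .radial(ne_248))

    ca112 <- a2 + 9.5 * u + c(0, 0, 2.0)
    add_atom(chain, 112L, "GLY", "CA", "C", ca112)
    org_p0 <- if (q == "Q1") list(chain = "A", resno = pos1 - 1L)
              else list(chain = "B", resno = comp_of(pos1 + 10L))
    org_p4 <- list(chain = p4$chain, resno = p4$resno)
    c3_p0 <- .coord_of(dna, fr0, org_p0$chain, org_p0$resno, "C3'")
    c3_p4 <- .coord_of(dna, fr0, org_p4$chain, org_p4$resno, "C3'")
    ca269 <- .place_internal(ca112, c3_p0, c3_p4, 15, 105, 25)
    add_atom(chain, 269L, "SER", "CA", "C", ca269)

    phi0 <- atan2(a2[2], a2[1])
    for (r in .EXTRA_CA) {
      phi <- phi0 + (r - 190) / 60
      add_atom(chain, as.integer(r), "ALA", "CA", "C",
               c(16 * cos(phi), 16 * sin(phi), a2[3] + (r - 190) * 0.04))
    }

    quarters[[q]] <- list(
      protein_chain = chain,
      residues = list(gly112 = 112L, lys120 = 120L, arg248 = 248L,
                      ser269 = 269L, arg273 = 273L, arg280 = 280L,
                      glu281 = 281L),
      positions = c(pos_entries, list(p4prime = p4)),
      contact_sites = contact_site,
      org_anchors = list(p0_c3 = org_p0, p4prime_c3 = org_p4),
      saltbridge = list(A = list(dna = sb_dna$A), B = list(),
                        C = list(), D = list(dna = sb_dna$D)),
      arg248 = list(m1 = list(donor_atom = "NH1", dna = a248_dna$m1,
                              acceptor_atoms = "O1P"),
                    m2 = list(donor_atom = "NH2", dna = a248_dna$m2,
                              acceptor_atoms = "O1P"))
    )
  }

  top <- rbind(dna$topology, do.call(rbind, protein_rows))
  xyz <- c(as.numeric(ens_xyz <- dna$xyz[1, ]),
           as.numeric(t(do.call(rbind, protein_xyz))))
  ens <- ensemble(top, matrix(xyz, nrow = 1))

  map <- validate_mapping(list(
    re_name = paste0("synthetic half site ", paste(bases, collapse = "")),
    half_site = paste(bases, collapse = ""),
    cap5 = toupper(cap5), cap3 = toupper(cap3),
    cutoff = 3.5,
    dna = list(ref_chain = "A", comp_chain = "B", n_bp = n,
               position1_resno = pos1),
    quarters = quarters
  ))

  # --- planted-contact rig -------------------------------------------------
  fr <- frame_coords(ens, 1)
  sel1 <- function(chain, resno, atom) {
    idx <- select_atoms(ens, chain_id = chain, residue_number = resno,
                        atom_name = atom)
    if (length(idx) == 0)
      stop("template rig atom missing: ", chain, "/", resno, "/", atom)
    idx
  }
  contacts <- list()
  add_contact <- function(key, prob_fun, anchor_idx, mobile_idx,
                          controlled_idx, placement,
                          donor_set, acceptor_set, offsets = NULL) {
    contacts[[key]] <<- list(key = key, prob_fun = prob_fun,
                             anchor = anchor_idx, mobile = mobile_idx,
                             controlled = controlled_idx,
                             placement = placement, offsets = offsets,
                             donor_set = donor_set,
                             acceptor_set = acceptor_set)
  }

  for (qi in 1:2) {
    q <- paste0("Q", qi)
    qmap <- map$quarters[[q]]
    chain <- qmap$protein_chain
    nz <- sel1(chain, 120, "NZ")
    for (k in 1:3) {
      site <- qmap$contact_sites[[k]]
      accs <- major_groove_acceptors(site$base)
      acc_idx <- sel1(site$chain, site$resno, accs)
      local({
        kk <- k
        add_contact(sprintf("%s.k120.p%d", q, kk),
                    function(truth, q) .quarter_prob(truth$lys120, q)[[kk]],
                    nz, .base_unit_idx(ens, site$chain, site$resno),
                    acc_idx, "rigid",
                    donor_set = nz, acceptor_set = acc_idx)
      })
    }
    p4 <- qmap$positions$p4prime
    o6 <- sel1(p4$chain, p4$resno, "O6"); n7 <- sel1(p4$chain, p4$resno, "N7")
    nh1 <- sel1(chain, 280, "NH1"); nh2 <- sel1(chain, 280, "NH2")
    ne280 <- sel1(chain, 280, "NE")
    add_contact(paste0(q, ".r280"),
                function(truth, q) .quarter_prob(truth$arg280, q)[[1]],
                nh1, .base_unit_idx(ens, p4$chain, p4$resno), o6, "rigid",
                donor_set = c(nh1, nh2), acceptor_set = c(o6, n7))
    oe1 <- sel1(chain, 281, "OE1"); oe2 <- sel1(chain, 281, "OE2")
    nh1_273 <- sel1(chain, 273, "NH1"); nh2_273 <- sel1(chain, 273, "NH2")
    ne_273 <- sel1(chain, 273, "NE")
    argN280 <- c(ne280, nh1, nh2); argN273 <- c(ne_273, nh1_273, nh2_273)
    sbA <- qmap$saltbridge$A$dna; sbD <- qmap$saltbridge$D$dna
    phosA <- .phosphate_idx(ens, sbA$chain, sbA$resno)
    phosD <- .phosphate_idx(ens, sbD$chain, sbD$resno)
    o1pA <- sel1(sbA$chain, sbA$resno, "O1P")
    o1pD <- sel1(sbD$chain, sbD$resno, "O1P")
    sb_prob <- function(link) {
      force(link)
      function(truth, q) {
        p <- .quarter_prob(truth$saltbridge, q)
        unname(if (!is.null(names(p))) p[[link]]
               else p[[match(link, c("A", "B", "C", "D"))]])
      }
    }
    add_contact(paste0(q, ".sbA"), sb_prob("A"), ne280,
                c(o1pA, setdiff(phosA, o1pA)), o1pA,
                "collinear", donor_set = argN280,
                acceptor_set = select_atoms(ens, chain_id = sbA$chain,
                                            residue_number = sbA$resno,
                                            atom_name = c("O1P", "O2P")),
                offsets = c(0, 1.3, 2.2))
    add_contact(paste0(q, ".sbB"), sb_prob("B"), ne280, c(oe1, oe2), oe1,
                "collinear", donor_set = argN280,
                acceptor_set = c(oe1, oe2), offsets = c(0, 1.2))
    add_contact(paste0(q, ".sbC"), sb_prob("C"), oe2,
                c(nh1_273, nh2_273, ne_273), nh1_273, "collinear",
                donor_set = argN273, acceptor_set = c(oe1, oe2),
                offsets = c(0, 1.2, 2.0))
    add_contact(paste0(q, ".sbD"), sb_prob("D"), nh1_273,
                c(o1pD, setdiff(phosD, o1pD)), o1pD,
                "collinear", donor_set = argN273,
                acceptor_set = select_atoms(ens, chain_id = sbD$chain,
                                            residue_number = sbD$resno,
                                            atom_name = c("O1P", "O2P")),
                offsets = c(0, 1.3, 2.2))
    a248 <- qmap$arg248
    for (m in c("m1", "m2")) {
      spec <- a248[[m]]
      don <- sel1(chain, 248, spec$donor_atom)
      acc <- sel1(spec$dna$chain, spec$dna$resno, spec$acceptor_atoms)
      local({
        mm <- m
        add_contact(sprintf("%s.r248.%s", q, mm),
                    function(truth, q)
                      .quarter_prob(truth$arg248, q)[[match(mm, c("m1", "m2"))]],
                    acc[1], don, don, "collinear",
                    donor_set = don, acceptor_set = acc, offsets = 0)
      })
    }
  }

  bend_unit <- sort(unique(c(
    select_atoms(ens, chain_id = "A")[
      ens$topology$residue_number[select_atoms(ens, chain_id = "A")] >= pos1 + 5L],
    select_atoms(ens, chain_id = "B")[
      ens$topology$residue_number[select_atoms(ens, chain_id = "B")] <=
        comp_of(pos1 + 5L)],
    select_atoms(ens, chain_id = "D")
  )))

  structure(list(ensemble = ens, map = map, contacts = contacts,
                 bend_unit = bend_unit,
                 z_junction = 3.38 * (pos1 + 4L - 1L + 0.5),
                 re_half = paste(bases, collapse = "")),
            class = "p53_template")
}

# truncated-normal draw (lower bound only)
.rtnorm <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower)
  guard <- 0
  while (length(bad) > 0 && guard < 100) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
    guard <- guard + 1
  }
  x[x < lower] <- lower
  x
}

.rot_about_axis_x <- function(coords, theta_deg, center) {
  r <- theta_deg * pi / 180
  R <- matrix(c(1, 0, 0,
                0, cos(r), sin(r),
                0, -sin(r), cos(r)), 3, 3)
  sweep(sweep(coords, 2, center) %*% t(R), 2, center, "+")
}

#' Generate a synthetic ensemble from a template and planted truth
#'
#' Per frame: every atom receives isotropic Gaussian jitter; the DNA
#' second half (with its monomer) is rotated to realize the planted bend;
#' each planted contact is independently bonded with its probability,
#' its mobile group translated so the controlled donor-acceptor distance
#' equals a draw from the bonded distribution, or - when not bonded -
#' left at rest if already beyond cutoff + 0.2 Angstrom, else pushed to
#' an unbonded draw; finally the planted correlated Calpha pair receives
#' its common-mode displacement.  Fully reproducible from the seed.
#'
#' @param template a `p53_template` from [build_template()].
#' @param truth a [planted_truth()].
#' @param seed RNG seed (default `truth$seed`).
#' @param forced optional named list of logical vectors (length
#'   `n_frames`) forcing the bonded state of specific contacts by key
#'   (used by the coupled-disruption scenario).
#' @return list with `ensemble`, `truth` (with realized bookkeeping:
#'   per-contact planted probability and realized bonded fraction) and
#'   `map`.
#' @export
generate_ensemble <- function(template, truth = planted_truth(),
                              seed = truth$seed, forced = NULL) {
  stopifnot(inherits(template, "p53_template"))
  truth <- validate_truth(truth)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ens <- template$ensemble
  na <- n_atoms(ens)
  nf <- truth$n_frames
  base <- frame_coords(ens, 1)
  if (abs(truth$bend) > 1e-9)
    base[template$bend_unit, ] <- .rot_about_axis_x(
      base[template$bend_unit, , drop = FALSE], truth$bend,
      c(0, 0, template$z_junction))

  # planted correlated pair
  cp <- truth$corr_pair
  if (is.null(cp))
    cp <- list(list(chain_id = "C", residue_number = 120, atom_name = "CA"),
               list(chain_id = "C", residue_number = 180, atom_name = "CA"))
  i1 <- do.call(select_atoms, c(list(ens), cp[[1]]))[1]
  i2 <- do.call(select_atoms, c(list(ens), cp[[2]]))[1]
  if (is.na(i1) || is.na(i2)) stop("correlated atom pair does not resolve")
  corr_u <- c(1, 0, 0)

  contacts <- template$contacts
  quarter_of <- function(key) sub("\\..*$", "", key)
  bonded_frac <- setNames(numeric(length(contacts)), names(contacts))

  out <- matrix(NA_real_, nf, 3L * na)
  for (f in seq_len(nf)) {
    fr <- base + matrix(rnorm(3L * na, 0, truth$sigma), na, 3)
    for (key in names(contacts)) {
      ct <- contacts[[key]]
      p <- ct$prob_fun(truth, quarter_of(key))
      bonded <- if (!is.null(forced[[key]])) forced[[key]][f]
                else runif(1) < p
      anchor <- fr[ct$anchor, ]
      ctrl <- fr[ct$controlled, , drop = FALSE]
      dctrl <- sqrt(rowSums(sweep(ctrl, 2, anchor)^2))
      near <- which.min(dctrl)
      u <- .unit(ctrl[near, ] - anchor)
      place <- function(d) {
        if (ct$placement == "rigid") {
          shift <- (anchor + d * u) - ctrl[near, ]
          fr[ct$mobile, ] <<- sweep(fr[ct$mobile, , drop = FALSE], 2,
                                    shift, "+")
        } else {
          for (j in seq_along(ct$mobile))
            fr[ct$mobile[j], ] <<- anchor + (d + ct$offsets[j]) * u
        }
      }
      if (bonded) {
        place(.rtnorm(1, truth$bonded_mean, truth$bonded_sd,
                      truth$bonded_min))
        bonded_frac[key] <- bonded_frac[key] + 1
      } else {
        # analysis min over the configured donor/acceptor sets
        cur <- min(as.vector(
          sqrt(outer(rowSums(fr[ct$donor_set, , drop = FALSE]^2),
                     rowSums(fr[ct$acceptor_set, , drop = FALSE]^2), "+") -
               2 * fr[ct$donor_set, , drop = FALSE] %*%
                 t(fr[ct$acceptor_set, , drop = FALSE]))))
        if (cur < truth$unbonded_min) {
          d <- .rtnorm(1, truth$unbonded_mean, truth$unbonded_sd,
                       truth$unbonded_min)
          for (tries in 1:4) {
            place(d)
            cur <- min(as.vector(
              sqrt(outer(rowSums(fr[ct$donor_set, , drop = FALSE]^2),
                         rowSums(fr[ct$acceptor_set, , drop = FALSE]^2), "+") -
                   2 * fr[ct$donor_set, , drop = FALSE] %*%
                     t(fr[ct$acceptor_set, , drop = FALSE]))))
            if (cur >= truth$unbonded_min) break
            d <- d + (truth$unbonded_min - cur) + 0.05
          }
        }
      }
    }
    s <- rnorm(1, 0, truth$corr_amplitude)
    fr[i1, ] <- fr[i1, ] + s * corr_u
    fr[i2, ] <- fr[i2, ] + truth$corr_sign * s * corr_u
    out[f, ] <- as.numeric(t(fr))
  }
  truth$realized_bonded_fraction <- bonded_frac / nf
  truth$corr_pair_resolved <- c(i1, i2)
  list(ensemble = ensemble(ens$topology, out), truth = truth,
       map = template$map)
}

#' Coupled Lys120/Arg280 disruption scenario
#'
#' Emulates concerted loss of the Lys120 central-base hydrogen bond and
#' the Arg280 G4' contact in the first quarter site: per frame, Lys120
#' breaks with probability `p_marginal`; with probability `p_joint` the
#' Arg280 state is coupled (copies the Lys120 state), otherwise it is an
#' independent Bernoulli with the same marginal.  `p_joint = 1` makes
#' the contacts break strictly together; `p_joint = 0` makes them
#' independent.
#'
#' @param template a `p53_template`.
#' @param p_joint coupling probability in \[0, 1\].
#' @param p_marginal per-frame disruption probability of each contact.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param ... further arguments passed to [planted_truth()].
#' @return as [generate_ensemble()]; the truth additionally records
#'   `p_joint`, `p_marginal` and `expected_co_disruption`.
#' @export
coupled_disruption_scenario <- function(template, p_joint,
                                        p_marginal = 0.5,
                                        n_frames = 2000, seed = 1L, ...) {
  if (p_joint < 0 || p_joint > 1) stop("p_joint must lie in [0, 1]")
  set.seed(as.integer(seed))
  broken_l <- runif(n_frames) < p_marginal
  coupled <- runif(n_frames) < p_joint
  broken_r <- ifelse(coupled, broken_l, runif(n_frames) < p_marginal)
  truth <- planted_truth(n_frames = n_frames, seed = seed, ...)
  gen <- generate_ensemble(
    template, truth, seed = seed,
    forced = list(Q1.k120.p2 = !broken_l, Q1.r280 = !broken_r))
  gen$truth$p_joint <- p_joint
  gen$truth$p_marginal <- p_marginal
  gen$truth$expected_co_disruption <-
    p_marginal * (p_joint + (1 - p_joint) * p_marginal)
  gen$truth$realized_co_disruption <- mean(broken_l & broken_r)
  gen
}

#' Write a generated ensemble bundle to disk
#'
#' Emits the multi-model PDB, the mapping configuration (YAML) and the
#' planted-truth record (JSON) side by side.
#'
#' @param gen result of [generate_ensemble()] or
#'   [coupled_disruption_scenario()].
#' @param dir output directory (created if needed).
#' @param stem file stem (default `"synthetic"`).
#' @return invisibly, named character vector of the three paths.
#' @export
write_ensemble_bundle <- function(gen, dir, stem = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(pdb = file.path(dir, paste0(stem, ".pdb")),
             mapping = file.path(dir, paste0(stem, "_mapping.yaml")),
             truth = file.path(dir, paste0(stem, "_truth.json")))
  write_multimodel_pdb(gen$ensemble, paths[["pdb"]])
  write_mapping(gen$map, paths[["mapping"]])
  truth <- gen$truth
  truth$corr_pair <- NULL   # atom indices already recorded
  jsonlite::write_json(unclass(truth), paths[["truth"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
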