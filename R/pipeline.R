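# End-to-end runs: consensus scoring of response-element sequences,
# fingerprint analysis of an ensemble + mapping, and synthetic-ensemble
# simulation.  Reports are TSV/JSON twins plus a machine-readable run
# manifest; outputs are deterministic for fixed inputs and seed.

#' Run configuration for the fingerprint pipeline
#'
#' @param cutoff hydrogen-bond / salt-bridge cutoff (Angstrom).
#' @param occupancy_window tail fraction for occupancy statistics
#'   (default 2/3, the tail of the trajectory after equilibration-style
#'   settling).
#' @param fluctuation_window tail fraction for fluctuation analyses
#'   (default 1/6).
#' @param seed integer seed (used by `run_simulate`).
#' @return list of class `"run_config"`.
#' @export
run_config <- function(cutoff = 3.5, occupancy_window = 2 / 3,
                       fluctuation_window = 1 / 6, seed = 1L) {
  if (cutoff <= 0) stop("cutoff must be positive")
  for (f in c(occupancy_window, fluctuation_window))
    if (!(f > 0 && f <= 1)) stop("window fractions must lie in (0, 1]")
  structure(list(cutoff = cutoff, occupancy_window = occupancy_window,
                 fluctuation_window = fluctuation_window,
                 seed = as.integer(seed)),
            class = "run_config")
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Consensus-scoring command
#'
#' Parses one or more response-element sequences and writes per-element
#' mismatch reports (TSV + JSON) plus a summary table.
#'
#' @param sequences named character vector of 20-bp sequences, or a
#'   single path to a FASTA/plain-text file.
#' @param out_dir output directory.
#' @return invisibly, the summary data.frame (name, mismatch_count).
#' @export
run_consensus <- function(sequences, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (length(sequences) == 1 && file.exists(sequences))
    res <- list(read_re(sequences))
  else {
    if (is.null(names(sequences)))
      names(sequences) <- paste0("RE", seq_along(sequences))
    res <- lapply(names(sequences), function(nm) parse_re(nm, sequences[[nm]]))
  }
  rows <- lapply(res, function(re) {
    rep <- score_consensus(re)
    stem <- file.path(out_dir, gsub("[^A-Za-z0-9._-]", "_", re$name))
    write_mismatch_report(rep, tsv = paste0(stem, "_mismatches.tsv"),
                          json = paste0(stem, "_mismatches.json"))
    data.frame(name = re$name, mismatch_count = rep$mismatch_count,
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  .write_tsv(summary, file.path(out_dir, "consensus_summary.tsv"))
  invisible(summary)
}

# Table-1-shaped pivot of the Lys120 fingerprint: one row per quarter,
# occupancy of the contacted (annotation-free, maximal) strand per
# position.
.lys120_pivot <- function(tab) {
  out <- lapply(split(tab, tab$quarter), function(df) {
    occ <- vapply(1:3, function(k) {
      rows <- df[grepl(sprintf("pos%d", k), df$contact), , drop = FALSE]
      max(rows$occupancy)
    }, numeric(1))
    data.frame(quarter = df$quarter[1], pos1 = occ[1], pos2 = occ[2],
               pos3 = occ[3], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.saltbridge_pivot <- function(tab) {
  out <- lapply(split(tab, tab$quarter), function(df) {
    v <- setNames(df$occupancy, df$link)
    data.frame(quarter = df$quarter[1], A = v[["A"]], B = v[["B"]],
               C = v[["C"]], D = v[["D"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fingerprint-analysis command
#'
#' Runs every analysis stage on an ensemble + mapping and writes the
#' report bundle: Lys120 occupancy table (long and quarter-by-position
#' pivot), Arg280 contact table, salt-bridge network table, Arg248
#' distance series, organizational angle/dihedral table, RMSD series and
#' RMSF profile per monomer, DNA bend, covariance map, and a JSON run
#' manifest with inputs, parameters and file checksums.
#'
#' @param ens an `ensemble` (or path to a multi-model PDB).
#' @param map a `p53_mapping` (or path to a mapping YAML).
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results.
#' @export
run_fingerprint <- function(ens, map, out_dir, config = run_config()) {
  if (is.character(ens)) ens <- read_multimodel_pdb(ens)
  if (is.character(map)) map <- read_mapping(map)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ow <- config$occupancy_window; fw <- config$fluctuation_window
  cutoff <- config$cutoff

  k120 <- lys120_fingerprint(ens, map, window = ow, cutoff = cutoff)
  r280 <- arg280_contact(ens, map, window = ow, cutoff = cutoff)
  sb <- saltbridge_network(ens, map, window = ow, cutoff = cutoff)
  r248 <- arg248_distances(ens, map, window = ow, cutoff = cutoff)

  .write_tsv(k120, file.path(out_dir, "lys120_occupancy_long.tsv"))
  .write_tsv(.lys120_pivot(k120), file.path(out_dir, "lys120_occupancy.tsv"))
  .write_tsv(r280$table, file.path(out_dir, "arg280_occupancy.tsv"))
  .write_tsv(sb, file.path(out_dir, "saltbridge_long.tsv"))
  .write_tsv(.saltbridge_pivot(sb), file.path(out_dir, "saltbridge.tsv"))
  r248_long <- do.call(rbind, lapply(names(r248), function(q)
    do.call(rbind, lapply(names(r248[[q]]), function(m)
      data.frame(quarter = q, monitor = m, frame = r248[[q]][[m]]$frame,
                 distance = r248[[q]][[m]]$distance)))))
  .write_tsv(r248_long, file.path(out_dir, "arg248_distances.tsv"))

  org <- lapply(setNames(nm = names(map$quarters)), function(q)
    org_geometry(ens, map, q, window = fw))
  org_tab <- do.call(rbind, lapply(names(org), function(q)
    data.frame(quarter = q,
               angle = org[[q]]$avg_structure_angle,
               dihedral = org[[q]]$avg_structure_dihedral,
               mean_angle = org[[q]]$mean_angle,
               mean_dihedral = org[[q]]$mean_dihedral)))
  .write_tsv(org_tab, file.path(out_dir, "org_geometry.tsv"))

  # per-monomer RMSD of the key side chains (fit on monomer Calpha)
  rmsd_rows <- list()
  for (q in names(map$quarters)) {
    qmap <- map$quarters[[q]]
    fit <- select_atoms(ens, chain_id = qmap$protein_chain, atom_name = "CA")
    for (res in c(lys120 = qmap$residues$lys120,
                  arg280 = qmap$residues$arg280,
                  arg248 = qmap$residues$arg248)) {
      meas <- setdiff(select_atoms(ens, chain_id = qmap$protein_chain,
                                   residue_number = res), fit)
      if (length(meas) == 0) next
      rs <- rmsd_series(ens, fit, meas)
      rmsd_rows[[paste(q, res)]] <- data.frame(
        quarter = q, residue_number = res, frame = rs$frame, rmsd = rs$rmsd)
    }
  }
  .write_tsv(do.call(rbind, rmsd_rows), file.path(out_dir, "rmsd_series.tsv"))

  rmsf_rows <- list()
  for (q in names(map$quarters)) {
    qmap <- map$quarters[[q]]
    sel <- select_atoms(ens, chain_id = qmap$protein_chain, atom_name = "CA")
    pr <- rmsf_profile(ens, sel, window = fw)
    pr$quarter <- q
    rmsf_rows[[q]] <- pr
  }
  .write_tsv(do.call(rbind, rmsf_rows), file.path(out_dir, "rmsf.tsv"))

  avg <- average_structure(ens, window = fw, fit_sel = NULL)
  avg_ens <- ensemble(ens$topology, matrix(as.numeric(t(avg)), nrow = 1))
  bend <- bend_angle(avg_ens, ref_chain = map$dna$ref_chain,
                     comp_chain = map$dna$comp_chain)
  .write_tsv(data.frame(segment = sprintf("1-%d", bend$n_bp),
                        bend = bend$angle, degenerate = bend$degenerate),
             file.path(out_dir, "bend.tsv"))

  cov_maps <- lapply(setNames(nm = names(map$quarters)), function(q) {
    sel <- select_atoms(ens, chain_id = map$quarters[[q]]$protein_chain,
                        atom_name = "CA")
    cm <- covariance_map(ens, sel, fit_sel = NULL, window = ow)
    write_covariance_tsv(cm, file.path(out_dir,
                                       paste0("covariance_", q, ".tsv")))
    cm
  })

  files <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    parameters = unclass(config),
    n_frames = n_frames(ens), n_atoms = n_atoms(ens),
    quarters = names(map$quarters),
    outputs = lapply(setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(lys120 = k120, arg280 = r280, saltbridge = sb,
                 arg248 = r248, org = org, bend = bend,
                 covariance = cov_maps, manifest = manifest))
}

#' Simulation command
#'
#' Builds a template for the given half site, generates a synthetic
#' ensemble with the planted truth, and writes the fixture bundle
#' (multi-model PDB + mapping YAML + truth JSON).
#'
#' @param out_dir output directory.
#' @param half_site 10-bp half-site sequence.
#' @param truth a [planted_truth()]; its `seed` drives all randomness.
#' @param stem output file stem.
#' @return invisibly, the bundle paths.
#' @export
run_simulate <- function(out_dir, half_site = "GGGCATGCCC",
                         truth = planted_truth(), stem = "synthetic") {
  template <- build_template(half_site)
  gen <- generate_ensemble(template, truth)
  write_ensemble_bundle(gen, out_dir, stem)
}
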