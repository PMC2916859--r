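# Mapping configuration: binds protein chains/residue numbers and DNA
# chains/residues to quarter sites, registers which DNA residue is local
# position 1 of each quarter, and names the monitored contact atoms.
# Stored as a YAML key-value file so a run is reproducible from the file
# alone.

#' Read a quarter-site mapping configuration
#'
#' @param path YAML file path.
#' @return list of class `"p53_mapping"`.
#' @export
read_mapping <- function(path) {
  map <- yaml::read_yaml(path)
  validate_mapping(map)
}

#' Write a quarter-site mapping configuration
#'
#' @param map a `p53_mapping` list.
#' @param path output YAML path.
#' @return invisibly, `path`.
#' @export
write_mapping <- function(map, path) {
  yaml::write_yaml(unclass(map), path)
  invisible(path)
}

#' Validate a mapping configuration
#'
#' Checks the fields every analysis stage relies on: DNA chain ids, at
#' least one quarter entry, and per-quarter protein chain, residue
#' numbers, position registrations and organizational anchors.
#'
#' @param map a list (e.g. from [yaml::read_yaml()]).
#' @return the map, classed `"p53_mapping"`.
#' @export
validate_mapping <- function(map) {
  need <- function(ok, what)
    if (!isTRUE(ok)) stop("mapping configuration lacks ", what, call. = FALSE)
  need(!is.null(map$dna$ref_chain), "dna$ref_chain")
  need(!is.null(map$dna$comp_chain), "dna$comp_chain")
  need(length(map$quarters) >= 1, "at least one quarter entry")
  for (q in names(map$quarters)) {
    qq <- map$quarters[[q]]
    need(!is.null(qq$protein_chain), paste0(q, "$protein_chain"))
    need(!is.null(qq$residues), paste0(q, "$residues"))
    need(!is.null(qq$positions), paste0(q, "$positions"))
    need(!is.null(qq$org_anchors), paste0(q, "$org_anchors"))
  }
  class(map) <- c("p53_mapping", "list")
  map
}

# Resolve a {chain, resno} site plus atom name(s) to topology indices;
# errors name the contact when nothing resolves.
.resolve_site <- function(ens, site, atom_name, contact = "contact") {
  idx <- select_atoms(ens, chain_id = site$chain,
                      residue_number = site$resno, atom_name = atom_name)
  if (length(idx) == 0)
    stop(sprintf("mapping error: cannot resolve %s (chain %s resno %s atom %s)",
                 contact, site$chain, site$resno,
                 paste(atom_name, collapse = "/")), call. = FALSE)
  idx
}

# Protein residue atom resolution for a quarter entry.
.resolve_residue <- function(ens, qmap, resno, atom_name, contact = "residue") {
  idx <- select_atoms(ens, chain_id = qmap$protein_chain,
                      residue_number = resno, atom_name = atom_name)
  if (length(idx) == 0)
    stop(sprintf("mapping error: cannot resolve %s (chain %s resno %s atom %s)",
                 contact, qmap$protein_chain, resno,
                 paste(atom_name, collapse = "/")), call. = FALSE)
  idx
}

#' Major-groove hydrogen-bond acceptor atoms for a base
#'
#' G exposes O6 and N7 (the pair that supports a three-centered hydrogen
#' bond), A exposes N7, T exposes O4, and C has no major-groove acceptor.
#'
#' @param base one of `A`, `C`, `G`, `T`.
#' @return character vector of atom names (empty for C).
#' @export
major_groove_acceptors <- function(base) {
  switch(toupper(base),
         G = c("O6", "N7"),
         A = "N7",
         T = "O4",
         C = character(0),
         stop("unknown base: ", base))
}
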