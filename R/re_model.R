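# Response-element representation and consensus-motif scoring.
#
# A p53 response element (RE) is a 20-bp site of two palindromic 10-bp half
# sites; each half site splits into two 5-bp quarter sites, one per p53
# core-domain monomer.  On the reference strand a half site reads
# Pu-Pu-Pu-C-W | W-G-Py-Py-Py (Pu = A/G, Py = C/T, W = A/T).  Quarter sites
# Q1/Q3 carry the unprimed labels 1..5; Q2/Q4 carry 5'..1' because their
# monomer reads the opposite strand.

.BASES <- c("A", "C", "G", "T")

.CLASS_MEMBERS <- list(
  Pu = c("A", "G"),
  Py = c("C", "T"),
  W  = c("A", "T"),
  A = "A", C = "C", G = "G", T = "T"
)

#' The p53 half-site consensus motif
#'
#' Per-position base-class symbols for one 10-bp half site,
#' `Pu Pu Pu C W W G Py Py Py`; the full-site motif is the half-site motif
#' repeated.  The half-site motif is its own reverse complement under the
#' class mapping Pu<->Py, C<->G, W<->W.
#'
#' @param full logical; if `TRUE` (default) return the 20-position
#'   full-site motif, otherwise the 10-position half-site motif.
#' @return character vector of class symbols with S3 class
#'   `"consensus_motif"`.
#' @examples
#' consensus_motif(full = FALSE)
#' @export
consensus_motif <- function(full = TRUE) {
  half <- c("Pu", "Pu", "Pu", "C", "W", "W", "G", "Py", "Py", "Py")
  m <- if (full) rep(half, 2) else half
  class(m) <- "consensus_motif"
  m
}

#' Test a base for membership in a consensus class
#'
#' @param base single upper-case base.
#' @param class_symbol one of `Pu`, `Py`, `W`, `A`, `C`, `G`, `T`.
#' @return logical.
#' @export
base_in_class <- function(base, class_symbol) {
  members <- .CLASS_MEMBERS[[as.character(class_symbol)]]
  if (is.null(members))
    stop("unknown consensus class symbol: ", class_symbol)
  toupper(base) %in% members
}

.check_alphabet <- function(sequence, context = "sequence") {
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!chars %in% .BASES)
  if (length(bad) > 0)
    stop(sprintf("invalid character '%s' at position %d in %s",
                 chars[bad[1]], bad[1], context), call. = FALSE)
  chars
}

#' Quarter-site position labels
#'
#' Q1/Q3 positions are labelled `1..5` left to right on the reference
#' strand; Q2/Q4 columns are labelled `5'..1'` because the primed labels
#' name base pairs from the bound monomer's point of view.
#'
#' @param quarter one of `"Q1".."Q4"`.
#' @return character vector of 5 labels.
#' @export
quarter_labels <- function(quarter) {
  if (quarter %in% c("Q1", "Q3")) as.character(1:5)
  else if (quarter %in% c("Q2", "Q4")) paste0(5:1, "'")
  else stop("unknown quarter site: ", quarter)
}

#' Parse a 20-bp response-element sequence
#'
#' Tokenizes a 20-base reference-strand sequence into two 10-bp half sites
#' and four 5-bp quarter sites Q1..Q4 with their position labels.  Input
#' case is preserved for display (some published tables mark consensus
#' deviations in lower case) but ignored in all scoring.
#'
#' @param name element name (free text).
#' @param sequence 20 characters from `A,C,G,T` (case-insensitive; spaces
#'   are stripped).
#' @return object of class `"response_element"`: a list with `name`,
#'   `sequence` (upper case), `display_sequence` (input case),
#'   `half_sites` (length-2 character), `quarter_sites` (named length-4
#'   character) and `labels` (per-quarter position labels).
#' @examples
#' re <- parse_re("14-3-3sigma", "AGGCATGTGCCACCATGCCC")
#' re$quarter_sites
#' @export
parse_re <- function(name, sequence) {
  raw <- gsub("[[:space:]]", "", sequence)
  n <- nchar(raw)
  if (n != 20L)
    stop(sprintf("response-element sequence must have 20 bases, got %d", n),
         call. = FALSE)
  chars <- .check_alphabet(raw, context = paste0("RE '", name, "'"))
  seq_up <- paste(chars, collapse = "")
  quarters <- substring(seq_up, c(1, 6, 11, 16), c(5, 10, 15, 20))
  names(quarters) <- paste0("Q", 1:4)
  out <- list(
    name = name,
    sequence = seq_up,
    display_sequence = raw,
    half_sites = c(substr(seq_up, 1, 10), substr(seq_up, 11, 20)),
    quarter_sites = quarters,
    labels = lapply(setNames(nm = paste0("Q", 1:4)), quarter_labels)
  )
  class(out) <- "response_element"
  out
}

#' @export
print.response_element <- function(x, ...) {
  cat("p53 response element:", x$name, "\n")
  cat("  sequence   :", substr(x$sequence, 1, 10), substr(x$sequence, 11, 20), "\n")
  cat("  quarters   :", paste(names(x$quarter_sites), x$quarter_sites,
                              sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Score a response element against the consensus motif
#'
#' Tests every one of the 20 reference-strand positions for membership in
#' its consensus class.  Positions labelled W (A/T) accept either base
#' with no penalty; scoring is binary class membership, with no weights.
#'
#' @param re a `response_element` from [parse_re()].
#' @param motif a [consensus_motif()]; default the standard full-site motif.
#' @return object of class `"mismatch_report"`: list with `name`,
#'   `report` (data.frame: quarter, label, base, expected_class, match)
#'   and `mismatch_count`.
#' @examples
#' score_consensus(parse_re("GADD45", "GAACATGTCTAAGCATGCTG"))$mismatch_count
#' @export
score_consensus <- function(re, motif = consensus_motif()) {
  stopifnot(inherits(re, "response_element"))
  if (length(motif) != 20L)
    stop("full-site motif must have 20 positions")
  bases <- strsplit(re$sequence, "")[[1]]
  quarter <- rep(paste0("Q", 1:4), each = 5)
  label <- unlist(lapply(paste0("Q", 1:4), quarter_labels), use.names = FALSE)
  match <- mapply(base_in_class, bases, as.character(motif))
  rep <- data.frame(
    quarter = quarter, label = label, base = bases,
    expected_class = as.character(motif), match = unname(match),
    stringsAsFactors = FALSE
  )
  out <- list(name = re$name, report = rep,
              mismatch_count = sum(!rep$match))
  class(out) <- "mismatch_report"
  out
}

#' @export
print.mismatch_report <- function(x, ...) {
  cat("consensus mismatch report:", x$name,
      sprintf("(%d mismatching position%s)\n", x$mismatch_count,
              if (x$mismatch_count == 1) "" else "s"))
  bad <- x$report[!x$report$match, , drop = FALSE]
  if (nrow(bad) > 0) print(bad, row.names = FALSE)
  invisible(x)
}

#' Reverse complement of a DNA sequence
#'
#' Standard Watson-Crick reverse complement; upper-case `A,C,G,T` only.
#'
#' @param sequence character string.
#' @return character string.
#' @examples
#' reverse_complement("AGGCA")   # "TGCCT"
#' @export
reverse_complement <- function(sequence) {
  .check_alphabet(sequence)
  paste(rev(strsplit(chartr("ACGTacgt", "TGCATGCA", sequence), "")[[1]]),
        collapse = "")
}

#' Complement a single base
#' @param base single base character.
#' @return complementary base.
#' @export
complement_base <- function(base) {
  .check_alphabet(base)
  chartr("ACGT", "TGCA", toupper(base))
}

# Map a quarter-local position label to the global column on the reference
# strand (1..20) and the strand that physically carries the contacted base.
# Within a quarter, label k' names the base PAIRED with local position k:
# for Q1/Q3 the local (unprimed) strand is the global reference strand; for
# Q2/Q4 the local strand is the complementary chain and the primed partners
# sit on the reference strand.
.quarter_column <- function(quarter, k) {
  offset <- switch(quarter, Q1 = 0L, Q2 = 5L, Q3 = 10L, Q4 = 15L,
                   stop("unknown quarter site: ", quarter))
  if (quarter %in% c("Q1", "Q3")) offset + k else offset + (6L - k)
}

#' Resolve the contacted base for a quarter-site position label
#'
#' Returns the strand and base whose major-groove face a residue
#' approaches at a quarter-site position.  Unprimed labels resolve to the
#' quarter's local strand (read 5'->3' as Pu-Pu-Pu-C-W), primed labels to
#' the paired base on the opposite strand.  Label `"0"` denotes the base
#' pair immediately 5'-adjacent to local position 1 (used by the
#' organizational descriptor); it resolves on the local strand and, for
#' column indices outside the 20-mer, reports the base as `NA` (flanking
#' cap territory).
#'
#' The returned `strand` is reported in the quarter-local frame, matching
#' the published table layout: `"reference"` means the quarter's unprimed
#' strand, `"complementary"` the primed partner strand.  `global_strand`
#' and `column` give the absolute location on the 20-mer reference strand.
#'
#' @param re a `response_element`.
#' @param quarter `"Q1".."Q4"`.
#' @param label `"1".."5"`, `"1'".."5'"`, or `"0"` (prime accepted as
#'   `'`, `′` or `*`).
#' @param position0_offset integer shift (in bp along the local strand)
#'   applied to label `"0"`; default `-1` (immediately 5'-adjacent).
#' @return list with `strand`, `base`, `global_strand`, `column`.
#' @examples
#' re <- parse_re("14-3-3sigma", "AGGCATGTGCCACCATGCCC")
#' contact_partner(re, "Q1", "2")    # reference strand G
#' contact_partner(re, "Q2", "4'")   # primed partner, G
#' @export
contact_partner <- function(re, quarter, label, position0_offset = -1L) {
  stopifnot(inherits(re, "response_element"))
  lab <- gsub("[′*]", "'", as.character(label))
  primed <- grepl("'$", lab)
  k <- suppressWarnings(as.integer(sub("'$", "", lab)))
  if (is.na(k) || (k != 0 && !(k %in% 1:5)) || (k == 0 && primed))
    stop("unknown quarter-site position label: ", label, call. = FALSE)

  local_is_ref <- quarter %in% c("Q1", "Q3")
  if (!quarter %in% paste0("Q", 1:4))
    stop("unknown quarter site: ", quarter)

  if (k == 0L) {
    # bp adjacent (5' on the local strand) to local position 1
    col1 <- .quarter_column(quarter, 1L)
    step <- if (local_is_ref) position0_offset else -position0_offset
    col <- col1 + step
    base <- if (col >= 1 && col <= 20) {
      b <- substr(re$sequence, col, col)
      if (local_is_ref) b else complement_base(b)
    } else NA_character_
    return(list(strand = "reference", base = base,
                global_strand = if (local_is_ref) "reference" else "complementary",
                column = col))
  }

  col <- .quarter_column(quarter, k)
  ref_base <- substr(re$sequence, col, col)
  if (!primed) {
    # local strand base
    list(strand = "reference",
         base = if (local_is_ref) ref_base else complement_base(ref_base),
         global_strand = if (local_is_ref) "reference" else "complementary",
         column = col)
  } else {
    # paired base on the opposite (primed) strand
    list(strand = "complementary",
         base = if (local_is_ref) complement_base(ref_base) else ref_base,
         global_strand = if (local_is_ref) "complementary" else "reference",
         column = col)
  }
}

#' The six published p53 response elements
#'
#' Reference-strand sequences of the six naturally occurring response
#' elements analysed throughout the package examples: two each from the
#' cell-cycle-arrest, DNA-repair and apoptosis functional groups.
#'
#' @return data.frame with columns `name`, `group`, `sequence`.
#' @examples
#' vapply(seq_len(6), function(i) {
#'   re <- with(p53_response_elements()[i, ], parse_re(name, sequence))
#'   score_consensus(re)$mismatch_count
#' }, integer(1))
#' @export
p53_response_elements <- function() {
  data.frame(
    name = c("14-3-3sigma", "GADD45", "Noxa", "p21-5", "p53R2", "Puma"),
    group = c("cell cycle arrest", "DNA repair", "apoptosis",
              "cell cycle arrest", "DNA repair", "apoptosis"),
    sequence = c(
      "AGGCATGTGCCACCATGCCC",
      "GAACATGTCTAAGCATGCTG",
      "AGGCTTGCCCCGGCAAGTTG",
      "GAACATGCCCCAACATGTTG",
      "TGACATGCCCAGGCATGTCT",
      "CTGCAAGTCCTGACTTGTCC"
    ),
    stringsAsFactors = FALSE
  )
}

#' Read a response element from FASTA or plain text
#'
#' Accepts a single-record FASTA file (the header, minus `>`, becomes the
#' name) or a plain text file whose non-empty lines are concatenated.
#'
#' @param path file path.
#' @param name optional name overriding the FASTA header / file name.
#' @return a `response_element`.
#' @export
read_re <- function(path, name = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty sequence file: ", path)
  if (startsWith(lines[1], ">")) {
    header <- sub("^>\\s*", "", lines[1])
    seq <- paste(lines[-1], collapse = "")
    if (is.null(name)) name <- header
  } else {
    seq <- paste(lines, collapse = "")
    if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  }
  parse_re(name, seq)
}

#' Write a mismatch report as TSV and/or JSON
#'
#' @param report a `mismatch_report`.
#' @param tsv,json optional output paths (skipped when `NULL`).
#' @return invisibly, the report data.frame.
#' @export
write_mismatch_report <- function(report, tsv = NULL, json = NULL) {
  stopifnot(inherits(report, "mismatch_report"))
  if (!is.null(tsv))
    write.table(report$report, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(
      list(name = report$name, mismatch_count = report$mismatch_count,
           report = report$report),
      json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report$report)
}
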