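# Fixed amino-acid-change scan: alignment columns where a focal body-size
# group shares one residue and the background carnivores carry different
# residue(s), with gap/ambiguity exclusion and mapping of alignment columns
# to ungapped reference (human) coordinates for reporting and domain
# annotation.

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y")

#' Read a protein multiple alignment from FASTA
#'
#' @param path FASTA file of aligned amino-acid sequences (equal lengths;
#'   `-` for gaps).
#' @return Named character vector (species -> aligned sequence, uppercase).
#' @export
read_alignment_fasta <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("alignment file not found: %s", path))
  aa <- Biostrings::readAAStringSet(path)
  aln <- toupper(as.character(aa))
  names(aln) <- sub("\\s.*$", "", names(aa))
  validate_alignment(aln)
}

#' Write a protein alignment to FASTA
#' @param aln Named character vector of aligned sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  aln <- validate_alignment(aln)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(aln), path, width = 70L)
  invisible(path)
}

#' @keywords internal
validate_alignment <- function(aln) {
  if (inherits(aln, "AAStringSet")) aln <- toupper(as.character(aln))
  if (!is.character(aln) || is.null(names(aln)) || any(!nzchar(names(aln)))) {
    abort_data("alignment must be a named character vector")
  }
  if (anyDuplicated(names(aln))) abort_data("duplicate species in alignment")
  len <- unique(nchar(aln))
  if (length(len) != 1L || len < 1L) {
    abort_data("alignment rows must all have the same positive length")
  }
  bad <- setdiff(unique(strsplit(paste(aln, collapse = ""), "")[[1L]]),
                 c(AA_ALPHABET, "-", "X", "*"))
  if (length(bad)) {
    abort_data(sprintf("unexpected alignment character(s): %s",
                       paste(bad, collapse = " ")))
  }
  aln
}

#' @keywords internal
alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln), ""))
}

#' Scan an alignment for group-fixed amino acid changes
#'
#' Finds columns where every focal species carries the same residue and the
#' background disagrees. In `strict` mode (default) the background must
#' itself be uniform on a single different residue — the pattern behind
#' substitution labels like "S513L". In `relaxed` mode the background rows
#' may vary as long as none carries the focal residue. Columns containing a
#' gap (`-`) or ambiguity (`X`, `*`) in any focal or background row are
#' excluded: an ambiguous column cannot certify fixation. Rows outside
#' `focal` and `background` (outgroups, the reference) are ignored by the
#' scan itself.
#'
#' @param aln Named character vector (see [read_alignment_fasta()]).
#' @param focal Focal species labels (>= 2, all present in `aln`).
#' @param background Background species labels (disjoint from `focal`).
#' @param mode `"strict"` or `"relaxed"`.
#' @return `data.frame` with column (1-based alignment coordinate),
#'   focal_residue, background_residue (unique background residues,
#'   collapsed with `/` in relaxed mode).
#' @export
scan_fixed_changes <- function(aln, focal, background,
                               mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  aln <- validate_alignment(aln)
  if (length(focal) < 2L) abort_config("need at least 2 focal species")
  if (length(intersect(focal, background))) {
    abort_config("focal and background sets must be disjoint")
  }
  missing <- setdiff(c(focal, background), names(aln))
  if (length(missing)) {
    abort_data(sprintf("species missing from alignment: %s",
                       paste(missing, collapse = ", ")))
  }
  M <- alignment_matrix(aln[c(focal, background)])
  fg <- M[seq_along(focal), , drop = FALSE]
  bg <- M[length(focal) + seq_along(background), , drop = FALSE]
  excluded_chars <- c("-", "X", "*")
  hits <- list()
  for (j in seq_len(ncol(M))) {
    col_fg <- fg[, j]
    col_bg <- bg[, j]
    if (any(c(col_fg, col_bg) %in% excluded_chars)) next
    a <- unique(col_fg)
    if (length(a) != 1L) next
    b <- unique(col_bg)
    ok <- if (mode == "strict") length(b) == 1L && b != a else !(a %in% b)
    if (!ok) next
    hits[[length(hits) + 1L]] <- data.frame(
      column = j, focal_residue = a,
      background_residue = paste(sort(b), collapse = "/"),
      stringsAsFactors = FALSE)
  }
  if (!length(hits)) {
    return(data.frame(column = integer(0), focal_residue = character(0),
                      background_residue = character(0)))
  }
  do.call(rbind, hits)
}

#' Map alignment columns to ungapped reference coordinates
#'
#' The reference position of an alignment column is the count of non-gap
#' reference residues in columns 1..column — i.e. the 1-based position in
#' the ungapped reference sequence (human numbering when the reference row
#' is human). Returns `NA` where the reference itself has a gap.
#'
#' @param aln Named character vector alignment.
#' @param ref_species Label of the reference row.
#' @param column Integer vector of 1-based alignment columns.
#' @return Integer vector of reference positions (`NA` at reference gaps).
#' @export
map_to_reference <- function(aln, ref_species, column) {
  aln <- validate_alignment(aln)
  if (!(ref_species %in% names(aln))) {
    abort_data(sprintf("reference species '%s' not in alignment", ref_species))
  }
  ref <- strsplit(aln[[ref_species]], "")[[1L]]
  if (any(column < 1L | column > length(ref))) {
    abort_data("alignment column out of range")
  }
  cum <- cumsum(ref != "-")
  pos <- cum[column]
  pos[ref[column] == "-"] <- NA_integer_
  as.integer(pos)
}

#' Annotate fixed-change sites with protein domains
#'
#' Domain intervals come from upstream annotation (e.g. Pfam scans of the
#' reference protein) as 1-based inclusive ranges in reference coordinates;
#' each site gains the name of any covering interval.
#'
#' @param sites `data.frame` with a `ref_position` column (as produced by
#'   [fixed_change_sites()]).
#' @param domains `data.frame` with columns name, start, end (1-based
#'   inclusive, reference coordinates); may be empty.
#' @return `sites` with a `domain` column (`NA` when uncovered).
#' @export
annotate_domains <- function(sites, domains) {
  if (is.null(domains) || nrow(domains) == 0L) {
    sites$domain <- rep(NA_character_, nrow(sites))
    return(sites)
  }
  miss <- setdiff(c("name", "start", "end"), names(domains))
  if (length(miss)) {
    abort_data(sprintf("domain table missing column(s): %s",
                       paste(miss, collapse = ", ")))
  }
  if (any(domains$start > domains$end)) abort_data("domain interval with start > end")
  sites$domain <- vapply(sites$ref_position, function(p) {
    if (is.na(p)) return(NA_character_)
    hit <- domains$name[domains$start <= p & p <= domains$end]
    if (length(hit)) hit[1L] else NA_character_
  }, character(1))
  sites
}

#' Full fixed-change site report for one gene alignment
#'
#' Combines the scan, reference-coordinate mapping and substitution labels
#' ("S513L" style: background residue, reference position, focal residue;
#' only emitted when the background residue is unique and the reference
#' position defined — otherwise the site is still reported with its
#' alignment coordinate).
#'
#' @param aln Named character vector alignment.
#' @param focal,background,mode As in [scan_fixed_changes()].
#' @param ref_species Optional reference row label for coordinate mapping.
#' @param domains Optional domain interval table (see [annotate_domains()]).
#' @param gene Gene id carried into the output.
#' @return `data.frame`: gene, column, ref_position, label, focal_residue,
#'   background_residue, domain.
#' @export
fixed_change_sites <- function(aln, focal, background, mode = "strict",
                               ref_species = NULL, domains = NULL,
                               gene = NA_character_) {
  sites <- scan_fixed_changes(aln, focal, background, mode = mode)
  n <- nrow(sites)
  sites$gene <- rep(gene, n)
  sites$ref_position <- if (!is.null(ref_species) && n) {
    map_to_reference(aln, ref_species, sites$column)
  } else {
    rep(NA_integer_, n)
  }
  single_bg <- !grepl("/", sites$background_residue, fixed = TRUE)
  sites$label <- ifelse(
    single_bg & !is.na(sites$ref_position),
    paste0(sites$background_residue, sites$ref_position, sites$focal_residue),
    NA_character_)
  sites <- annotate_domains(sites, domains)
  sites[c("gene", "column", "ref_position", "label", "focal_residue",
          "background_residue", "domain")]
}
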