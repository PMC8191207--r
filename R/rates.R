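# Per-gene, per-branch dN/dS ingestion and the root-to-tip omega statistic.
#
# A branch-rates table is the surrogate for free-ratio codon-model output:
# one row per gene x branch with dN, dS and omega = dN/dS. The per-species
# statistic is the unweighted mean of omega over the branches on the path
# from the root to that species' tip, after discarding branches whose dN or
# dS falls below a detection threshold (default 0.0002): at such low
# divergence the omega ratio is numerically unstable and would distort the
# path average.

#' Is a branch's rate estimate usable?
#'
#' A branch contributes to the root-to-tip average only when both dN and dS
#' reach the threshold; "less than" is strict, so values exactly at the
#' threshold are kept.
#'
#' @param dN,dS Non-negative substitution-rate estimates (subst/site).
#' @param threshold Minimum acceptable dN and dS (default 2e-4).
#' @return Logical vector.
#' @export
branch_is_valid <- function(dN, dS, threshold = 2e-4) {
  if (any(!is.na(dN) & dN < 0) || any(!is.na(dS) & dS < 0)) {
    abort_data("dN and dS must be non-negative")
  }
  !is.na(dN) & !is.na(dS) & dN >= threshold & dS >= threshold
}

#' @keywords internal
validate_rates_table <- function(rates) {
  req <- c("gene", "branch", "dN", "dS")
  miss <- setdiff(req, names(rates))
  if (length(miss)) {
    abort_data(sprintf("rates table missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (nrow(rates) == 0L) {   # header-only files read back as logical columns
    for (col in c("dN", "dS", "omega")) {
      if (col %in% names(rates)) rates[[col]] <- as.numeric(rates[[col]])
    }
    for (col in c("gene", "branch")) rates[[col]] <- as.character(rates[[col]])
  }
  for (col in c("dN", "dS")) {
    if (!is.numeric(rates[[col]])) abort_data(sprintf("column '%s' must be numeric", col))
  }
  if (!("omega" %in% names(rates))) {
    rates$omega <- ifelse(rates$dS > 0, rates$dN / rates$dS, NA_real_)
  }
  if (!is.numeric(rates$omega)) abort_data("column 'omega' must be numeric")
  key <- paste(rates$gene, rates$branch, sep = "\r")
  if (anyDuplicated(key)) {
    d <- rates[duplicated(key), , drop = FALSE][1L, ]
    abort_data(sprintf("duplicate gene x branch row: %s / %s", d$gene, d$branch))
  }
  rates
}

#' Read a branch-rates table from TSV
#'
#' Expects columns `gene`, `branch`, `dN`, `dS` and optionally `omega`
#' (recomputed as `dN/dS` when absent; `dS = 0` leaves omega `NA`, and the
#' branch is excluded by the validity rule rather than raising a division
#' error).
#'
#' @param path Path to a tab-separated file.
#' @return A `data.frame` with columns gene, branch, dN, dS, omega.
#' @export
read_rates_tsv <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("rates file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA", check.names = FALSE)
  validate_rates_table(df)
}

#' Write a branch-rates table to TSV
#' @param rates A branch-rates `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rates_tsv <- function(rates, path) {
  rates <- validate_rates_table(rates)
  write_tsv_na(rates[c("gene", "branch", "dN", "dS", "omega")], path)
}

# TSV writer used throughout: literal "NA" for missing, LF endings, no quotes.
#' @keywords internal
write_tsv_na <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-species root-to-tip omega
#'
#' For each gene and each tip, averages branch omega over the valid branches
#' on the root-to-tip path (unweighted arithmetic mean) and log10-transforms
#' the result. A branch is invalid when dN or dS is below `threshold` or
#' when the branch is absent from the rates table; invalid branches are
#' simply dropped from the average. A species with no valid path branch gets
#' `NA` and is excluded from downstream regression.
#'
#' @param tree A labeled `phylo` object (see [parse_newick()]).
#' @param rates Branch-rates `data.frame` (gene, branch, dN, dS\[, omega\]).
#' @param threshold dN/dS validity threshold (default 2e-4).
#' @return `data.frame` with gene, species, omega_bar, log10_omega_bar,
#'   n_valid_branches.
#' @export
root_to_tip_omega <- function(tree, rates, threshold = 2e-4) {
  if (is.null(tree$node.label)) tree <- label_internal_nodes(tree)
  rates <- validate_rates_table(rates)
  all_ids <- node_labels(tree)
  unknown <- setdiff(unique(rates$branch), all_ids)
  if (length(unknown)) {
    abort_data(sprintf("branch id(s) absent from tree: %s",
                       paste(unknown, collapse = ", ")))
  }
  tips <- tree$tip.label
  paths <- lapply(tips, function(tp) root_to_tip_path(tree, tp))
  names(paths) <- tips

  genes <- unique(rates$gene)
  if (length(genes) == 0L) {
    return(data.frame(gene = character(0), species = character(0),
                      omega_bar = numeric(0), log10_omega_bar = numeric(0),
                      n_valid_branches = integer(0)))
  }
  out <- vector("list", length(genes))
  for (g in seq_along(genes)) {
    sub <- rates[rates$gene == genes[g], , drop = FALSE]
    valid <- branch_is_valid(sub$dN, sub$dS, threshold) & !is.na(sub$omega)
    om <- stats::setNames(ifelse(valid, sub$omega, NA_real_), sub$branch)
    rows <- lapply(tips, function(tp) {
      vals <- om[paths[[tp]]]       # missing branch -> NA -> invalid
      vals <- vals[!is.na(vals)]
      n <- length(vals)
      ob <- if (n) mean(vals) else NA_real_
      data.frame(gene = genes[g], species = tp, omega_bar = ob,
                 log10_omega_bar = if (n) log10(ob) else NA_real_,
                 n_valid_branches = n, stringsAsFactors = FALSE)
    })
    out[[g]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read a root-to-tip table
#' @param rtt Root-to-tip `data.frame` from [root_to_tip_omega()].
#' @param path TSV path.
#' @return `path` (write) or the table (read).
#' @export
write_rtt_tsv <- function(rtt, path) {
  write_tsv_na(rtt[c("gene", "species", "omega_bar", "log10_omega_bar",
                     "n_valid_branches")], path)
}

#' @rdname write_rtt_tsv
#' @export
read_rtt_tsv <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("root-to-tip file not found: %s", path))
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, na.strings = "NA")
}
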