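# Rapidly-evolving-gene (REG) layer: likelihood-ratio test of a two-ratio
# branch model (separate foreground/background omega) against the one-ratio
# null, Benjamini-Hochberg FDR across genes within a foreground group, and
# the foreground-faster decision rule. The log-likelihoods arrive as a
# table (codon-model optimization happens upstream, outside this package).

#' Likelihood-ratio test of nested branch models
#'
#' `stat = 2 * (lnL1 - lnL0)` compared to a chi-square distribution with
#' `df = k1 - k0` degrees of freedom (default 1: the two-ratio model frees
#' one extra omega). Tiny negative differences (optimizer noise, up to
#' 1e-6) are clamped to zero; larger ones indicate a failed upstream
#' optimization and raise an error.
#'
#' @param lnL0,lnL1 Log-likelihoods of the null (one-ratio) and alternative
#'   (two-ratio) models. Vectorized.
#' @param df Degrees of freedom (default 1).
#' @return `data.frame` with columns `stat` and `p`.
#' @export
lrt <- function(lnL0, lnL1, df = 1) {
  if (any(df < 1)) abort_config("df must be >= 1")
  delta <- lnL1 - lnL0
  if (any(delta < -1e-6)) {
    i <- which(delta < -1e-6)[1L]
    abort_data(sprintf(
      "lnL1 < lnL0 (delta = %.6g) at record %d: models not nested or optimization failed",
      delta[i], i))
  }
  stat <- pmax(2 * delta, 0)
  data.frame(stat = stat, p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-aligned with the input (a thin wrapper
#' over [stats::p.adjust()] with input validation).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort_data("p-values must be in [0, 1] with no NA")
  }
  stats::p.adjust(p, method = "BH")
}

#' @keywords internal
validate_branch_records <- function(records) {
  req <- c("gene", "group", "lnL0", "lnL1", "omega_fg", "omega_bg")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    abort_data(sprintf("branch-model table missing column(s): %s",
                       paste(miss, collapse = ", ")))
  }
  if (any(records$omega_fg < 0, na.rm = TRUE) ||
      any(records$omega_bg < 0, na.rm = TRUE)) {
    abort_data("omega values must be non-negative")
  }
  if (!("k0" %in% names(records))) records$k0 <- 1L
  if (!("k1" %in% names(records))) records$k1 <- records$k0 + 1L
  key <- paste(records$group, records$gene, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), ][1L, ]
    abort_data(sprintf("duplicate gene within group: %s / %s", d$group, d$gene))
  }
  records
}

#' Call rapidly evolving genes from branch-model records
#'
#' For each record, computes the LRT of the two-ratio vs one-ratio model. A
#' gene is a REG (`is_reg`) when its foreground omega exceeds the
#' background omega and the raw LRT p-value is below `alpha`; `is_reg_fdr`
#' additionally requires the Benjamini-Hochberg adjusted p-value (computed
#' within each foreground group separately) to be below `alpha`.
#'
#' @param records `data.frame` with columns gene, group, lnL0, lnL1,
#'   omega_fg, omega_bg and optionally k0, k1.
#' @param alpha Significance threshold (default 0.05).
#' @return `data.frame` adding stat, p_value, p_adjusted, is_reg,
#'   is_reg_fdr; one row per input record, input order preserved.
#' @export
classify_regs <- function(records, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) abort_config("alpha must be in (0, 1)")
  records <- validate_branch_records(records)
  tst <- lrt(records$lnL0, records$lnL1, df = records$k1 - records$k0)
  records$stat <- tst$stat
  records$p_value <- tst$p
  records$p_adjusted <- NA_real_
  for (grp in unique(records$group)) {
    i <- records$group == grp
    records$p_adjusted[i] <- bh_fdr(records$p_value[i])
  }
  records$is_reg <- records$omega_fg > records$omega_bg &
    records$p_value < alpha
  records$is_reg_fdr <- records$is_reg & records$p_adjusted < alpha
  records
}

#' Assign body-size groups from phenotypes
#'
#' Thresholds follow the study design for carnivorans:
#' `extremely_large` = body mass > 350 kg; `small` = body mass < 12 kg AND
#' head-body length < 1 m; `extremely_small` = body mass < 1 kg (a subset
#' of small, reported as a separate logical); everything else is
#' `background`. Species with a missing phenotype are labeled `unassigned`.
#'
#' @param phenotypes `data.frame` with `species`, `head_body_length_cm`,
#'   `body_mass_g`.
#' @return `data.frame` with species, group
#'   (extremely_large/small/background/unassigned) and logical
#'   `extremely_small`.
#' @export
assign_size_groups <- function(phenotypes) {
  req <- c("species", "head_body_length_cm", "body_mass_g")
  miss <- setdiff(req, names(phenotypes))
  if (length(miss)) {
    abort_data(sprintf("phenotype table missing column(s): %s",
                       paste(miss, collapse = ", ")))
  }
  mass <- phenotypes$body_mass_g
  len <- phenotypes$head_body_length_cm
  group <- rep("background", nrow(phenotypes))
  group[!is.na(mass) & mass > 350e3] <- "extremely_large"
  group[!is.na(mass) & !is.na(len) & mass < 12e3 & len < 100] <- "small"
  unassigned <- is.na(mass) | is.na(len)
  group[unassigned] <- "unassigned"
  data.frame(
    species = phenotypes$species, group = group,
    extremely_small = !unassigned & mass < 1e3 & group == "small",
    stringsAsFactors = FALSE)
}

#' Focal species set for the fixed-change scan
#'
#' The extremely small species (mass < 1 kg within the small group), topped
#' up with the lightest remaining species when fewer than two qualify, so a
#' focal group always exists.
#'
#' @param phenotypes Phenotype table (`species`, `head_body_length_cm`,
#'   `body_mass_g`).
#' @return Character vector of focal species labels (length >= 2).
#' @export
derive_focal_species <- function(phenotypes) {
  groups <- assign_size_groups(phenotypes)
  focal <- groups$species[groups$extremely_small]
  if (length(focal) < 2L) {
    ord <- phenotypes$species[order(phenotypes$body_mass_g)]
    focal <- utils::head(unique(c(focal, ord)), 2L)
  }
  focal
}

#' Read / write branch-model record tables
#' @param path TSV path with columns gene, group, lnL0, lnL1, omega_fg,
#'   omega_bg \[, k0, k1\].
#' @return The validated `data.frame` (read) or `path` (write).
#' @export
read_branch_records_tsv <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("branch-model file not found: %s", path))
  validate_branch_records(utils::read.delim(path, sep = "\t",
                                            stringsAsFactors = FALSE,
                                            na.strings = "NA"))
}

#' @rdname read_branch_records_tsv
#' @param records Branch-model `data.frame`.
#' @export
write_branch_records_tsv <- function(records, path) {
  write_tsv_na(validate_branch_records(records), path)
}
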