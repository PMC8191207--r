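# Two-step P-value calibration and the dual-phenotype BSAG decision.
#
# Rather than correcting the genome scan for multiple testing, each gene x
# phenotype regression is stress-tested for robustness to single species:
#   P.all    -- PGLS p-value over all usable species;
#   P.robust -- p-value after discarding the species with the largest
#               absolute residual from the full fit;
#   P.max    -- the maximum p-value over refits that each drop one species.
# A gene is a body-size-associated gene (BSAG) when all three p-values fall
# below alpha for BOTH phenotypes (head-body length and body mass); its
# direction is the sign of the body-mass slope.

#' Two-step robustness calibration of one gene x phenotype regression
#'
#' Runs the full PGLS fit, the "robust" refit without the largest-residual
#' species, and the family of leave-one-out refits whose maximum p-value is
#' reported. The phylogenetic covariance is re-restricted (and lambda
#' re-estimated) at every refit. In the default `"drop-from-full"` mode the
#' leave-one-out refits each drop one species from the full set; the
#' alternative `"drop-from-robust"` mode drops each remaining species from
#' the already-reduced robust set (fits of size n - 2).
#'
#' @param rtt_gene Root-to-tip rows for one gene (`species`,
#'   `log10_omega_bar`).
#' @param phenotype Named numeric vector of raw phenotype values.
#' @param tree A labeled `phylo` object.
#' @param mode `"drop-from-full"` (default) or `"drop-from-robust"`.
#' @param min_species Minimum species for any fit; refits that would fall
#'   below it mark the result incomplete.
#' @param lambda Optional fixed lambda passed through to [pgls_gene()].
#' @param residual_scale `"raw"` (default) identifies the dropped species by
#'   the largest absolute raw residual; `"whitened"` uses the
#'   covariance-whitened residuals instead.
#' @return An object of class `calibration_result`: gene-agnostic list with
#'   p_all, p_robust, p_max, slope_all, lambda_all, dropped_species,
#'   leave_one_out (data.frame species/p), n_used, complete.
#' @export
two_step_calibration <- function(rtt_gene, phenotype, tree,
                                 mode = c("drop-from-full", "drop-from-robust"),
                                 min_species = 10, lambda = NULL,
                                 residual_scale = c("raw", "whitened")) {
  mode <- match.arg(mode)
  residual_scale <- match.arg(residual_scale)
  incomplete <- function(reason) {
    structure(list(p_all = NA_real_, p_robust = NA_real_, p_max = NA_real_,
                   slope_all = NA_real_, lambda_all = NA_real_,
                   dropped_species = NA_character_,
                   leave_one_out = data.frame(species = character(0),
                                              p = numeric(0)),
                   n_used = 0L, complete = FALSE, reason = reason),
              class = "calibration_result")
  }
  full <- pgls_gene(rtt_gene, phenotype, tree, min_species = min_species,
                    lambda = lambda)
  if (is.null(full)) return(incomplete("too few species for full fit"))
  n <- full$n
  if (n < min_species + 2L) {
    return(incomplete("too few species for leave-one-out refits"))
  }
  species <- full$species
  res <- full$residuals
  if (residual_scale == "whitened") {
    C <- vcv_matrix(tree, species)
    U <- chol(lambda_transform(C, full$lambda_hat))
    res <- stats::setNames(as.numeric(backsolve(U, res, transpose = TRUE)),
                           species)
  }
  dropped <- species[which.max(abs(res))]

  refit_without <- function(drop_set) {
    keep <- setdiff(species, drop_set)
    sub <- rtt_gene[rtt_gene$species %in% keep, , drop = FALSE]
    pgls_gene(sub, phenotype, tree, min_species = min_species, lambda = lambda)
  }
  robust <- refit_without(dropped)
  if (is.null(robust)) return(incomplete("robust refit below minimum species"))

  loo_base <- if (mode == "drop-from-full") species else setdiff(species, dropped)
  extra_drop <- if (mode == "drop-from-full") character(0) else dropped
  loo_p <- vapply(loo_base, function(sp) {
    f <- refit_without(c(extra_drop, sp))
    if (is.null(f)) NA_real_ else f$p_value
  }, numeric(1))
  if (anyNA(loo_p)) return(incomplete("leave-one-out refit below minimum species"))

  structure(list(
    p_all = full$p_value, p_robust = robust$p_value, p_max = max(loo_p),
    slope_all = full$slope, lambda_all = full$lambda_hat,
    dropped_species = dropped,
    leave_one_out = data.frame(species = loo_base, p = unname(loo_p),
                               stringsAsFactors = FALSE),
    n_used = n, complete = TRUE, reason = NA_character_
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  if (!x$complete) {
    cat("Calibration incomplete:", x$reason, "\n")
  } else {
    cat(sprintf(
      "Calibration: n = %d, slope = %.4g, P.all = %.3g, P.robust = %.3g (drop %s), P.max = %.3g\n",
      x$n_used, x$slope_all, x$p_all, x$p_robust, x$dropped_species, x$p_max))
  }
  invisible(x)
}

#' @keywords internal
calibration_significant <- function(res, alpha) {
  isTRUE(res$complete) && !anyNA(c(res$p_all, res$p_robust, res$p_max)) &&
    res$p_all < alpha && res$p_robust < alpha && res$p_max < alpha
}

#' Dual-phenotype BSAG decision for one gene
#'
#' A gene is called a body-size-associated gene when all six calibrated
#' p-values (P.all, P.robust, P.max for head-body length and for body mass)
#' fall below `alpha`. The reported direction follows the sign of the
#' body-mass slope; if the two phenotype slopes disagree the record is kept
#' but flagged `sign_concordant = FALSE`.
#'
#' @param res_length,res_mass `calibration_result`s for the two phenotypes.
#' @param alpha Significance threshold (default 0.05).
#' @param gene Optional gene id carried into the record.
#' @return A list of class `bsag_record`, or `NULL` when not significant.
#' @export
classify_bsag <- function(res_length, res_mass, alpha = 0.05, gene = NA_character_) {
  if (!(alpha > 0 && alpha < 1)) abort_config("alpha must be in (0, 1)")
  if (!calibration_significant(res_length, alpha) ||
      !calibration_significant(res_mass, alpha)) {
    return(NULL)
  }
  direction <- if (res_mass$slope_all > 0) "positive" else "negative"
  structure(list(
    gene = gene, direction = direction,
    sign_concordant = sign(res_length$slope_all) == sign(res_mass$slope_all),
    length = res_length, mass = res_mass
  ), class = "bsag_record")
}

#' Genome-wide BSAG scan
#'
#' Runs the two-step calibration for every gene against both phenotypes and
#' applies the dual-phenotype decision rule. Genes whose calibration is
#' incomplete (too few usable species) are reported in the per-gene table
#' with their skip reason and never abort the scan.
#'
#' @param rtt Root-to-tip table ([root_to_tip_omega()]) covering all genes.
#' @param phenotypes `data.frame` with columns `species`,
#'   `head_body_length_cm`, `body_mass_g`.
#' @param tree A labeled `phylo` object.
#' @param alpha Significance threshold (default 0.05).
#' @param min_species,mode,lambda Passed to [two_step_calibration()].
#' @return A list of class `bsag_scan`: `bsag` (one row per called gene),
#'   `per_gene` (full calibration report), and `counts`
#'   (n_genes, n_sig_length, n_sig_mass, n_bsag, n_positive, n_negative).
#' @export
scan_genome <- function(rtt, phenotypes, tree, alpha = 0.05, min_species = 10,
                        mode = "drop-from-full", lambda = NULL) {
  if (!(alpha > 0 && alpha < 1)) abort_config("alpha must be in (0, 1)")
  req <- c("species", "head_body_length_cm", "body_mass_g")
  miss <- setdiff(req, names(phenotypes))
  if (length(miss)) {
    abort_data(sprintf("phenotype table missing column(s): %s",
                       paste(miss, collapse = ", ")))
  }
  ph_len <- stats::setNames(phenotypes$head_body_length_cm, phenotypes$species)
  ph_mass <- stats::setNames(phenotypes$body_mass_g, phenotypes$species)
  genes <- unique(rtt$gene)

  per_gene <- vector("list", length(genes))
  bsag_rows <- list()
  n_sig_len <- 0L; n_sig_mass <- 0L
  for (i in seq_along(genes)) {
    g <- genes[i]
    rg <- rtt[rtt$gene == g, , drop = FALSE]
    cal_l <- two_step_calibration(rg, ph_len, tree, mode = mode,
                                  min_species = min_species, lambda = lambda)
    cal_m <- two_step_calibration(rg, ph_mass, tree, mode = mode,
                                  min_species = min_species, lambda = lambda)
    sig_l <- calibration_significant(cal_l, alpha)
    sig_m <- calibration_significant(cal_m, alpha)
    n_sig_len <- n_sig_len + sig_l
    n_sig_mass <- n_sig_mass + sig_m
    rec <- classify_bsag(cal_l, cal_m, alpha = alpha, gene = g)
    per_gene[[i]] <- data.frame(
      gene = g, n_length = cal_l$n_used, n_mass = cal_m$n_used,
      slope_length = cal_l$slope_all, slope_mass = cal_m$slope_all,
      lambda_length = cal_l$lambda_all, lambda_mass = cal_m$lambda_all,
      p_all_length = cal_l$p_all, p_robust_length = cal_l$p_robust,
      p_max_length = cal_l$p_max,
      p_all_mass = cal_m$p_all, p_robust_mass = cal_m$p_robust,
      p_max_mass = cal_m$p_max,
      sig_length = sig_l, sig_mass = sig_m, is_bsag = !is.null(rec),
      skip_reason = if (!cal_l$complete) cal_l$reason
                    else if (!cal_m$complete) cal_m$reason else NA_character_,
      stringsAsFactors = FALSE)
    if (!is.null(rec)) {
      bsag_rows[[length(bsag_rows) + 1L]] <- data.frame(
        gene = g, direction = rec$direction,
        sign_concordant = rec$sign_concordant,
        slope_length = cal_l$slope_all, slope_mass = cal_m$slope_all,
        lambda_length = cal_l$lambda_all, lambda_mass = cal_m$lambda_all,
        p_all_length = cal_l$p_all, p_robust_length = cal_l$p_robust,
        p_max_length = cal_l$p_max,
        p_all_mass = cal_m$p_all, p_robust_mass = cal_m$p_robust,
        p_max_mass = cal_m$p_max, stringsAsFactors = FALSE)
    }
  }
  per_gene <- if (length(per_gene)) do.call(rbind, per_gene) else
    data.frame(gene = character(0))
  bsag <- if (length(bsag_rows)) do.call(rbind, bsag_rows) else
    data.frame(gene = character(0), direction = character(0),
               sign_concordant = logical(0))
  counts <- list(n_genes = length(genes), n_sig_length = n_sig_len,
                 n_sig_mass = n_sig_mass, n_bsag = nrow(bsag),
                 n_positive = sum(bsag$direction == "positive"),
                 n_negative = sum(bsag$direction == "negative"))
  stopifnot(counts$n_bsag <= min(counts$n_sig_length, counts$n_sig_mass))
  structure(list(bsag = bsag, per_gene = per_gene, counts = counts),
            class = "bsag_scan")
}

#' @export
print.bsag_scan <- function(x, ...) {
  with(x$counts, cat(sprintf(
    "BSAG scan: %d genes; %d significant vs length, %d vs mass; %d BSAGs (%d positive, %d negative)\n",
    n_genes, n_sig_length, n_sig_mass, n_bsag, n_positive, n_negative)))
  invisible(x)
}
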