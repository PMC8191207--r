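# Orchestration: a validated run configuration plus the five pipeline
# commands (simulate, scan, branch-test, fixed-changes, all). Each command
# is an ordinary R function over the module layer; the thin command-line
# wrapper in inst/cli/ maps subcommands and flags onto them. All tabular
# outputs are TSV with a literal "NA" for missing values, UTF-8, LF line
# endings; every simulation-driven run writes a manifest (config + seed)
# from which its outputs are bit-identically re-derivable.

#' Build and validate a pipeline run configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param tree,phenotypes,rates,alignments_dir,lrt_records Input paths
#'   (Newick, phenotype TSV, branch-rates TSV, directory of FASTA
#'   alignments, branch-model TSV). Defaults point inside `out_dir`, which
#'   is where [cmd_simulate()] writes them.
#' @param alpha Significance threshold in (0, 1), default 0.05.
#' @param threshold Branch dN/dS validity threshold, default 2e-4.
#' @param min_species Minimum species per gene regression, default 10.
#' @param calibration_mode `"drop-from-full"` or `"drop-from-robust"`.
#' @param scan_mode Fixed-change scan mode, `"strict"` or `"relaxed"`.
#' @param focal_species,background_species Optional explicit species sets
#'   for the fixed-change scan; by default the focal set is the extremely
#'   small group derived from the phenotype table and the background is
#'   every other phenotyped species.
#' @param ref_species Optional reference row label for coordinate mapping.
#' @param seed Integer seed for simulation-driven runs.
#' @param sim Optional list of [simulation_config()] overrides.
#' @param verbose Emit progress messages (default TRUE).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir = "carnsize_out",
                       tree = file.path(out_dir, "tree.nwk"),
                       phenotypes = file.path(out_dir, "phenotypes.tsv"),
                       rates = file.path(out_dir, "rates.tsv"),
                       alignments_dir = file.path(out_dir, "alignments"),
                       lrt_records = file.path(out_dir, "lrt_records.tsv"),
                       alpha = 0.05, threshold = 2e-4, min_species = 10,
                       calibration_mode = "drop-from-full",
                       scan_mode = "strict",
                       focal_species = NULL, background_species = NULL,
                       ref_species = NULL, seed = 1, sim = list(),
                       verbose = TRUE) {
  cfg <- as.list(environment())
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort_config("alpha must be in (0, 1)")
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    abort_config("threshold must be positive")
  }
  if (!calibration_mode %in% c("drop-from-full", "drop-from-robust")) {
    abort_config("calibration_mode must be drop-from-full or drop-from-robust")
  }
  if (!scan_mode %in% c("strict", "relaxed")) {
    abort_config("scan_mode must be strict or relaxed")
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; `overrides`
#' (typically command-line flags) take precedence over file values.
#'
#' @param path YAML file path.
#' @param overrides Named list overriding file values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) abort_config(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) abort_config("config file must contain a YAML mapping")
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort_config(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' @keywords internal
write_manifest <- function(config, out_dir, stage, extra = list()) {
  keep <- config[!vapply(config, is.null, logical(1))]
  keep <- keep[!names(keep) %in% "verbose"]
  manifest <- c(list(stage = stage, package_version =
                       as.character(utils::packageVersion("carnsize"))),
                keep, extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Simulate a dataset to disk
#'
#' Writes tree.nwk, phenotypes.tsv, rates.tsv, truth_genes.tsv,
#' truth_rtt.tsv, lrt_records.tsv, alignments/*.fasta,
#' planted_sites.tsv and manifest.json under `config$out_dir`.
#'
#' @param config A `run_config`.
#' @return The `sim_dataset`, invisibly.
#' @export
cmd_simulate <- function(config = run_config()) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out)) abort_config(sprintf("cannot create output dir: %s", out))
  sim_cfg <- do.call(simulation_config,
                     utils::modifyList(list(seed = config$seed,
                                            threshold = config$threshold),
                                       config$sim))
  ds <- simulate_dataset(sim_cfg)
  ape::write.tree(ds$tree, config$tree)
  write_tsv_na(ds$phenotypes, config$phenotypes)
  write_rates_tsv(ds$rates, config$rates)
  write_tsv_na(ds$truth_genes, file.path(out, "truth_genes.tsv"))
  write_rtt_tsv(ds$truth_rtt, file.path(out, "truth_rtt.tsv"))
  write_tsv_na(ds$lrt_records, config$lrt_records)
  dir.create(config$alignments_dir, showWarnings = FALSE, recursive = TRUE)
  registry <- list()
  for (g in names(ds$alignments)) {
    write_alignment_fasta(ds$alignments[[g]]$alignment,
                          file.path(config$alignments_dir, paste0(g, ".fasta")))
    reg <- ds$alignments[[g]]$registry
    if (nrow(reg)) {
      reg$gene <- g
      registry[[g]] <- reg[c("gene", "column", "focal_residue",
                             "background_residue")]
    }
  }
  reg_df <- if (length(registry)) do.call(rbind, registry) else
    data.frame(gene = character(0), column = integer(0),
               focal_residue = character(0), background_residue = character(0))
  write_tsv_na(reg_df, file.path(out, "planted_sites.tsv"))
  write_manifest(unclass(sim_cfg), out, "simulate",
                 extra = list(focal_species = ds$focal,
                              n_species = length(ds$tree$tip.label)))
  msg_log(sprintf("simulated %d genes for %d species into %s",
                  nrow(ds$truth_genes), length(ds$tree$tip.label), out),
          verbose = config$verbose)
  invisible(ds)
}

#' Run the BSAG genome scan
#'
#' Reads tree, phenotypes and branch rates, computes root-to-tip omega,
#' runs the calibrated dual-phenotype PGLS scan, and writes bsag.tsv,
#' gene_report.tsv, rtt.tsv and counts.json.
#'
#' @param config A `run_config`.
#' @return The `bsag_scan`, invisibly.
#' @export
cmd_scan <- function(config = run_config()) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  tree <- parse_newick(file = config$tree)
  phenotypes <- read_phenotypes_tsv(config$phenotypes)
  rates <- read_rates_tsv(config$rates)
  if (nrow(rates) == 0L) {
    warning("rates table is empty: writing empty scan outputs", call. = FALSE)
  }
  rtt <- root_to_tip_omega(tree, rates, threshold = config$threshold)
  scan <- scan_genome(rtt, phenotypes, tree, alpha = config$alpha,
                      min_species = config$min_species,
                      mode = config$calibration_mode)
  write_rtt_tsv(rtt, file.path(out, "rtt.tsv"))
  write_tsv_na(scan$bsag, file.path(out, "bsag.tsv"))
  write_tsv_na(scan$per_gene, file.path(out, "gene_report.tsv"))
  jsonlite::write_json(scan$counts, file.path(out, "counts.json"),
                       auto_unbox = TRUE, digits = NA)
  msg_log(sprintf(
    "scan: %d genes, %d sig length, %d sig mass, %d BSAGs (%d+/%d-)",
    scan$counts$n_genes, scan$counts$n_sig_length, scan$counts$n_sig_mass,
    scan$counts$n_bsag, scan$counts$n_positive, scan$counts$n_negative),
    verbose = config$verbose)
  invisible(scan)
}

#' Run the REG branch-model test layer
#'
#' Reads the branch-model record table, applies the LRT + BH-FDR +
#' foreground-faster rule per foreground group, and writes regs.tsv.
#'
#' @param config A `run_config`.
#' @return The REG `data.frame`, invisibly.
#' @export
cmd_branch_test <- function(config = run_config()) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  records <- read_branch_records_tsv(config$lrt_records)
  regs <- classify_regs(records, alpha = config$alpha)
  write_tsv_na(regs, file.path(out, "regs.tsv"))
  msg_log(sprintf("branch test: %d records, %d REGs raw, %d after FDR",
                  nrow(regs), sum(regs$is_reg), sum(regs$is_reg_fdr)),
          verbose = config$verbose)
  invisible(regs)
}

#' Run the fixed amino-acid-change scan over an alignment directory
#'
#' Scans every `*.fasta` alignment for group-fixed changes. Unless given
#' explicitly, the focal set is the extremely small group derived from the
#' phenotype table and the background is every other phenotyped species
#' present in the alignment (reference and outgroup rows are thereby
#' excluded from the scan). Writes fixed_sites.tsv.
#'
#' @param config A `run_config`.
#' @return The sites `data.frame`, invisibly.
#' @export
cmd_fixed_changes <- function(config = run_config()) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- sort(list.files(config$alignments_dir, pattern = "\\.fasta$",
                           full.names = TRUE))
  focal <- config$focal_species
  background <- config$background_species
  if (is.null(focal) || is.null(background)) {
    phenotypes <- read_phenotypes_tsv(config$phenotypes)
    if (is.null(focal)) focal <- derive_focal_species(phenotypes)
    if (is.null(background)) background <- setdiff(phenotypes$species, focal)
  }
  sites <- list()
  for (f in files) {
    aln <- read_alignment_fasta(f)
    gene <- sub("\\.fasta$", "", basename(f))
    bg <- intersect(background, names(aln))
    sites[[gene]] <- fixed_change_sites(
      aln, focal = focal, background = bg, mode = config$scan_mode,
      ref_species = config$ref_species, gene = gene)
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(gene = character(0), column = integer(0),
               ref_position = integer(0), label = character(0),
               focal_residue = character(0), background_residue = character(0),
               domain = character(0))
  rownames(sites) <- NULL
  write_tsv_na(sites, file.path(out, "fixed_sites.tsv"))
  msg_log(sprintf("fixed-change scan: %d alignments, %d sites",
                  length(files), nrow(sites)), verbose = config$verbose)
  invisible(sites)
}

#' Run the full pipeline
#'
#' Simulates a dataset when the configured rates file does not yet exist,
#' then runs the BSAG scan, the REG branch test and the fixed-change scan,
#' logging stage timings.
#'
#' @param config A `run_config`.
#' @return List with scan, regs, sites, invisibly.
#' @export
cmd_all <- function(config = run_config()) {
  t0 <- proc.time()[["elapsed"]]
  stage <- function(what, expr) {
    t <- proc.time()[["elapsed"]]
    res <- expr
    msg_log(sprintf("[%s] %.1fs", what, proc.time()[["elapsed"]] - t),
            verbose = config$verbose)
    res
  }
  if (!file.exists(config$rates)) stage("simulate", cmd_simulate(config))
  scan <- stage("scan", cmd_scan(config))
  regs <- if (file.exists(config$lrt_records)) {
    stage("branch-test", cmd_branch_test(config))
  } else NULL
  sites <- if (dir.exists(config$alignments_dir)) {
    stage("fixed-changes", cmd_fixed_changes(config))
  } else NULL
  msg_log(sprintf("pipeline complete in %.1fs",
                  proc.time()[["elapsed"]] - t0), verbose = config$verbose)
  invisible(list(scan = scan, regs = regs, sites = sites))
}

#' Read a phenotype table from TSV
#'
#' @param path TSV with columns species, head_body_length_cm, body_mass_g.
#' @return Validated `data.frame`.
#' @export
read_phenotypes_tsv <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("phenotype file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA")
  miss <- setdiff(c("species", "head_body_length_cm", "body_mass_g"), names(df))
  if (length(miss)) {
    abort_data(sprintf("phenotype table missing column(s): %s",
                       paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(df$species)) abort_data("duplicate species in phenotype table")
  df
}
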