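make_rtt <- function(tree, log10_omega, gene = "g") {
  data.frame(gene = gene, species = names(log10_omega),
             omega_bar = 10^log10_omega, log10_omega_bar = log10_omega,
             n_valid_branches = 3L, stringsAsFactors = FALSE)
}

test_that("a strongly associated gene passes all three calibrated p-values", {
  set.seed(10)
  tr <- simulate_tree(20)
  ph <- simulate_phenotypes(tr)
  phv <- setNames(ph$body_mass_g, ph$species)
  g <- simulate_gene_rates(tr, ph, beta = 0.6, sigma_g = 0.1,
                           subthreshold_frac = 0)
  rtt <- root_to_tip_omega(tr, g$rates)
  cal <- two_step_calibration(rtt, phv, tr)
  expect_true(cal$complete)
  expect_lt(cal$p_all, 0.05)
  expect_lt(cal$p_robust, 0.05)
  expect_lt(cal$p_max, 0.05)
  expect_gt(cal$slope_all, 0)
  # leave-one-out bookkeeping
  expect_equal(nrow(cal$leave_one_out), 20L)
  expect_equal(cal$p_max, max(cal$leave_one_out$p))
  expect_gte(cal$p_max, min(cal$leave_one_out$p))
  expect_true(cal$dropped_species %in% cal$leave_one_out$species)
})

test_that("a signal carried by a single leverage species is rejected by P.max", {
  set.seed(11)
  tr <- simulate_tree(20)
  C <- vcv_matrix(tr)
  x10 <- brownian_sample(C, 4, 0.4)
  # flat response plus one extreme species aligned with its extreme predictor
  y <- rnorm(20, mean = -0.7, sd = 0.05)
  names(y) <- C$species
  lever <- names(which.max(abs(x10 - mean(x10))))
  x10[lever] <- max(x10) + 2.5
  y[lever] <- -0.7 + 1.2
  ph <- setNames(10^x10, names(x10))
  cal <- two_step_calibration(make_rtt(tr, y), ph, tr)
  expect_true(cal$complete)
  expect_lt(cal$p_all, 0.05)
  expect_gte(cal$p_max, 0.05)
  # the refit without the leverage species is the one that loses significance
  loo_lever <- cal$leave_one_out$p[cal$leave_one_out$species == lever]
  expect_gte(loo_lever, 0.05)
  expect_equal(cal$p_max, loo_lever)
})

test_that("drop-from-robust mode runs leave-one-out on the reduced set", {
  set.seed(12)
  tr <- simulate_tree(16)
  ph <- simulate_phenotypes(tr)
  phv <- setNames(ph$body_mass_g, ph$species)
  g <- simulate_gene_rates(tr, ph, beta = 0.5, sigma_g = 0.15,
                           subthreshold_frac = 0)
  rtt <- root_to_tip_omega(tr, g$rates)
  cal_full <- two_step_calibration(rtt, phv, tr, mode = "drop-from-full",
                                   min_species = 10)
  cal_rob <- two_step_calibration(rtt, phv, tr, mode = "drop-from-robust",
                                  min_species = 10)
  expect_equal(nrow(cal_full$leave_one_out), 16L)
  expect_equal(nrow(cal_rob$leave_one_out), 15L)
  expect_false(cal_rob$dropped_species %in% cal_rob$leave_one_out$species)
})

test_that("calibration refuses genes too small for leave-one-out refits", {
  set.seed(13)
  tr <- simulate_tree(11)
  ph <- simulate_phenotypes(tr)
  phv <- setNames(ph$body_mass_g, ph$species)
  g <- simulate_gene_rates(tr, ph, beta = 0.4, subthreshold_frac = 0)
  rtt <- root_to_tip_omega(tr, g$rates)
  cal <- two_step_calibration(rtt, phv, tr, min_species = 10)
  expect_false(cal$complete)
  expect_match(cal$reason, "leave-one-out")
})

test_that("classify_bsag applies the six-threshold rule and slope signs", {
  mk <- function(p, slope) {
    structure(list(p_all = p[1], p_robust = p[2], p_max = p[3],
                   slope_all = slope, lambda_all = 0.9,
                   dropped_species = "sp01",
                   leave_one_out = data.frame(species = "sp01", p = p[3]),
                   n_used = 20L, complete = TRUE, reason = NA_character_),
              class = "calibration_result")
  }
  rec <- classify_bsag(mk(c(0.01, 0.03, 0.049), 0.3),
                       mk(c(0.02, 0.04, 0.01), 0.5), gene = "g1")
  expect_s3_class(rec, "bsag_record")
  expect_equal(rec$direction, "positive")
  expect_true(rec$sign_concordant)
  # one p at 0.06 kills the call
  expect_null(classify_bsag(mk(c(0.01, 0.03, 0.06), 0.3),
                            mk(c(0.02, 0.04, 0.01), 0.5)))
  expect_null(classify_bsag(mk(c(0.06, 0.01, 0.01), 0.3),
                            mk(c(0.02, 0.04, 0.01), 0.5)))
  # discordant slopes: direction follows mass, flagged
  rec2 <- classify_bsag(mk(c(0.01, 0.01, 0.01), 0.3),
                        mk(c(0.01, 0.01, 0.01), -0.2))
  expect_equal(rec2$direction, "negative")
  expect_false(rec2$sign_concordant)
  expect_error(classify_bsag(mk(c(0.01, 0.01, 0.01), 1),
                             mk(c(0.01, 0.01, 0.01), 1), alpha = 1.5),
               class = "carnsize_config_error")
})

test_that("scan_genome is self-consistent with a naive recheck of its report", {
  set.seed(14)
  cfg <- simulation_config(seed = 14, n_effect_genes = 6, n_null_genes = 6,
                           subthreshold_frac = 0)
  ds <- simulate_dataset(cfg)
  rtt <- root_to_tip_omega(ds$tree, ds$rates)
  scan <- scan_genome(rtt, ds$phenotypes, ds$tree)
  pg <- scan$per_gene
  naive_bsag <- pg$gene[
    pg$p_all_length < 0.05 & pg$p_robust_length < 0.05 & pg$p_max_length < 0.05 &
    pg$p_all_mass < 0.05 & pg$p_robust_mass < 0.05 & pg$p_max_mass < 0.05 &
    !is.na(pg$p_all_length) & !is.na(pg$p_all_mass)]
  expect_setequal(scan$bsag$gene, naive_bsag)
  expect_equal(scan$counts$n_bsag, length(naive_bsag))
  expect_lte(scan$counts$n_bsag,
             min(scan$counts$n_sig_length, scan$counts$n_sig_mass))
  expect_equal(scan$counts$n_positive + scan$counts$n_negative,
               scan$counts$n_bsag)
  # effect genes dominate the calls; the per-gene report covers all genes
  expect_equal(nrow(pg), 12L)
  expect_gt(mean(grepl("^eff", scan$bsag$gene)), 0.5)
})

test_that("scan_genome handles an empty gene set", {
  tr <- simulate_tree(10, seed = 1)
  ph <- simulate_phenotypes(tr, seed = 2)
  rtt <- data.frame(gene = character(0), species = character(0),
                    omega_bar = numeric(0), log10_omega_bar = numeric(0),
                    n_valid_branches = integer(0))
  scan <- scan_genome(rtt, ph, tr)
  expect_equal(nrow(scan$bsag), 0L)
  expect_equal(scan$counts$n_genes, 0L)
  expect_equal(scan$counts$n_bsag, 0L)
})
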