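test_that("simulated trees are ultrametric, unit height and seed-stable", {
  tr <- simulate_tree(20, seed = 1)
  expect_equal(length(tr$tip.label), 20L)
  expect_true(is_ultrametric_tol(tr))
  expect_equal(max(ape::node.depth.edgelength(tr)), 1, tolerance = 1e-9)
  tr2 <- simulate_tree(20, seed = 1)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  expect_equal(length(simulate_tree(3, seed = 2)$tip.label), 3L)
  expect_error(simulate_tree(2), class = "carnsize_config_error")
})

test_that("brownian_sample has the requested moments and degenerate limit", {
  tr <- simulate_tree(4, seed = 3)
  C <- vcv_matrix(tr)
  expect_equal(unname(brownian_sample(C, mean = 2, sigma2 = 0)), rep(2, 4))
  x1 <- brownian_sample(C, 0, 1, seed = 9)
  x2 <- brownian_sample(C, 0, 1, seed = 9)
  expect_identical(x1, x2)
  # Monte Carlo covariance check
  set.seed(4)
  draws <- t(replicate(5000, brownian_sample(C, 0, 2)))
  S <- cov(draws)
  expect_equal(S, 2 * C$C, tolerance = 0.05 * max(2 * C$C), ignore_attr = TRUE)
  expect_error(brownian_sample(matrix(c(1, 2, 2, 1), 2), 0, 1),
               class = "carnsize_numeric_error")
})

test_that("simulated phenotypes follow the allometric construction", {
  tr <- simulate_tree(20, seed = 5)
  ph0 <- simulate_phenotypes(tr, length_slope = 0, length_noise_var = 1e-12,
                             seed = 6)
  expect_equal(diff(range(log10(ph0$head_body_length_cm))), 0, tolerance = 1e-4)
  ph <- simulate_phenotypes(tr, seed = 7)
  expect_true(all(ph$body_mass_g > 0 & ph$head_body_length_cm > 0))
  # strong allometry signal when noise is tiny relative to slope * variance
  cors <- replicate(200, {
    p <- simulate_phenotypes(tr, length_noise_var = 1e-4)
    cor(log10(p$head_body_length_cm), log10(p$body_mass_g))
  })
  expect_gt(mean(cors), 0.8)
})

test_that("gene-rate generator achieves its tip targets through the pipeline", {
  set.seed(8)
  tr <- simulate_tree(20)
  ph <- simulate_phenotypes(tr)
  g <- simulate_gene_rates(tr, ph, beta = 0.4, subthreshold_frac = 0)
  # with no forced sub-threshold branches every branch is valid
  expect_true(all(branch_is_valid(g$rates$dN, g$rates$dS)))
  expect_true(all(g$rates$omega >= 1e-4 & g$rates$omega <= 10))
  # achieved truth = the pipeline statistic on the generated table
  rtt <- root_to_tip_omega(tr, g$rates)
  m <- merge(rtt, g$truth$achieved, by = c("gene", "species"))
  expect_equal(m$omega_bar.x, m$omega_bar.y, tolerance = 1e-8)
  # and the achieved means track the planted targets closely here
  tgt <- g$truth$target_log10[m$species]
  expect_lt(stats::median(abs(m$log10_omega_bar.x - tgt)), 0.05)

  # forced sub-threshold branches are marked invalid
  g2 <- simulate_gene_rates(tr, ph, beta = 0.4, subthreshold_frac = 0.2)
  frac_invalid <- mean(!branch_is_valid(g2$rates$dN, g2$rates$dS))
  expect_gte(frac_invalid, 0.15)
  expect_error(simulate_gene_rates(tr, ph, sigma_g = 0),
               class = "carnsize_config_error")
})

test_that("alignment generator plants recoverable sites and validates columns", {
  species <- sprintf("s%d", 1:8)
  focal <- c("s1", "s2", "s3")
  planted <- data.frame(column = 50L, focal_residue = "W",
                        background_residue = "C")
  sim <- simulate_alignment(species, focal, length = 200, planted = planted,
                            gap_columns = c(10L, 20L), seed = 9)
  hits <- scan_fixed_changes(sim$alignment, focal, setdiff(species, focal),
                             mode = "relaxed")
  expect_true(50L %in% hits$column)
  expect_equal(sim$registry, planted)
  expect_error(
    simulate_alignment(species, focal, length = 200, planted = planted,
                       gap_columns = 50L),
    "disjoint", class = "carnsize_config_error")
  expect_error(
    simulate_alignment(species, focal, length = 20, planted = planted),
    "range", class = "carnsize_config_error")

  # without planted sites, chance fixed differences are rare
  set.seed(10)
  empty <- replicate(100, {
    s <- simulate_alignment(species, focal, length = 200)
    nrow(scan_fixed_changes(s$alignment, focal, setdiff(species, focal)))
  })
  expect_gte(mean(empty == 0), 0.95)
})

test_that("LRT record generator honours counts, direction and power", {
  expect_equal(nrow(simulate_lrt_records(0, 0)), 0L)
  rec <- simulate_lrt_records(50, 50, noncentrality = 10, seed = 11)
  expect_equal(sum(rec$is_alt), 50L)
  expect_true(all(rec$omega_fg[rec$is_alt] > rec$omega_bg[rec$is_alt]))
  expect_true(all(rec$lnL1 >= rec$lnL0))
  out <- classify_regs(rec)
  expect_gt(mean(out$is_reg[rec$is_alt]), 0.8)   # power at ncp 10
  expect_error(simulate_lrt_records(5, 5, noncentrality = -1),
               class = "carnsize_config_error")
})

test_that("whole-dataset simulation is reproducible and internally consistent", {
  cfg <- simulation_config(seed = 12, n_effect_genes = 2, n_null_genes = 3,
                           n_alignment_genes = 2, n_lrt_null = 10,
                           n_lrt_alt = 5)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ape::write.tree(ds1$tree), ape::write.tree(ds2$tree))
  expect_identical(ds1$rates, ds2$rates)
  expect_identical(ds1$alignments, ds2$alignments)
  expect_identical(ds1$lrt_records, ds2$lrt_records)
  # generated data pass the pipeline's validators
  expect_silent(root_to_tip_omega(ds1$tree, ds1$rates))
  expect_silent(validate_alignment <- lapply(ds1$alignments, function(a) {
    carnsize:::validate_alignment(a$alignment)
  }))
  expect_equal(nrow(ds1$truth_genes), 5L)
  expect_true(all(ds1$truth_genes$is_null == grepl("^null", ds1$truth_genes$gene)))
  # achieved truth matches the pipeline statistic gene by gene
  rtt <- root_to_tip_omega(ds1$tree, ds1$rates)
  key <- function(d) d[order(d$gene, d$species),
                       c("gene", "species", "omega_bar")]
  expect_equal(key(rtt)$omega_bar, key(ds1$truth_rtt)$omega_bar,
               tolerance = 1e-8)
  expect_error(simulation_config(n_species = 2),
               class = "carnsize_config_error")
  expect_error(simulation_config(subthreshold_frac = 1),
               class = "carnsize_config_error")
})
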