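toy_alignment <- function() {
  c(f1 = "MKLSAQL",
    f2 = "MKLSAQL",
    f3 = "MKLSAQL",
    b1 = "MKLSAQS",
    b2 = "MKLSAQS",
    b3 = "MKLSAQS",
    b4 = "MKLSAQS")
}

test_that("strict scan finds uniform focal-vs-background columns, gaps excluded", {
  aln <- toy_alignment()
  sites <- scan_fixed_changes(aln, focal = c("f1", "f2", "f3"),
                              background = c("b1", "b2", "b3", "b4"))
  expect_equal(sites$column, 7L)
  expect_equal(sites$focal_residue, "L")
  expect_equal(sites$background_residue, "S")

  # a gap in one background row removes the site
  aln2 <- aln
  substr(aln2["b2"], 7, 7) <- "-"
  expect_equal(nrow(scan_fixed_changes(aln2, c("f1", "f2", "f3"),
                                       c("b1", "b2", "b3", "b4"))), 0L)
  # X is treated like a gap
  aln3 <- aln
  substr(aln3["f1"], 7, 7) <- "X"
  expect_equal(nrow(scan_fixed_changes(aln3, c("f1", "f2", "f3"),
                                       c("b1", "b2", "b3", "b4"))), 0L)
})

test_that("relaxed mode tolerates background variation; strict does not", {
  aln <- toy_alignment()
  substr(aln["b3"], 7, 7) <- "T"       # background {S,S,T,S}
  strict <- scan_fixed_changes(aln, c("f1", "f2", "f3"),
                               c("b1", "b2", "b3", "b4"), mode = "strict")
  relaxed <- scan_fixed_changes(aln, c("f1", "f2", "f3"),
                                c("b1", "b2", "b3", "b4"), mode = "relaxed")
  expect_equal(nrow(strict), 0L)
  expect_equal(relaxed$column, 7L)
  expect_equal(relaxed$background_residue, "S/T")
})

test_that("scan validates its species arguments", {
  aln <- toy_alignment()
  expect_error(scan_fixed_changes(aln, "f1", c("b1", "b2")),
               class = "carnsize_config_error")
  expect_error(scan_fixed_changes(aln, c("f1", "b1"), c("b1", "b2")),
               "disjoint", class = "carnsize_config_error")
  expect_error(scan_fixed_changes(aln, c("f1", "zz"), c("b1", "b2")),
               "missing", class = "carnsize_data_error")
})

test_that("reference mapping counts non-gap reference positions", {
  aln <- c(ref = "M-KL", a = "MRKL", b = "MRKL")
  expect_equal(map_to_reference(aln, "ref", 3L), 2L)
  expect_equal(map_to_reference(aln, "ref", 1L), 1L)
  expect_true(is.na(map_to_reference(aln, "ref", 2L)))  # gap in reference
  expect_equal(map_to_reference(aln, "ref", c(1L, 3L, 4L)), c(1L, 2L, 3L))
  expect_error(map_to_reference(aln, "ref", 9L), class = "carnsize_data_error")
  expect_error(map_to_reference(aln, "nope", 1L), class = "carnsize_data_error")
})

test_that("domain annotation labels covered sites only", {
  sites <- data.frame(gene = "CDC7like", column = c(520L, 30L),
                      ref_position = c(513L, NA))
  dom <- data.frame(name = "protein kinase", start = 400L, end = 650L)
  out <- annotate_domains(sites, dom)
  expect_equal(out$domain, c("protein kinase", NA))
  out2 <- annotate_domains(data.frame(ref_position = 200L), dom)
  expect_true(is.na(out2$domain))
  out3 <- annotate_domains(sites, dom[0, ])
  expect_true(all(is.na(out3$domain)))
  expect_error(annotate_domains(sites, data.frame(name = "x", start = 5, end = 2)),
               class = "carnsize_data_error")
})

test_that("full site report composes substitution-style labels", {
  aln <- toy_alignment()
  aln["human"] <- "MK-SAQS"     # reference with a gap at column 3
  sites <- fixed_change_sites(aln, focal = c("f1", "f2", "f3"),
                              background = c("b1", "b2", "b3", "b4"),
                              ref_species = "human",
                              domains = data.frame(name = "kinase",
                                                   start = 1, end = 10),
                              gene = "g")
  expect_equal(sites$ref_position, 6L)   # column 7 minus the reference gap
  expect_equal(sites$label, "S6L")
  expect_equal(sites$domain, "kinase")
  # a site at a reference gap keeps its alignment coordinate, label NA
  aln2 <- aln
  aln2["human"] <- "MKLSAQ-"
  sites2 <- fixed_change_sites(aln2, c("f1", "f2", "f3"),
                               c("b1", "b2", "b3", "b4"),
                               ref_species = "human", gene = "g")
  expect_equal(sites2$column, 7L)
  expect_true(is.na(sites2$ref_position))
  expect_true(is.na(sites2$label))
})

test_that("strict hits are a subset of relaxed hits on random alignments", {
  set.seed(30)
  for (i in 1:200) {
    sim <- simulate_alignment(sprintf("s%d", 1:8), focal = c("s1", "s2", "s3"),
                              length = 60, mutation_rate = 0.15)
    strict <- scan_fixed_changes(sim$alignment, c("s1", "s2", "s3"),
                                 sprintf("s%d", 4:8), mode = "strict")
    relaxed <- scan_fixed_changes(sim$alignment, c("s1", "s2", "s3"),
                                  sprintf("s%d", 4:8), mode = "relaxed")
    expect_true(all(strict$column %in% relaxed$column))
  }
})

test_that("scanning ignores row order and rows outside focal/background", {
  set.seed(31)
  sim <- simulate_alignment(sprintf("s%d", 1:8), focal = c("s1", "s2"),
                            length = 100,
                            planted = data.frame(column = 10L,
                                                 focal_residue = "W",
                                                 background_residue = "A"))
  aln <- sim$alignment
  ref <- scan_fixed_changes(aln, c("s1", "s2"), sprintf("s%d", 3:8))
  shuffled <- scan_fixed_changes(aln[sample(names(aln))],
                                 c("s1", "s2"), sprintf("s%d", 3:8))
  expect_equal(shuffled, ref)
  # an outgroup row carrying the focal residue does not affect the scan
  aln["outgroup"] <- aln[["s1"]]
  with_out <- scan_fixed_changes(aln, c("s1", "s2"), sprintf("s%d", 3:8))
  expect_equal(with_out, ref)
})

test_that("alignment FASTA round-trips", {
  sim <- simulate_alignment(sprintf("s%d", 1:5), focal = c("s1", "s2"),
                            length = 80, gap_columns = c(4L, 9L), seed = 32)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_alignment_fasta(sim$alignment, path)
  back <- read_alignment_fasta(path)
  expect_identical(back, sim$alignment)
})
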