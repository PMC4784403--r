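make_panel <- function(snp_id, ref, alt, training_mean = NULL) {
  df <- data.frame(snp_id = snp_id, ref_allele = ref, alt_allele = alt,
                   stringsAsFactors = FALSE)
  if (!is.null(training_mean)) df$training_mean <- training_mean
  validate_allele_panel(df)
}

test_that("harmonization truth table: 3 genotypes x 4 allele configurations", {
  # panel SNP with ref A / alt C; the four ways a study file can code
  # the same SNP and the hand-derived count each genotype must map to
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  configs <- list(
    list(coded = "A", other = "C", expect = identity),        # ref coding
    list(coded = "C", other = "A", expect = function(x) 2 - x), # alt coding
    list(coded = "T", other = "G", expect = identity),        # ref, flipped strand
    list(coded = "G", other = "T", expect = function(x) 2 - x)) # alt, flipped strand
  panel <- make_panel("rs1", "A", "C")
  for (cfg in configs) {
    for (g in 0:2) {
      G <- genotype_matrix(matrix(g, 1, 1), "s1", "rs1",
                           cfg$coded, cfg$other)
      out <- harmonize_alleles(G, panel)
      expect_equal(unname(out$values[1, 1]), cfg$expect(g),
                   info = paste("coded", cfg$coded, "genotype", g))
      expect_identical(out$coded_allele, "A")
      expect_identical(out$other_allele, "C")
    }
  }
})

test_that("harmonization is an involution under panel ref/alt swap", {
  set.seed(11)
  vals <- matrix(sample(0:2, 40, replace = TRUE), 4, 10)
  snps <- sprintf("rs%02d", 1:10)
  refs <- sample(c("A", "C", "G", "T"), 10, replace = TRUE)
  alts <- vapply(refs, function(r) sample(setdiff(c("A", "C", "G", "T"),
                                                  c(r, c(A = "T", C = "G",
                                                         G = "C", T = "A")[r])),
                                          1), character(1))
  G <- genotype_matrix(vals, paste0("s", 1:4), snps, refs, alts)
  panel <- make_panel(snps, alts, refs)          # forces a 2-x recode
  swapped <- make_panel(snps, refs, alts)
  once <- harmonize_alleles(G, panel)
  twice <- harmonize_alleles(once, swapped)
  expect_equal(unname(twice$values), unname(vals))
})

test_that("unknown coded alleles are assumed reference-coded; errors are raised", {
  panel <- make_panel(c("rs1", "rs2"), c("A", "C"), c("G", "T"))
  G <- genotype_matrix(matrix(c(0, 1, 2, 1), 2, 2), c("s1", "s2"),
                       c("rs1", "rs2"))
  out <- harmonize_alleles(G, panel)
  expect_equal(out$values, G$values)
  expect_identical(out$coded_allele, c("A", "C"))

  G_missing <- genotype_matrix(matrix(0, 1, 1), "s1", "rs99")
  expect_error(harmonize_alleles(G_missing, panel), "absent from panel")

  # C/G cannot be reconciled with A/G directly or via complementation
  G_bad <- genotype_matrix(matrix(1, 1, 1), "s1", "rs1", "C", "G")
  expect_error(harmonize_alleles(G_bad, panel), "irreconcilable.*rs1")
})

test_that("strand-ambiguous SNPs warn by default and drop in strict mode", {
  panel <- make_panel("rs1", "A", "T")
  G <- genotype_matrix(matrix(2, 1, 1), "s1", "rs1", "T", "A")
  expect_warning(out <- harmonize_alleles(G, panel), "ambiguous")
  expect_equal(unname(out$values[1, 1]), 0)   # taken at face value: alt coding
  expect_warning(strict <- harmonize_alleles(G, panel, strict = TRUE),
                 "dropped")
  expect_equal(ncol(strict$values), 0L)
})

test_that("harmonized columns follow panel order", {
  panel <- make_panel(c("rs1", "rs2", "rs3"), rep("A", 3), rep("G", 3))
  G <- genotype_matrix(matrix(c(0, 1, 2), 1, 3), "s1",
                       c("rs3", "rs1", "rs2"))
  out <- harmonize_alleles(G, panel)
  expect_identical(out$snp_ids, c("rs1", "rs2", "rs3"))
  expect_equal(unname(out$values[1, ]), c(1, 2, 0))
})

test_that("missing-rate filter removes samples first, then SNPs", {
  G0 <- tiny_genotypes()
  expect_equal(filter_by_missing_rate(G0, 1, 1)$values, G0$values)

  # a sample with 1 of 10 calls missing exceeds the 0.05 default
  vals <- matrix(0, 2, 10)
  vals[1, 4] <- NA
  G <- genotype_matrix(vals, c("bad", "good"), sprintf("m%02d", 1:10))
  out <- filter_by_missing_rate(G)
  expect_identical(out$sample_ids, "good")
  expect_identical(attr(out, "samples_removed"), "bad")

  # 4x4 with known missing pattern: brute-force both passes by hand
  v <- matrix(0, 4, 4)
  v[1, 1:2] <- NA          # sample 1: 50 % missing
  v[2, 3] <- NA            # sample 2: 25 % missing
  v[3:4, 4] <- NA          # SNP 4: missing for remaining samples
  G2 <- genotype_matrix(v, paste0("s", 1:4), paste0("m", 1:4))
  out2 <- filter_by_missing_rate(G2, max_sample_missing = 0.3,
                                 max_snp_missing = 0.4)
  # brute force: drop s1 (0.5 > 0.3); then per-SNP missing over s2..s4:
  # m1 0/3, m2 0/3, m3 1/3 > 0.4? no (0.33); m4 2/3 > 0.4 -> dropped
  expect_identical(out2$sample_ids, c("s2", "s3", "s4"))
  expect_identical(out2$snp_ids, c("m1", "m2", "m3"))
  # surviving samples were under threshold on the original SNP set,
  # and surviving SNPs are under threshold on the surviving samples
  expect_true(all(rowMeans(is.na(v[2:4, ])) <= 0.3))
  expect_true(all(colMeans(is.na(out2$values)) <= 0.4))

  v_all <- matrix(NA_real_, 2, 2)
  G3 <- genotype_matrix(v_all, c("a", "b"), c("m1", "m2"))
  expect_error(filter_by_missing_rate(G3, 0.5, 0.5), "all.*samples")
})

test_that("imputation prefers training means and never touches observed calls", {
  G0 <- tiny_genotypes()
  no_miss <- subset_genotypes(G0, samples = 1)
  expect_equal(impute_missing(no_miss)$values, no_miss$values)

  G <- genotype_matrix(matrix(c(0, 2, NA), 3, 1), paste0("s", 1:3), "rs1")
  expect_equal(unname(impute_missing(G)$values[3, 1]), 1.0)

  panel <- make_panel("rs1", "A", "G", training_mean = 0.3)
  expect_equal(unname(impute_missing(G, panel)$values[3, 1]), 0.3)

  # observed cells bit-identical after imputation
  imp <- impute_missing(G0)
  obs <- !is.na(G0$values)
  expect_identical(imp$values[obs], G0$values[obs])
  expect_false(anyNA(imp$values))
  expect_true(all(imp$values >= 0 & imp$values <= 2))

  G_empty <- genotype_matrix(matrix(NA_real_, 2, 1), c("a", "b"), "rs9")
  expect_error(impute_missing(G_empty), "rs9")
})
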