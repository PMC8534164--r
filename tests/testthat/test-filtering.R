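test_that("filter cascade applies the four rules conjunctively", {
  df <- variantTable(
    variantRow(pop_af_max = 0.01),                       # fails pop_af
    variantRow(pop_af_max = 0.0001, common_snp = TRUE,
               clinvar = "pathogenic"),                  # ClinVar rescue
    variantRow(alt_reads_fwd = 2L, alt_reads_rev = 2L,
               vaf = 0.05, pop_af_max = 0),              # inclusive bounds
    variantRow(common_snp = TRUE),                       # fails common_snp
    variantRow(alt_reads_fwd = 1L, alt_reads_rev = 9L),  # fails strand
    variantRow(vaf = 0.049))                             # fails vaf
  rep <- filterVariants(df, runConfig())
  expect_identical(nrow(keptVariants(rep)), 2L)
  expect_identical(removedVariants(rep)$reasons,
                   c("pop_af", "common_snp", "strand", "vaf"))
  t <- filterTallies(rep)
  expect_identical(unname(t[c("pop_af", "common_snp", "strand", "vaf",
                              "kept", "total")]),
                   c(1L, 1L, 1L, 1L, 2L, 6L))
})

test_that("ClinVar rescue applies to the common-SNP rule only", {
  # a pathogenic common SNP still fails strand and VAF rules
  df <- variantRow(common_snp = TRUE, clinvar = "pathogenic",
                   alt_reads_fwd = 1L, vaf = 0.01)
  rep <- filterVariants(df)
  expect_identical(nrow(keptVariants(rep)), 0L)
  expect_identical(removedVariants(rep)$reasons, "strand;vaf")
})

test_that("filtering is idempotent, order-invariant, and matches an
           independent predicate", {
  set.seed(42)
  n <- 200L
  df <- do.call(rbind, replicate(n, variantRow(), simplify = FALSE))
  df$pos <- seq_len(n) * 10L
  df$pop_af_max <- sample(c(0, 0.0005, 0.01), n, replace = TRUE)
  df$common_snp <- sample(c(TRUE, FALSE), n, replace = TRUE)
  df$clinvar <- sample(c("pathogenic", "benign", "unknown"), n,
                       replace = TRUE)
  df$alt_reads_fwd <- sample(0:6, n, replace = TRUE)
  df$alt_reads_rev <- sample(0:6, n, replace = TRUE)
  df$vaf <- round(stats::runif(n, 0, 0.2), 3)

  rep <- filterVariants(df)
  kept <- keptVariants(rep)

  # independently coded row-wise predicate
  oracle <- vapply(seq_len(n), function(i) {
    r <- df[i, ]
    isTRUE(r$pop_af_max < 0.001) &&
      (!r$common_snp || identical(r$clinvar, "pathogenic")) &&
      r$alt_reads_fwd >= 2 && r$alt_reads_rev >= 2 && r$vaf >= 0.05
  }, logical(1))
  expect_identical(sort(kept$pos), sort(df$pos[oracle]))

  # idempotence and order-invariance
  rep2 <- filterVariants(kept)
  expect_identical(keptVariants(rep2), kept)
  perm <- sample.int(n)
  repPerm <- filterVariants(df[perm, ])
  expect_identical(sort(keptVariants(repPerm)$pos), sort(kept$pos))
})

test_that("driver classification requires the gene list and any evidence
           arm", {
  drv <- toyDriverList()
  twoOfThree <- classifyDriver(
    variantRow(gene = "TP53", pred_sift = "deleterious",
               pred_polyphen2 = "deleterious"), drv)
  expect_true(twoOfThree$pathogenic)
  expect_identical(twoOfThree$evidence, "predictor_consensus")

  noArm <- classifyDriver(
    variantRow(gene = "TP53", pred_sift = "tolerated",
               pred_polyphen2 = "missing",
               pred_mutationtaster = "missing"), drv)
  expect_false(noArm$pathogenic)
  expect_true(noArm$in_driver_list)

  offList <- classifyDriver(
    variantRow(gene = "NOTAGENE", clinvar = "pathogenic"), drv)
  expect_false(offList$in_driver_list)
  expect_false(offList$pathogenic)

  multiArm <- classifyDriver(
    variantRow(gene = "PIK3CA", clinvar = "pathogenic", hotspot = TRUE),
    drv)
  expect_identical(multiArm$evidence, "clinvar,hotspot")
})

test_that("driver classification is monotone in evidence", {
  drv <- toyDriverList()
  set.seed(7)
  for (i in 1:50) {
    base <- variantRow(
      gene = sample(c("TP53", "XYZ"), 1),
      clinvar = sample(c("pathogenic", "unknown"), 1),
      pred_sift = sample(c("deleterious", "tolerated"), 1),
      pred_polyphen2 = sample(c("deleterious", "missing"), 1),
      hotspot = sample(c(TRUE, FALSE), 1))
    more <- base
    arm <- sample(c("clinvar", "hotspot", "pred"), 1)
    if (arm == "clinvar") more$clinvar <- "pathogenic"
    if (arm == "hotspot") more$hotspot <- TRUE
    if (arm == "pred") {
      more$pred_sift <- "deleterious"
      more$pred_polyphen2 <- "deleterious"
    }
    expect_gte(classifyDriver(more, drv)$pathogenic,
               classifyDriver(base, drv)$pathogenic)
  }
})

test_that("copy-number directionality keeps coherent events only", {
  df <- data.frame(
    patient_id = "P1", sample_id = "S1",
    gene = c("MCL1", "RB1", "MYC", "PTEN", "GX", "EGFR"),
    copy_number = c(5L, 1L, 2L, 2L, 4L, 1L),
    gene_role = c("oncogene", "tsg", "oncogene", "tsg", "unknown",
                  "oncogene"),
    stringsAsFactors = FALSE)
  out <- filterCnvs(df)
  expect_identical(out$kept$gene, c("MCL1", "RB1"))
  expect_identical(out$kept$direction, c("amplification", "deletion"))
  rm <- out$removed
  expect_identical(rm$reason[rm$gene == "MYC"], "copy-neutral")
  expect_identical(rm$reason[rm$gene == "GX"], "no directional rule")
  expect_identical(rm$reason[rm$gene == "EGFR"], "oncogene loss")
})

test_that("mutational burden is the exact per-megabase ratio", {
  recs <- function(n) data.frame(consequence = rep("nonsynonymous", n))
  expect_identical(computeTmb(recs(37)), 1)
  expect_identical(computeTmb(recs(0)), 0)
  expect_identical(computeTmb(recs(333)), 9)
  # linearity
  expect_identical(computeTmb(recs(24)), 2 * computeTmb(recs(12)))
  # nonsynonymous-only switch
  mixed <- data.frame(consequence = c(rep("synonymous", 30),
                                      rep("nonsynonymous", 5),
                                      rep("indel", 2)))
  expect_equal(computeTmb(mixed, nonsynOnly = TRUE), 7 / 37)
  expect_equal(computeTmb(mixed), 1)
  expect_error(computeTmb(recs(1), exomeMb = 0), "positive")
})
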