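test_that("simulation is byte-deterministic under a fixed seed", {
  a <- simulatePatient(nLesions = 3, seed = 11)
  b <- simulatePatient(nLesions = 3, seed = 11)
  expect_identical(a$variants, b$variants)
  expect_identical(a$cnvs, b$cnvs)
  expect_identical(a$truth, b$truth)
  c <- simulatePatient(nLesions = 3, seed = 12)
  expect_false(identical(a$variants, c$variants))
})

test_that("early lymph-node divergence separates the lineages' private
           mutations", {
  sim <- simulatePatient(nLesions = 4, lymphNodeEarly = TRUE,
                         mutationsPerClone = 10, seed = 8,
                         patientId = "PX")
  v <- sim$variants
  bySample <- split(paste(v$chrom, v$pos, v$ref, v$alt, sep = ":"),
                    v$sample_id)
  ln <- Reduce(union, bySample[grep("_LN", names(bySample))])
  tu <- Reduce(union, bySample[grep("_TU", names(bySample))])
  truncal <- Reduce(intersect, bySample)
  # LN lesions carry none of the tumor lineage's non-truncal mutations
  expect_length(intersect(setdiff(tu, truncal), ln), 0)
})

test_that("single-clone patients are entirely truncal", {
  sim <- simulatePatient(nLesions = 2, nClones = 1, seed = 5)
  expect_true(all(sim$truth@clonality == "truncal"))
  pres <- presenceSets(sim$variants, filterCnvs(sim$cnvs)$kept)
  part <- classifyClonality(pres)
  expect_true(all(part$labels == "truncal"))
})

test_that("ground-truth clonality equals set algebra over lesion mutation
           sets", {
  for (i in 1:8) {
    sim <- simulatePatient(nLesions = sample(2:6, 1), seed = 800 + i,
                           patientId = "PX")
    v <- sim$variants
    bySample <- split(paste(v$chrom, v$pos, v$ref, v$alt, sep = ":"),
                      v$sample_id)
    events <- unique(unlist(bySample))
    occ <- vapply(events, function(e)
      sum(vapply(bySample, function(s) e %in% s, logical(1))), integer(1))
    oracle <- ifelse(occ == length(bySample), "truncal",
                     ifelse(occ == 1L, "private", "shared"))
    truth <- sim$truth@clonality[events]
    expect_identical(unname(truth), unname(oracle))
  }
})

test_that("simulated context frequencies converge to the planted mixture", {
  cat5 <- makeToyCatalog(5, seed = 3)
  sim <- simulatePatient(nLesions = 2, nClones = 1,
                         mutationsPerClone = 12000, indelFrac = 0,
                         catalog = cat5, seed = 3)
  mix <- sim$truth@cloneMixtures[1, ]
  p <- as.numeric(mix %*% signatureProbs(cat5))
  v <- sim$variants[sim$variants$sample_id == sim$variants$sample_id[1], ]
  sp <- countContexts(v)
  obs <- spectrumCounts(sp) / spectrumTotal(sp)
  expect_lt(0.5 * sum(abs(obs - p)), 0.05)  # total variation distance
})

test_that("indels arise without contexts at the configured rate", {
  sim <- simulatePatient(nLesions = 2, nClones = 1,
                         mutationsPerClone = 4000, seed = 13)
  v <- sim$variants[sim$variants$sample_id == sim$variants$sample_id[1], ]
  frac <- mean(v$consequence == "indel")
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
  expect_true(all(is.na(v$context[v$consequence == "indel"])))
})

test_that("filter decoys are planted per rule with exact labels", {
  sim <- simulatePatient(nLesions = 2, seed = 21)
  planted <- plantFilterDecoys(sim$variants, nPerRule = 5, seed = 2)
  expect_identical(nrow(planted$variants), nrow(sim$variants) + 25L)
  tab <- table(planted$truth$planted_rule)
  expect_identical(as.integer(tab[c("fails_common_snp", "fails_pop_af",
                                    "fails_strand", "fails_vaf",
                                    "override_survivor")]),
                   rep(5L, 5))

  dec <- merge(planted$variants, planted$truth,
               by = c("sample_id", "chrom", "pos", "ref", "alt"))
  strand <- dec[dec$planted_rule == "fails_strand", ]
  expect_true(all(pmin(strand$alt_reads_fwd, strand$alt_reads_rev) < 2))
  vaf <- dec[dec$planted_rule == "fails_vaf", ]
  expect_true(all(vaf$vaf < 0.05))
  ov <- dec[dec$planted_rule == "override_survivor", ]
  expect_true(all(ov$common_snp & ov$clinvar == "pathogenic"))
})

test_that("toy catalogs are normalized, distinct and reproducible", {
  cat6 <- makeToyCatalog(6, seed = 4)
  P <- signatureProbs(cat6)
  expect_equal(unname(rowSums(P)), rep(1, 6))
  cos <- P / sqrt(rowSums(P^2))
  cm <- cos %*% t(cos)
  diag(cm) <- 0
  expect_lte(max(cm), 0.7)
  expect_identical(signatureProbs(makeToyCatalog(6, seed = 4)), P)
  expect_error(makeToyCatalog(1), "nSignatures")
})

test_that("infeasible generator configurations error", {
  expect_error(simulatePatient(nLesions = 1), "nLesions")
  expect_error(simulatePatient(nLesions = 3, mutationsPerClone = 0),
               "mutationsPerClone")
  expect_error(simulatePatient(nLesions = 2, lymphNodeEarly = TRUE),
               "nLymphNodes")
})
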