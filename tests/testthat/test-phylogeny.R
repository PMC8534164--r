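test_that("clonality partition follows the all/one/some rule", {
  pres <- list(S1 = c("a", "b", "c"), S2 = c("a", "b"),
               S3 = c("a", "d"), S4 = c("a"))
  part <- classifyClonality(pres)
  expect_identical(unname(part$labels[c("a", "b", "c", "d")]),
                   c("truncal", "shared", "private", "private"))
  expect_identical(part$truncal, 1L)
  expect_identical(part$shared, 1L)
  expect_identical(unname(part$private[c("S1", "S3")]), c(1L, 1L))
  # conservation
  expect_identical(part$truncal + part$shared + sum(part$private),
                   length(part$labels))
  expect_error(classifyClonality(list(S1 = "a")), "single-sample")
})

test_that("clonality labels equal simulator ground truth", {
  for (i in 1:10) {
    sim <- simulatePatient(nLesions = sample(2:5, 1), seed = 500 + i,
                           lymphNodeEarly = i %% 2 == 0,
                           nLymphNodes = 2L,
                           patientId = "PX")
    pres <- presenceSets(sim$variants, filterCnvs(sim$cnvs)$kept)
    part <- classifyClonality(pres)
    truth <- sim$truth@clonality
    expect_identical(sort(names(part$labels)), sort(names(truth)))
    expect_identical(part$labels[names(truth)], truth)
  }
})

test_that("binary matrices are deduplicated, normal-rooted, and keyed by
           event", {
  pres <- list(S1 = "chr1:5:C:T", S2 = "chr1:5:C:T")
  mat <- buildBinaryMatrix(pres, "P1")
  expect_identical(matrixEvents(mat),
                   matrix(c(1L, 1L, 0L), 3, 1,
                          dimnames = list(c("S1", "S2", "normal"),
                                          "chr1:5:C:T")))

  # duplicate event in one sample collapses to a single column
  cn <- data.frame(patient_id = "P1", sample_id = c("S1", "S2", "S3"),
                   gene = "MCL1", copy_number = 5L,
                   gene_role = "oncogene",
                   direction = "amplification")
  pres2 <- presenceSets(NULL, rbind(cn, cn[1, ]))
  mat2 <- buildBinaryMatrix(pres2, "P1")
  expect_identical(colnames(matrixEvents(mat2)), "MCL1:amp")
  expect_equal(unname(colSums(matrixEvents(mat2))), 3)
})

test_that("Fitch scores match hand-derived counts on a fixed quartet", {
  phy <- ape::read.tree(text = "((A,B),(C,normal));")
  m1 <- rbind(A = 1L, B = 1L, C = 0L, normal = 0L)
  m2 <- rbind(A = 1L, B = 0L, C = 1L, normal = 0L)
  colnames(m1) <- colnames(m2) <- "e1"
  expect_identical(fitchScore(phy, asMutationMatrix(m1)), 1L)
  expect_identical(fitchScore(phy, asMutationMatrix(m2)), 2L)
  expect_error(
    fitchScore(ape::read.tree(text = "((A,X),(C,normal));"),
               asMutationMatrix(m1)),
    "mismatch")
})

test_that("Fitch scoring agrees with brute-force labelings and phangorn", {
  set.seed(9)
  for (i in 1:30) {
    nTaxa <- sample(4:6, 1)
    m <- randomBinaryMatrix(nTaxa, sample(3:12, 1))
    mm <- asMutationMatrix(m)
    topo <- phangorn::allTrees(nTaxa, rooted = FALSE,
                               tip.label = rownames(m))
    phy <- topo[[sample(length(topo), 1)]]
    sc <- fitchScore(phy, mm)
    expect_identical(sc, as.integer(bruteTreeScore(phy, m)))
    dat <- phangorn::phyDat(m, type = "USER", levels = c(0L, 1L))
    expect_identical(sc, as.integer(phangorn::fitch(phy, dat)))
  }
})

test_that("exhaustive search finds all and only minimum-score trees", {
  set.seed(21)
  # quartet: minimum over the 3 unrooted topologies, verified explicitly
  m <- randomBinaryMatrix(4, 8)
  mm <- asMutationMatrix(m)
  trees <- searchParsimony(mm)
  allTopo <- phangorn::allTrees(4, rooted = FALSE,
                                tip.label = rownames(m))
  scores <- vapply(allTopo, bruteTreeScore, numeric(1), m = m)
  expect_identical(treeScore(trees[[1]]), as.integer(min(scores)))
  expect_identical(length(trees), sum(scores == min(scores)))

  # truncal-only matrices: every topology ties at score = #columns
  tr <- matrix(1L, 3, 5,
               dimnames = list(c("S1", "S2", "S3"), paste0("e", 1:5)))
  tr <- rbind(tr, normal = 0L)
  trees <- searchParsimony(asMutationMatrix(tr))
  expect_identical(length(trees), 3L)
  expect_true(all(vapply(trees, treeScore, integer(1)) == 5L))
})

test_that("early-divergence simulations recover the lymph-node clade", {
  sim <- simulatePatient(nLesions = 4, lymphNodeEarly = TRUE,
                         mutationsPerClone = 10, seed = 77,
                         patientId = "PX")
  pres <- presenceSets(sim$variants, filterCnvs(sim$cnvs)$kept)
  mat <- buildBinaryMatrix(pres, "PX")
  trees <- searchParsimony(mat)
  expect_identical(length(trees), 1L)  # unique MP tree
  expect_match(newickString(trees[[1]]), "\\(PX_LN1:[0-9]+,PX_LN2:")
})

test_that("branch changes sum to the score and land on forced branches", {
  # truncal column: one change on the branch separating normal
  tr <- matrix(1L, 2, 3,
               dimnames = list(c("S1", "S2"), paste0("e", 1:3)))
  tr <- rbind(tr, normal = 0L)
  tree <- searchParsimony(asMutationMatrix(tr))[[1]]
  expect_identical(newickString(tree), "((S1:0,S2:0):3,normal:0);")

  # private column: change on the terminal branch
  pv <- rbind(S1 = c(1L, 1L), S2 = c(1L, 0L), normal = c(0L, 0L))
  colnames(pv) <- c("t", "p")
  tree <- searchParsimony(asMutationMatrix(pv))[[1]]
  expect_identical(newickString(tree), "((S1:1,S2:0):1,normal:0);")

  # conservation on random matrices
  set.seed(33)
  for (i in 1:20) {
    m <- randomBinaryMatrix(sample(4:6, 1), sample(4:10, 1))
    mm <- asMutationMatrix(m)
    tree <- searchParsimony(mm)[[1]]
    expect_identical(as.integer(sum(treePhylo(tree)$edge.length)),
                     fitchScore(tree, mm))
    expect_identical(treeScore(tree), fitchScore(tree, mm))
  }
})

test_that("bootstrap supports are deterministic and bounded", {
  # only supporting columns: the clade is in every replicate
  m <- rbind(S1 = c(1L, 1L, 1L, 1L), S2 = c(1L, 1L, 1L, 1L),
             S3 = c(0L, 0L, 0L, 0L))
  m <- m[, colSums(m) > 0]
  m <- rbind(m, normal = c(0L, 0L, 0L, 0L))
  colnames(m) <- paste0("e", 1:4)
  mm <- asMutationMatrix(m)
  b <- bootstrapSupport(mm, reps = 25, seed = 4)
  expect_identical(unname(b$supports[["S1|S2"]]), 100)

  one <- bootstrapSupport(mm, reps = 1, seed = 9)
  expect_true(all(one$supports %in% c(0, 100)))

  b2 <- bootstrapSupport(mm, reps = 25, seed = 4)
  expect_identical(b$supports, b2$supports)
  expect_identical(newickString(b$tree), newickString(b2$tree))
})

test_that("taxon-count bounds are enforced", {
  big <- matrix(1L, 13, 2,
                dimnames = list(c(paste0("S", 1:12), "normal"), c("a", "b")))
  big["normal", ] <- 0L
  expect_error(searchParsimony(asMutationMatrix(big)), "12 taxa")
})
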