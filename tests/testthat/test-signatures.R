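test_that("context counting bins SNVs pyrimidine-centrically", {
  one <- countContexts(variantRow(ref = "C", alt = "T", context = "ACA"))
  expect_identical(sum(spectrumCounts(one)), 1)
  expect_identical(unname(spectrumCounts(one)[["A[C>T]A"]]), 1)

  # purine reference on the forward strand folds onto the same bin
  rc <- countContexts(variantRow(ref = "G", alt = "A", context = "TGT"))
  expect_identical(unname(spectrumCounts(rc)[["A[C>T]A"]]), 1)

  empty <- countContexts(variantRow()[0, ])
  expect_identical(spectrumTotal(empty), 0)

  # indels are skipped with a count, missing SNV context errors
  withIndel <- variantTable(
    variantRow(),
    variantRow(ref = "AT", alt = "A", context = NA_character_,
               consequence = "indel"))
  sp <- countContexts(withIndel)
  expect_identical(sp@skipped, 1L)
  expect_identical(spectrumTotal(sp), 1)
  expect_error(countContexts(variantRow(context = NA_character_)),
               "without trinucleotide context")
})

test_that("context counting conserves SNV record counts", {
  set.seed(3)
  for (i in 1:5) {
    sim <- simulatePatient(nLesions = 2, seed = 300 + i)
    v <- sim$variants[sim$variants$sample_id ==
                        sim$variants$sample_id[1], ]
    sp <- countContexts(v)
    nSnv <- sum(nchar(v$ref) == 1 & nchar(v$alt) == 1)
    expect_identical(spectrumTotal(sp), as.numeric(nSnv))
    expect_identical(sp@skipped, nrow(v) - nSnv)
  }
})

test_that("forward-selection refit recovers mixtures", {
  cat5 <- makeToyCatalog(5, seed = 1)
  P <- signatureProbs(cat5)

  # pure signature, noiseless
  pure <- new("ContextSpectrum", sampleId = "pure",
              counts = stats::setNames(P[3, ] * 1000, contextLabels96()),
              skipped = 0L)
  w <- exposureWeights(refitExposures(pure, cat5))
  expect_gte(w[["TS03"]], 0.99)
  expect_identical(unname(sum(w > 0)), 1L)

  # exact 0.6/0.4 mixture matches the dense constrained-LS oracle
  v <- 0.6 * P[1, ] + 0.4 * P[2, ]
  mix <- new("ContextSpectrum", sampleId = "mix",
             counts = stats::setNames(v * 10000, contextLabels96()),
             skipped = 0L)
  w <- exposureWeights(refitExposures(mix, cat5))
  expect_equal(unname(w[1:2]), c(0.6, 0.4), tolerance = 0.01)
  oracle <- denseRefitOracle(v, cat5)
  expect_true(all(abs(w - oracle) <= 0.01))

  # weights under the reporting cutoff are zeroed
  v3 <- 0.67 * P[1, ] + 0.3 * P[2, ] + 0.03 * P[4, ]
  low <- new("ContextSpectrum", sampleId = "low",
             counts = stats::setNames(v3 * 10000, contextLabels96()),
             skipped = 0L)
  w3 <- exposureWeights(refitExposures(low, cat5, cutoff = 0.06))
  expect_identical(unname(w3[["TS04"]]), 0)

  expect_error(refitExposures(
    new("ContextSpectrum", sampleId = "z",
        counts = stats::setNames(numeric(96), contextLabels96()),
        skipped = 0L), cat5), "no binned")
})

test_that("refit reconstruction error never increases as the cutoff
           decreases", {
  cat5 <- makeToyCatalog(5, seed = 2)
  sp <- simulateContextSpectrum(cat5, c(0.5, 0.3, 0.2, 0, 0), n = 400,
                                sampleId = "s")
  v <- spectrumCounts(sp) / spectrumTotal(sp)
  errs <- vapply(c(0.3, 0.15, 0.06, 0.01, 0), function(cut) {
    w <- exposureWeights(refitExposures(sp, cat5, cutoff = cut))
    reconstructionError(w, v, cat5)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("small-scale parameter recovery from multinomial spectra", {
  cat5 <- makeToyCatalog(5, seed = 5)
  set.seed(11)
  cosines <- numeric(40)
  for (i in 1:40) {
    k <- sample(1:3, 1)
    true <- numeric(5)
    true[sample(5, k)] <- stats::rgamma(k, 2)
    true <- true / sum(true)
    sp <- simulateContextSpectrum(cat5, true, n = 500,
                                  sampleId = paste0("s", i))
    w <- exposureWeights(refitExposures(sp, cat5))
    cosines[i] <- sum(w * true) / sqrt(sum(w^2) * sum(true^2))
  }
  expect_gte(mean(cosines), 0.95)
})

test_that("exposure clustering uses Euclidean distances deterministically", {
  W <- rbind(a = c(1, 0, 0), b = c(1, 0, 0), c = c(0, 1, 0))
  cl <- clusterExposures(W, k = 2)
  expect_identical(cl$hclust$height[1], 0)           # identical pair
  expect_identical(cl$labels[["a"]], cl$labels[["b"]])
  expect_false(cl$labels[["a"]] == cl$labels[["c"]])

  # one-dimensional weights: merge heights follow linkage arithmetic
  W1 <- cbind(c(s1 = 0.1, s2 = 0.5, s3 = 0.9))
  cl1 <- clusterExposures(W1, linkage = "average", k = 2)
  lab <- cl1$labels
  valid <- identical(lab[["s1"]], lab[["s2"]]) ||
    identical(lab[["s2"]], lab[["s3"]])
  expect_true(valid && lab[["s1"]] != lab[["s3"]])
  expect_equal(sort(cl1$hclust$height), c(0.4, 0.6))

  expect_error(clusterExposures(W, k = 5), "exceeds")
})

test_that("samples group by the size of their cluster's shared signature
           set", {
  W <- rbind(
    a = c(TS01 = 0.9, TS02 = 0,   TS03 = 0,    TS04 = 0),
    b = c(0.8,        0,          0.15,        0),
    c = c(0.5,        0,          0.3,         0),
    d = c(0.3,        0.2,        0.3,         0.2),
    e = c(0.25,       0.25,       0.25,        0.25))
  labels <- c(a = 1L, b = 2L, c = 2L, d = 3L, e = 3L)
  g <- sharedSignatureGroups(W, labels, presenceCutoff = 0.06)
  expect_identical(unname(g[c("a", "b", "c", "d", "e")]),
                   c("1", "2", "2", ">=3", ">=3"))

  # empty shared set falls outside the scheme
  W0 <- rbind(x = c(1, 0), y = c(0, 1))
  expect_warning(
    g0 <- sharedSignatureGroups(W0, c(x = 1L, y = 1L)),
    "empty shared")
  expect_identical(unname(g0), c("0", "0"))
})

test_that("dendrograms serialize to nested lists", {
  W <- rbind(a = c(1, 0), b = c(0.9, 0.1), c = c(0, 1))
  cl <- clusterExposures(W, k = 2)
  d <- dendrogramToList(cl$hclust)
  expect_true(is.numeric(d$height))
  expect_identical(length(d$children), 2L)
  txt <- jsonlite::toJSON(d, auto_unbox = TRUE)
  expect_match(txt, "\"leaf\"")
})
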