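fakeVector <- function(values) {
  stats::setNames(values, thermalIndexNames())
}

# Reference built from three synthetic index vectors with known spread.
refFromValues <- function(valsets, form = "II") {
  buildReference(lapply(valsets, fakeVector), form)
}

test_that("reference statistics are mean and sd/sqrt(n)", {
  ref <- refFromValues(list(rep(2, 10), rep(4, 10), rep(6, 10)))
  expect_equal(unname(ref@stats[, "mean"]), rep(4, 10))
  expect_equal(unname(ref@stats[, "se"]), rep(2 / sqrt(3), 10),
               tolerance = 1e-12)
  expect_equal(unname(ref@stats[, "n"]), rep(3, 10))
  # identical vectors: SE = 0 everywhere
  ref0 <- refFromValues(list(rep(5, 10), rep(5, 10)))
  expect_equal(unname(ref0@stats[, "se"]), rep(0, 10))
  # single vector: degenerate, warned
  expect_warning(ref1 <- refFromValues(list(rep(5, 10))), "single")
  expect_equal(unname(ref1@stats[, "se"]), rep(0, 10))
  expect_error(buildReference(list(), "II"), "at least one")
})

test_that("one-sample t-test direction and significance", {
  # value equal to mean: never significant
  expect_equal(testIndex(4, 4, 1, 5), "not_significant")
  # frozen from the t CDF: mean 12, se 2/sqrt(3), n 3, value 20 ->
  # t = -6.93, df 2, p = 0.0202
  expect_equal(testIndex(20, 12, 2 / sqrt(3), 3, alpha = 0.05),
               "significant_higher")
  expect_equal(2 * pt(-abs((12 - 20) / (2 / sqrt(3))), df = 2), 0.0202,
               tolerance = 1e-4 / 0.0202)
  # just below the same p-value the call flips
  expect_equal(testIndex(20, 12, 2 / sqrt(3), 3, alpha = 0.02),
               "not_significant")
  expect_equal(testIndex(4, 12, 2 / sqrt(3), 3, alpha = 0.05),
               "significant_lower")
  # SE = 0: any deviation is significant, an exact match is not
  expect_equal(testIndex(5.001, 5, 0, 3), "significant_higher")
  expect_equal(testIndex(4.999, 5, 0, 3), "significant_lower")
  expect_equal(testIndex(5, 5, 0, 3), "not_significant")
  expect_error(testIndex(5, 5, 1, 5, alpha = 1.5), "alpha")
  expect_error(testIndex(5, 5, 1, 5, alpha = 0), "alpha")
})

test_that("per-index scores follow the direction table and thresholds", {
  ref <- refFromValues(list(rep(9, 10), rep(10, 10), rep(11, 10)))
  # all values at the mean: total 0, neutral
  sc <- scoreSequence(fakeVector(rep(10, 10)), ref)
  expect_equal(sum(sc$scores), 0)
  expect_equal(sc$classification, "neutral")
  # push three cold-direction indices far out: +3 -> cold
  v <- rep(10, 10)
  names(v) <- thermalIndexNames()
  v[c("n_gly", "n_ser", "n_acidic")] <- 40   # cold direction is "higher"
  sc3 <- scoreSequence(fakeVector(v), ref)
  expect_equal(sc3$total, 3)
  expect_equal(sc3$classification, "cold")
  # 4 cold + 1 hot = +3 -> still cold
  v2 <- v; v2["n_polar_uncharged"] <- 40; v2["n_pro"] <- 40  # pro: hot
  sc4 <- scoreSequence(fakeVector(v2), ref)
  expect_equal(sc4$total, 3)
  expect_equal(sc4$classification, "cold")
  # mirrored deviations classify hot at -3
  v3 <- rep(10, 10); names(v3) <- thermalIndexNames()
  v3[c("n_pro", "n_charged", "aliphatic_index")] <- 40  # hot direction
  sch <- scoreSequence(fakeVector(v3), ref)
  expect_equal(sch$total, -3)
  expect_equal(sch$classification, "hot")
  expect_equal(classifyTotal(c(-10, -3, -2, 0, 2, 3, 10)),
               c("hot", "hot", "neutral", "neutral", "neutral", "cold",
                 "cold"))
})

test_that("flipping the direction table negates every score", {
  ref <- refFromValues(list(rep(9, 10), rep(10, 10), rep(11, 10)))
  set.seed(7)
  v <- fakeVector(10 + sample(c(-30, 0, 30), 10, replace = TRUE))
  flip <- ifelse(defaultDirections() == "higher", "lower", "higher")
  names(flip) <- names(defaultDirections())
  a <- scoreSequence(v, ref, defaultDirections())
  b <- scoreSequence(v, ref, flip)
  expect_equal(b$scores, -a$scores)
  expect_equal(b$total, -a$total)
})

test_that("shrinking alpha only drops per-index scores, never flips them", {
  # p-values are fixed per index, so the significant set is nested in alpha:
  # each per-index score either keeps its value or falls to 0
  ref <- refFromValues(list(rep(8, 10), rep(10, 10), rep(12, 10)))
  set.seed(13)
  for (i in 1:10) {
    v <- fakeVector(10 + rnorm(10, sd = 6))
    alphas <- c(0.2, 0.05, 0.01, 0.001)
    prev <- scoreSequence(v, ref, alpha = alphas[1])$scores
    for (a in alphas[-1]) {
      cur <- scoreSequence(v, ref, alpha = a)$scores
      expect_true(all(cur == prev | cur == 0))
      # when every deviation points the same way, |total| is monotone too
      prev <- cur
    }
  }
  # uniformly cold-direction deviations: |total| shrinks with alpha
  cold <- fakeVector(ifelse(defaultDirections() == "higher", 16, 4))
  totals <- vapply(c(0.2, 0.05, 0.01, 0.001), function(a)
    abs(scoreSequence(cold, ref, alpha = a)$total), numeric(1))
  expect_true(all(diff(totals) <= 0))
  # alpha -> 0 with positive SEs: nothing is significant
  v <- fakeVector(10 + rnorm(10, sd = 6))
  expect_equal(scoreSequence(v, ref, alpha = 1e-12)$total, 0)
})

test_that("cohort scoring is order-invariant and summarises correctly", {
  ch <- cachedCohort(seed = 1)
  recs <- assembleRecords(ch$fasta, ch$metadata)
  refs <- buildReferencesFromRecords(recs)
  res <- scoreCohort(recs, refs)
  expect_equal(res$summary$n_scored, 20)
  expect_equal(res$summary$n_scored,
               with(res$summary$counts, cold + hot + neutral))
  res_rev <- scoreCohort(rev(recs), refs)
  reord <- res_rev$scores[match(res$scores$seq_id, res_rev$scores$seq_id), ]
  rownames(reord) <- NULL
  expect_equal(reord, res$scores)
  # even-count median rule: mean of the middle two
  expect_equal(res$summary$median_cold_total,
               stats::median(res$scores$total[
                 res$scores$classification == "cold"]))
})

test_that("empty cohorts and unknown forms are handled", {
  ch <- cachedCohort(seed = 1)
  recs <- assembleRecords(ch$fasta, ch$metadata)
  refs <- buildReferencesFromRecords(recs)
  empty <- scoreCohort(list(), refs)
  expect_equal(empty$summary$n_scored, 0)
  expect_equal(unlist(empty$summary$counts), c(cold = 0, hot = 0,
                                               neutral = 0))
  expect_true(is.na(empty$summary$median_cold_total))
  odd <- recs[[which(!vapply(recs, function(r) r@is_reference,
                             logical(1)))[1]]]
  slot(odd, "form") <- "IV"
  expect_warning(res <- scoreCohort(c(recs, odd), refs), "no reference")
  expect_equal(res$summary$n_skipped, 1)
})

test_that("direction tables load from YAML and reject incomplete ones", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(as.list(defaultDirections()), tmp)
  expect_equal(readDirectionTable(tmp), defaultDirections())
  bad <- as.list(defaultDirections())[1:9]
  yaml::write_yaml(bad, tmp)
  expect_error(readDirectionTable(tmp), "missing")
})
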