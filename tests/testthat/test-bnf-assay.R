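fm_from_matrix <- function(mat, condition, isolate = NULL) {
  samples <- data.frame(sample_id = colnames(mat),
                        condition = condition,
                        stringsAsFactors = FALSE)
  if (!is.null(isolate)) samples$isolate_id <- isolate
  structure(list(mz = seq_len(nrow(mat)) + 100, intensities = mat,
                 samples = samples),
            class = "feature_matrix")
}

test_that("Welch t-test per feature matches stats::t.test", {
  set.seed(21)
  mat <- matrix(rlnorm(10 * 8), nrow = 10,
                dimnames = list(sprintf("F%04d", 1:10), paste0("s", 1:8)))
  cond <- rep(c("15N", "14N"), each = 4)
  tests <- test_features(fm_from_matrix(mat, cond))
  ref <- apply(mat, 1, function(x) {
    stats::t.test(x[cond == "15N"], x[cond == "14N"])$p.value
  })
  expect_equal(tests$p, unname(ref))
})

test_that("degenerate features get defined p-values", {
  mat <- rbind(F0001 = c(1, 1, 1, 1, 1, 1),        # equal, zero variance
               F0002 = c(1, 1, 1, 2, 2, 2),        # differing, zero variance
               F0003 = c(5, 6, 7, 5, 6, 7))        # equal means, noise
  colnames(mat) <- paste0("s", 1:6)
  cond <- rep(c("15N", "14N"), each = 3)
  tests <- test_features(fm_from_matrix(mat, cond))
  expect_equal(tests$p[1], 1)
  expect_lt(tests$p[2], 1e-6)
  expect_gt(tests$p[3], 0.9)
  # the exhaustive permutation oracle agrees that {1,1,1} vs {2,2,2}
  # is as extreme as the labeling allows (p = 2/20)
  perm <- brute_permutation_p(c(1, 1, 1), c(2, 2, 2))
  expect_equal(perm, 0.1)
  expect_lt(tests$p[2], perm)
  expect_error(test_features(fm_from_matrix(mat[, 1:3, drop = FALSE],
                                            c("15N", "15N", "14N"))),
               "at least 2 samples")
})

test_that("p-values are invariant to sample order within groups", {
  set.seed(5)
  mat <- matrix(rlnorm(5 * 6), nrow = 5,
                dimnames = list(NULL, paste0("s", 1:6)))
  cond <- rep(c("15N", "14N"), each = 3)
  p1 <- test_features(fm_from_matrix(mat, cond))$p
  perm <- c(3, 1, 2, 6, 4, 5)
  p2 <- test_features(fm_from_matrix(mat[, perm], cond[perm]))$p
  expect_equal(p1, p2)
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(0.007), 0.007)
  expect_equal(bh_qvalues(rep(1, 5)), rep(1, 5))
  expect_error(bh_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH equals the brute-force step-up on random vectors", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(1:1000, 1)
    p <- runif(n)^sample(c(1, 2, 4), 1)
    expect_equal(bh_qvalues(p), brute_bh(p))
  }
})

test_that("biomarker selection is inclusive in q and strict in fold change", {
  tests <- data.frame(feature = c("a", "b", "c"),
                      p = c(0.001, 0.001, 0.5),
                      fold_change = c(1.5, 1.0, 2.0))
  tests$p <- c(0.03, 0.02, 1)   # q = BH over 3
  sel <- select_biomarkers(tests, q_threshold = 0.05, fc_threshold = 1)
  expect_equal(sel$feature, "a")   # b fails strict fc, c fails q
  q <- bh_qvalues(tests$p)
  expect_true(all(sel$q <= 0.05))
  expect_equal(nrow(select_biomarkers(tests[0, ], 0.05, 1)), 0L)

  # a feature sitting exactly on q = 0.05 is retained
  tests2 <- data.frame(feature = "x", p = 0.05, fold_change = 1.5)
  expect_equal(nrow(select_biomarkers(tests2)), 1L)
})

test_that("bnf_ratio sums mean relative intensities of common biomarkers", {
  # one biomarker at 3% (15N) vs 1.5% (14N) -> ratio 2
  mat <- rbind(F0001 = c(3, 3, 1.5, 1.5),
               F0002 = c(97, 97, 98.5, 98.5))
  colnames(mat) <- paste0("s", 1:4)
  fm <- fm_from_matrix(mat, c("15N", "15N", "14N", "14N"),
                       isolate = rep("isoA", 4))
  rim <- relative_intensities(fm)
  bm <- data.frame(feature = "F0001")
  out <- bnf_ratio(rim, bm, "isoA")
  expect_equal(out$bnf_ratio, 2)
  expect_equal(out$group, "C")

  # identical intensities across conditions -> ratio 1
  mat2 <- rbind(F0001 = c(3, 3, 3, 3), F0002 = c(7, 7, 7, 7))
  colnames(mat2) <- paste0("s", 1:4)
  rim2 <- relative_intensities(
    fm_from_matrix(mat2, c("15N", "15N", "14N", "14N"),
                   isolate = rep("isoA", 4)))
  expect_equal(bnf_ratio(rim2, data.frame(feature = "F0001"),
                         "isoA")$bnf_ratio, 1)
  expect_error(bnf_ratio(rim2, data.frame(feature = "F0001"), "nope"),
               "unknown isolate")
})

test_that("BNF ratio is invariant to global per-sample scaling", {
  dat <- recovery_sim(seed = 314, n_metabolites = 10)
  fm <- align_peaks(dat$sim$peaks, dat$sim$samples, tolerance = 0.01)
  biomarkers <- select_biomarkers(test_features(fm))
  fm2 <- fm
  s15 <- fm2$samples$condition == "15N"
  fm2$intensities[, s15] <- fm2$intensities[, s15] * 10
  isolates <- unique(fm$samples$isolate_id)
  for (iso in isolates[1:5]) {
    expect_equal(
      bnf_ratio(relative_intensities(fm2), biomarkers, iso)$bnf_ratio,
      bnf_ratio(relative_intensities(fm), biomarkers, iso)$bnf_ratio)
  }
})

test_that("biomarkers absent in one condition drop from the common set", {
  mat <- rbind(F0001 = c(5, 5, 0, 0),    # 15N only
               F0002 = c(2, 2, 1, 1),
               F0003 = c(93, 93, 99, 99))
  colnames(mat) <- paste0("s", 1:4)
  fm <- fm_from_matrix(mat, c("15N", "15N", "14N", "14N"),
                       isolate = rep("isoA", 4))
  rim <- relative_intensities(fm)
  bm <- data.frame(feature = c("F0001", "F0002"))
  out <- bnf_ratio(rim, bm, "isoA")
  expect_equal(out$n_common, 1L)
  expect_equal(out$bnf_ratio, 2)
  # include_all keeps both biomarkers in the sums
  out2 <- bnf_ratio(rim, bm, "isoA", include_all = TRUE)
  expect_equal(out2$n_common, 2L)
  expect_equal(out2$bnf_ratio, 7 / 1)
  # a fully 15N-exclusive biomarker set is undetermined (group F)
  out3 <- bnf_ratio(rim, data.frame(feature = "F0001"), "isoA")
  expect_true(is.na(out3$bnf_ratio))
  expect_equal(out3$group, "F")
})

test_that("group assignment partitions ratios with left-closed bounds", {
  expect_equal(assign_group(c(4.6, 3.5, 2.5, 1.5, 0.6, NA)),
               c("A", "B", "C", "D", "E", "F"))
  expect_equal(assign_group(c(4, 3, 2, 1)), c("A", "B", "C", "D"))
  expect_error(assign_group(-0.5), "negative")
  # every ratio maps to exactly one group
  x <- seq(0, 10, by = 0.01)
  g <- assign_group(x)
  expect_true(all(g %in% c("A", "B", "C", "D", "E")))
  expect_equal(length(g), length(x))
})

test_that("bnf_summary mirrors the group table layout", {
  res <- data.frame(group = c("A", "D", "D", "F"))
  s <- bnf_summary(res)
  expect_equal(s$group, c("A", "B", "C", "D", "E", "F"))
  expect_equal(s$n_isolates, c(1L, 0L, 0L, 2L, 0L, 1L))
})
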