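test_that("confusion metrics match hand arithmetic", {
  m <- confusion_metrics(TP = 20, TN = 425, FP = 0, FN = 95)
  expect_equal(m$sensitivity, 20 / 115)
  expect_equal(round(m$sensitivity, 4), 0.1739)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 445 / 540)

  perfect <- confusion_metrics(TP = 10, TN = 10, FP = 0, FN = 0)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$MCC, 1)

  degenerate <- confusion_metrics(TP = 10, TN = 0, FP = 10, FN = 0)
  expect_equal(degenerate$MCC, 0)  # zero-denominator convention

  expect_error(confusion_metrics(0, 5, 5, 0), "positives")
  expect_error(confusion_metrics(5, 0, 0, 5), "negatives")
})

test_that("MCC is symmetric under simultaneous class/prediction swap (property)", {
  set.seed(9)
  for (i in 1:20) {
    tp <- sample(1:50, 1); tn <- sample(1:50, 1)
    fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    a <- confusion_metrics(tp, tn, fp, fn)$MCC
    b <- confusion_metrics(tn, tp, fn, fp)$MCC
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("AUC equals the Mann-Whitney pair-counting oracle", {
  expect_equal(roc_auc(c(5, 4, 3, 2), c(1, 1, -1, -1))$auc, 1)
  expect_equal(roc_auc(rep(1, 20), rep(c(1, -1), 10))$auc, 0.5)
  set.seed(31)
  for (rep in 1:20) {
    n <- 50
    scores <- round(rnorm(n), 1)  # rounding forces ties
    labels <- sample(c(1, -1), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    pos <- scores[labels > 0]; neg <- scores[labels < 0]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(r$auc, mean(pairs), tolerance = 1e-12)
    # curve is monotone in both coordinates
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation and is rank-invariant", {
  skip_if_not_installed("pROC")
  set.seed(17)
  scores <- rnorm(80)
  labels <- sample(c(1, -1), 80, replace = TRUE)
  ours <- roc_auc(scores, labels)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                               direction = "<",
                                               levels = c(-1, 1))))
  expect_equal(ours, ref, tolerance = 1e-12)
  # invariant under a strictly monotone transform of the scores
  expect_equal(roc_auc(exp(scores), labels)$auc, ours, tolerance = 1e-12)
})

test_that("select_threshold maximizes accuracy with specificity/threshold tie-breaks", {
  # separable scores: any threshold in (2, 3] attains accuracy 1;
  # the tie rule picks the largest in-grid value
  scores <- c(5, 4, 3, 2, 1, 0)
  labels <- c(1, 1, 1, -1, -1, -1)
  grid <- seq(-1, 5, by = 0.5)
  t <- select_threshold(scores, labels, grid)
  expect_equal(t, 3)
  expect_equal(select_threshold(scores, labels, 0.25), 0.25)
  # oracle re-check on random data: no other grid point beats the selection
  set.seed(23)
  s2 <- rnorm(60); l2 <- sample(c(1, -1), 60, replace = TRUE)
  g2 <- seq(-2, 2, by = 0.1)
  best <- select_threshold(s2, l2, g2)
  acc <- vapply(g2, function(t) mean((s2 >= t) == (l2 > 0)), numeric(1))
  expect_equal(mean((s2 >= best) == (l2 > 0)), max(acc))
})

test_that("cross-validation scores every example exactly once and is seeded", {
  b <- small_bundles()$SH3
  cv <- cross_validate(b, "PSSM", seed = 4)
  n <- nrow(b$positives) + nrow(b$negatives)
  m <- cv$metrics
  expect_equal(m$TP + m$TN + m$FP + m$FN, n)
  expect_length(cv$scores, n)
  cv2 <- cross_validate(b, "PSSM", seed = 4)
  expect_identical(cv$scores, cv2$scores)
  expect_equal(cv$metrics$MCC, cv2$metrics$MCC)
  # binary methods carry no ROC
  expect_null(cross_validate(b, "MIM", seed = 4)$roc)
  expect_null(cross_validate(b, "RES", seed = 4)$roc)
})

test_that("tripeptide selection and PSSM are fold-local (no test-fold leakage)", {
  # A sequence that appears only once cannot lend its tripeptides or
  # frequencies to the fold in which it is tested.  Probe: a PSSM trained
  # within CV must assign probability 0 to a residue unique to one test
  # peptide, so its background_odds score is 0 -- which can only happen if
  # the matrix excluded it.
  pos <- ligand_entries(c("WWWWWW", random_peptides(24, 6, seed = 61)), "SH3")
  neg <- ligand_entries(random_peptides(25, 6, seed = 62), "SH3")
  # make every other peptide tryptophan-free so W at position 1 is unique
  pos$sequence[-1] <- gsub("W", "A", pos$sequence[-1])
  neg$sequence <- gsub("W", "A", neg$sequence)
  b <- dataset_bundle("SH3", pos, neg)
  cv <- cross_validate(b, "PSSM", seed = 5)
  # locate the all-W peptide in the pooled score vector by replaying the
  # deterministic fold assignment
  f <- make_folds(b, 5, seed = 5)
  pooled_idx <- unlist(lapply(1:5, function(k)
    c(which(f$pos_fold == k), -which(f$neg_fold == k))))
  w_at <- which(pooled_idx == 1L)  # positive #1 is WWWWWW
  # its test-fold matrix never saw W, so its score must be exactly 0; a
  # leaky matrix built on the full data would score it (1/25 * 20)^6 > 0
  expect_identical(cv$scores[w_at], 0)
  expect_true(cv$labels[w_at])
})

test_that("composition_summary averages per-class AAC", {
  out <- composition_summary(list(one = "PPPPPP",
                                  two = c("PPPPPP", "GGGGGG")))
  expect_equal(out["one", "P"], 100)
  expect_equal(out["two", "P"], 50)
  expect_equal(out["two", "G"], 50)
  same <- composition_summary(list(a = c("ACDEFG"), b = c("ACDEFG")))
  expect_equal(same["a", ], same["b", ])
  # planted proline-rich class exceeds uniform background in mean P
  b <- small_bundles()
  cs <- composition_summary(list(
    SH3 = b$SH3$positives$sequence,
    background = attr(b, "background")$sequence))
  expect_gt(cs["SH3", "P"], cs["background", "P"])
})
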