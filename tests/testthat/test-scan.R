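# End-to-end scanning: union combination, ordering, determinism.

make_scan_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    b <- small_bundles()$SH3
    cache <<- list(
      bundle = b,
      model = svm_train(b, seed = 1),
      pssm = build_pssm(b$positives$sequence, 6, domain_class = "SH3"),
      ilib = instance_library(b$positives$sequence, "SH3"))
    cache
  }
})

test_that("a planted instance is reported in the MIM column under union semantics", {
  fx <- make_scan_fixture()
  planted <- fx$bundle$positives$sequence[1]
  gp <- generate_proteins(1, c(40, 40),
                          embedded = data.frame(peptide = planted,
                                                domain_class = "SH3"),
                          seed = 31)
  cfg <- scan_config("SH3", c("MIM"), instance_lib = fx$ilib)
  hits <- scan_sequences(gp$records, cfg)
  row <- hits[hits$start == gp$truth$start, ]
  expect_equal(nrow(row), 1L)
  expect_match(row$mim_instance, planted, fixed = TRUE)
  expect_true(is.na(row$svm_score))  # unselected methods stay empty
})

test_that("an unreachable SVM threshold empties the table; hits grow as it drops", {
  fx <- make_scan_fixture()
  gp <- generate_proteins(2, c(50, 60), seed = 32)
  hi <- scan_config("SH3", "SVM", svm_model = fx$model, svm_threshold = 1e6)
  expect_equal(nrow(scan_sequences(gp$records, hi)), 0L)
  lo <- scan_config("SH3", "SVM", svm_model = fx$model, svm_threshold = -1e6)
  n_all <- sum(vapply(gp$records, function(r) r$length - 6 + 1, numeric(1)))
  expect_equal(nrow(scan_sequences(gp$records, lo)), n_all)
})

test_that("rows are position-ordered, within-window, and count agreeing methods", {
  fx <- make_scan_fixture()
  planted <- fx$bundle$positives$sequence[2]
  gp <- generate_proteins(1, c(60, 60),
                          embedded = data.frame(peptide = planted,
                                                domain_class = "SH3"),
                          seed = 33)
  cfg <- scan_config("SH3", c("SVM", "PSSM", "RES", "MIM"),
                     svm_model = fx$model, pssm = fx$pssm,
                     instance_lib = fx$ilib, svm_threshold = -1e6,
                     pssm_threshold = 0)
  hits <- scan_sequences(gp$records, cfg)
  expect_true(!is.unsorted(hits$start))
  expect_true(all(hits$end - hits$start + 1L == 6L))
  # the planted window is called by SVM, PSSM and MIM at least
  row <- hits[hits$start == gp$truth$start, ]
  expect_gte(row$n_methods_agreeing, 3)
  # union output is a superset of each single method's output
  for (meth in c("SVM", "PSSM", "RES", "MIM")) {
    single <- scan_sequences(gp$records,
                             scan_config("SH3", meth,
                                         svm_model = fx$model, pssm = fx$pssm,
                                         instance_lib = fx$ilib,
                                         svm_threshold = -1e6,
                                         pssm_threshold = 0))
    expect_true(all(single$start %in% hits$start))
  }
})

test_that("records shorter than the window are skipped with a warning", {
  fx <- make_scan_fixture()
  cfg <- scan_config("SH3", "MIM", instance_lib = fx$ilib)
  recs <- list(seq_record("short", "PPP"),
               seq_record("ok", "AAKPRPLPVAAA"))
  expect_warning(hits <- scan_sequences(recs, cfg), "shorter than")
  expect_false("short" %in% hits$parent_id)
})

test_that("re-running a scan writes byte-identical output", {
  fx <- make_scan_fixture()
  gp <- generate_proteins(3, c(50, 80), seed = 35)
  cfg <- scan_config("SH3", c("SVM", "RES"), svm_model = fx$model,
                     svm_threshold = -1)
  p1 <- tempfile(); p2 <- tempfile()
  write_hits_table(scan_sequences(gp$records, cfg), p1)
  write_hits_table(scan_sequences(gp$records, cfg), p2)
  expect_identical(readLines(p1, encoding = "UTF-8"),
                   readLines(p2, encoding = "UTF-8"))
})

test_that("peptide-level union calls obey the union monotonicity", {
  fx <- make_scan_fixture()
  pep <- fx$bundle$positives$sequence[3]
  cfg_mim <- scan_config("SH3", "MIM", instance_lib = fx$ilib)
  expect_true(peptide_level_call(pep, cfg_mim))
  # random peptide sharing no library substring -> FALSE
  expect_false(peptide_level_call("ACDEFG", instance_library("WWWWWW") |>
                                    (\(l) scan_config("SH3", "MIM",
                                                      instance_lib = l))()))
  # the union call rate dominates any single method's call rate
  qs <- random_peptides(30, 6, seed = 36)
  cfg_union <- scan_config("SH3", c("RES", "MIM"), instance_lib = fx$ilib)
  cfg_res <- scan_config("SH3", "RES")
  union_rate <- mean(vapply(qs, peptide_level_call, logical(1), cfg_union))
  res_rate <- mean(vapply(qs, peptide_level_call, logical(1), cfg_res))
  expect_gte(union_rate, res_rate)
})

test_that("scan_config validates that selected methods have their resources", {
  expect_error(scan_config("SH3", "SVM"), "svm_model")
  expect_error(scan_config("SH3", "PSSM"), "pssm")
  expect_error(scan_config("SH3", "MIM"), "instance_lib")
  expect_s3_class(scan_config("SH3", "RES"), "scan_config")
})
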