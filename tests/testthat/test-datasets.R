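test_that("collapse_redundant keeps one copy per (sequence, protein, start) and is idempotent", {
  e <- ligand_entries(sequence = c("KPRPLP", "KPRPLP", "KPRPLP", "KPRPLP"),
                      domain_class = "SH3",
                      protein_id = c("A", "A", "B", "A"),
                      start = c(10L, 10L, 10L, 33L))
  out <- collapse_redundant(e)
  expect_equal(nrow(out), 3L)  # same-protein same-position duplicate dropped
  expect_equal(nrow(collapse_redundant(out)), 3L)  # idempotent
  expect_equal(nrow(collapse_redundant(e[0, ])), 0L)
})

test_that("unbalanced negatives are the exact union of the other classes plus background", {
  b <- small_bundles()
  # 30 SH3 / 35 WW / 40 PDZ positives, 30 background
  expect_equal(nrow(b$SH3$negatives), 35L + 40L + 30L)
  expect_equal(nrow(b$WW$negatives), 30L + 40L + 30L)
  expect_equal(nrow(b$PDZ$negatives), 30L + 35L + 30L)
  # all negatives cut to the target window length
  expect_true(all(nchar(b$PDZ$negatives$sequence) == 4L))
  expect_true(all(nchar(b$SH3$negatives$sequence) == 6L))
})

test_that("balanced negatives follow the per-pool quotas", {
  b <- small_bundles()
  pos_sets <- list(SH3 = b$SH3$positives, WW = b$WW$positives,
                   PDZ = b$PDZ$positives)
  bg <- attr(b, "background")
  neg <- assemble_negatives("SH3", pos_sets, bg, "balanced",
                            quotas = c(WW = 10L, PDZ = 10L, background = 10L),
                            seed = 5)
  expect_equal(nrow(neg), 30L)
  expect_equal(sum(neg$domain_class == "WW"), 10L)
  expect_equal(sum(neg$domain_class == "background"), 10L)
  # same seed reproduces the same subsample
  neg2 <- assemble_negatives("SH3", pos_sets, bg, "balanced",
                             quotas = c(WW = 10L, PDZ = 10L, background = 10L),
                             seed = 5)
  expect_identical(neg$sequence, neg2$sequence)
  expect_error(
    assemble_negatives("SH3", pos_sets, bg, "balanced",
                       quotas = c(WW = 999L, PDZ = 10L, background = 10L),
                       seed = 5),
    "exceeds pool")
})

test_that("sample_background is seeded, validates n, and handles a forced single window", {
  recs <- lapply(1:4, function(i) seq_record(paste0("r", i),
                                             random_peptides(1, 30, seed = i)))
  a <- sample_background(recs, 25, 6, seed = 99)
  b <- sample_background(recs, 25, 6, seed = 99)
  expect_identical(a$sequence, b$sequence)
  expect_true(all(nchar(a$sequence) == 6L))
  # peptides really come from the claimed (protein, start) positions
  for (k in seq_len(nrow(a))) {
    src <- recs[[match(a$protein_id[k], vapply(recs, `[[`, "", "id"))]]
    expect_equal(substr(src$sequence, a$start[k], a$start[k] + 5L),
                 a$sequence[k])
  }
  expect_error(sample_background(recs, 0, 6), "positive count")
  expect_error(sample_background(recs, 5, 64), "shorter than L")

  one <- list(seq_record("only", "KPRPLP"))
  forced <- sample_background(one, 3, 6, seed = 1)
  expect_equal(forced$sequence, rep("KPRPLP", 3))
})

test_that("fold assignment is stratified, exhaustive, disjoint and seeded", {
  b <- small_bundles()$SH3
  f <- make_folds(b, 5, seed = 3)
  expect_equal(sort(unique(f$pos_fold)), 1:5)
  # stratum fold sizes differ by at most 1
  expect_lte(diff(range(table(f$pos_fold))), 1)
  expect_lte(diff(range(table(f$neg_fold))), 1)
  # every example in exactly one fold
  expect_length(f$pos_fold, nrow(b$positives))
  expect_length(f$neg_fold, nrow(b$negatives))
  f2 <- make_folds(b, 5, seed = 3)
  expect_identical(f$pos_fold, f2$pos_fold)
  # 10+10 examples in 5 folds: exactly 2 positives and 2 negatives each
  tiny <- dataset_bundle("SH3",
                         ligand_entries(random_peptides(10, 6, seed = 1), "SH3"),
                         ligand_entries(random_peptides(10, 6, seed = 2), "SH3"))
  ft <- make_folds(tiny, 5, seed = 1)
  expect_true(all(table(ft$pos_fold) == 2))
  expect_true(all(table(ft$neg_fold) == 2))
  expect_error(make_folds(dataset_bundle("SH3",
                                         tiny$positives[1:3, ],
                                         tiny$negatives), 5, seed = 1),
               "at least 5")
})

test_that("dataset TSV round-trips through write_dataset_tsv / read_dataset_tsv", {
  b <- small_bundles()$WW
  path <- tempfile(fileext = ".tsv")
  write_dataset_tsv(b, path)
  back <- read_dataset_tsv(path)
  expect_equal(back$domain_class, "WW")
  expect_equal(back$positives$sequence, b$positives$sequence)
  expect_equal(back$negatives$sequence, b$negatives$sequence)
  expect_equal(back$positives$is_c_terminal, b$positives$is_c_terminal)
})
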