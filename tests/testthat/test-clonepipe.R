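test_that("background filtering applies the strict 0.1% rule per recipient", {
  # hand-computed: assigned total 6000, threshold 0.001 -> cut-off at 6 reads
  cm <- cm_fixture(matrix(c(5000, 4, 996), 3, 1,
                          dimnames = list(c("A", "B", "C"), "R1")))
  f <- filter_background(cm, 0.001)
  expect_equal(unname(f$counts[, 1]), c(5000, 0, 996))

  # threshold 0 changes nothing
  expect_equal(filter_background(cm, 0)$counts, cm$counts)

  # boundary: exactly at threshold is kept (strict <)
  cm2 <- cm_fixture(matrix(rep(1, 4), 4, 1,
                           dimnames = list(letters[1:4], "R1")))
  expect_equal(filter_background(cm2, 0.25)$counts, cm2$counts)

  # per-recipient: a barcode can be background in one recipient only
  cm3 <- cm_fixture(matrix(c(5, 9995, 500, 500), 2, 2,
                           dimnames = list(c("A", "B"), c("R1", "R2"))))
  f3 <- filter_background(cm3, 0.001)
  expect_equal(unname(f3$counts["A", ]), c(0, 500))

  expect_error(filter_background(cm, 1.5), "threshold")
})

test_that("multi-parental barcodes are excluded everywhere", {
  mat <- matrix(c(10, 0, 5,
                  8, 9, 7,
                  0, 4, 6), 3, 3, byrow = TRUE,
                dimnames = list(c("X", "Y", "Z"), c("P1", "P2", "D1")))
  cm <- cm_fixture(mat, roles = c("parental", "parental", "daughter"),
                   wells = c(1L, 2L, NA))
  out <- exclude_multi_parental(cm)
  # Y is in P1 and P2 -> gone from every recipient, including D1
  expect_false("Y" %in% rownames(out$counts))
  excl <- attr(out, "excluded")
  expect_equal(excl$barcode, "Y")
  expect_equal(excl$parental_ids, "P1,P2")
  # X is in P1 + daughter only: sharing with daughters is signal, kept
  expect_true("X" %in% rownames(out$counts))
  # Z is in one parental only: kept
  expect_true("Z" %in% rownames(out$counts))

  # no parental recipients: no-op with a warning
  cmp <- cm_fixture(mat, roles = rep("plain", 3))
  expect_warning(res <- exclude_multi_parental(cmp), "no-op")
  expect_equal(res$counts, cmp$counts)
})

test_that("normalization rescales each recipient to the target total", {
  cm <- cm_fixture(matrix(c(50, 150), 2, 1,
                          dimnames = list(c("A", "C"), "R1")))
  ct <- normalize_counts(cm)
  expect_equal(unname(ct$normalized[, 1]), c(250000, 750000))

  # single barcode -> the whole scale
  one <- cm_fixture(matrix(7, 1, 1, dimnames = list("A", "R1")))
  expect_equal(unname(normalize_counts(one)$normalized[1, 1]), 1e6)

  # idempotence: renormalizing a normalized matrix is a fixed point
  again <- normalize_counts(cm_fixture(ct$normalized))
  expect_equal(again$normalized, ct$normalized)

  expect_error(normalize_counts(cm, scale = -1), "scale")
})

test_that("the full pipeline recovers ground-truth clones in a clean run", {
  # sigma 0, error-free, dispersion 0, deep reads: every engrafted barcode
  # sits far above threshold, so kept barcodes = barcodes engrafted in the
  # parental recipients (minus multi-parental collisions, handled below)
  lib <- tiny_library(n = 1000, length = 8, seed = 41)
  m <- expansion_model(n_cells_per_well = 100, n_wells = 2,
                       transduction_efficiency = 0.5,
                       log_expansion_mean = log(1000),
                       log_expansion_sd = 0, pcr_dispersion = 0,
                       seq_error_rate = 0, reads_per_recipient = 1e6,
                       engraftment_fraction = 1, seed = 19)
  des <- pre_culture_design(n_wells = 2, n_daughters = 2)
  sim <- simulate_experiment(m, design = des, library = lib)
  ct <- run_pipeline(sim$counts)

  tr <- sim$truth
  kept_expected <- character(0)
  par_rec <- des$recipient[des$role == "parental"]
  eng_bc <- rowsum(tr$engrafted, tr$clones$barcode)
  present <- eng_bc[, par_rec, drop = FALSE] > 0
  multi <- rownames(eng_bc)[rowSums(present) >= 2]
  kept_expected <- setdiff(rownames(eng_bc)[rowSums(eng_bc) > 0], multi)
  expect_setequal(ct$kept_barcodes, kept_expected)
  expect_true(all(ct$exclusions$barcode %in% multi))

  # empty matrix -> empty clone table
  empty <- count_matrix(matrix(numeric(0), 0, 2,
                               dimnames = list(character(0), c("R1", "R2"))))
  ct0 <- run_pipeline(empty)
  expect_equal(nrow(ct0$normalized), 0L)
})

test_that("pipeline invariants hold over random matrices", {
  for (s in 1:12) {
    cm <- random_count_matrix(seed = 100 + s)
    ct <- suppressWarnings(run_pipeline(cm))
    # per-recipient totals at scale
    tot <- colSums(ct$normalized)
    expect_true(all(abs(tot[tot > 0] - 1e6) <= 1e-6 * 1e6))
    # the set surviving the background filter shrinks as threshold grows;
    # the composite pipeline's kept set is always a subset of the survivors
    # (the multi-parental rule is applied to post-filter presence, so it can
    # re-admit a barcode at a higher threshold — exclusion, not filtering)
    kept_prev <- NULL
    for (thr in c(0, 0.001, 0.01, 0.05)) {
      filt <- filter_background(cm, thr)
      survivors <- rownames(filt$counts)[rowSums(filt$counts) > 0]
      if (!is.null(kept_prev)) expect_true(all(survivors %in% kept_prev))
      kept_prev <- survivors
      kept <- suppressWarnings(run_pipeline(cm, threshold = thr))$kept_barcodes
      expect_true(all(kept %in% survivors))
    }
    # excluded multi-parental barcodes vanish from every recipient
    excl <- ct$exclusions$barcode[ct$exclusions$reason == "multi_parental"]
    expect_true(all(!excl %in% rownames(ct$normalized)))
  }
})

test_that("clone tables round-trip through TSV with exclusions", {
  cm <- random_count_matrix(seed = 321)
  ct <- suppressWarnings(run_pipeline(cm))
  path <- withr::local_tempfile(fileext = ".tsv")
  excl_path <- withr::local_tempfile(fileext = ".tsv")
  write_clone_table(ct, path, exclusions_path = excl_path)
  back <- read_clone_table(path, exclusions_path = excl_path)
  expect_equal(back$normalized, ct$normalized, tolerance = 1e-12)
  expect_equal(back$roles, ct$roles)
  expect_equal(back$threshold, ct$threshold)
  expect_equal(back$scale, ct$scale)
  expect_equal(back$exclusions$barcode, ct$exclusions$barcode)
  expect_equal(back$assigned_reads, ct$assigned_reads)
  expect_equal(back$input_assigned_reads, ct$input_assigned_reads)
})
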