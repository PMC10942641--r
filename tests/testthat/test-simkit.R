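test_that("clone sizes follow the lognormal law with seed determinism", {
  m0 <- expansion_model(n_cells_per_well = 500, n_wells = 1,
                        transduction_efficiency = 1,
                        log_expansion_mean = log(100),
                        log_expansion_sd = 0, seed = 5)
  cl <- simulate_clone_sizes(m0)
  # sigma = 0 degenerates: every clone has the same size
  expect_true(all(cl$harvest_count == cl$harvest_count[1]))

  # identical model + seed -> identical output
  expect_identical(simulate_clone_sizes(m0), simulate_clone_sizes(m0))

  # clone-size dispersion matches the lognormal closed forms. The linear-
  # scale CV at sigma = 1.5 is dominated by single jackpot clones (the 4th
  # moment grows as exp(9 sigma^2)), so a single 1000-clone draw scatters
  # far beyond 10%; the CV oracle is checked as a mean over replicates at a
  # moderate sigma, and the sigma = 1.5 case on the log scale where the
  # sample moment concentrates.
  cv_at <- function(sig, seed) {
    m <- expansion_model(n_cells_per_well = 1000, n_wells = 1,
                         transduction_efficiency = 1,
                         log_expansion_mean = log(1e4),
                         log_expansion_sd = sig, seed = seed)
    x <- simulate_clone_sizes(m)$harvest_count
    stats::sd(x) / mean(x)
  }
  cv_expected <- sqrt(exp(0.8^2) - 1)
  cv_mean <- mean(vapply(1:20, function(s) cv_at(0.8, s), numeric(1)))
  expect_lt(abs(cv_mean - cv_expected) / cv_expected, 0.10)

  m15 <- expansion_model(n_cells_per_well = 1000, n_wells = 1,
                         transduction_efficiency = 1,
                         log_expansion_mean = log(1e4),
                         log_expansion_sd = 1.5, seed = 1)
  sizes <- simulate_clone_sizes(m15)$harvest_count
  expect_lt(abs(stats::sd(log(sizes)) - 1.5) / 1.5, 0.10)

  expect_error(expansion_model(log_expansion_sd = -1), "log_expansion_sd")
})

test_that("barcode assignment is uniform with explicit collision reporting", {
  lib1 <- barcode_library("ACGTACGT")
  cl <- data.frame(clone_id = "c1", well = 1L, transduced = TRUE,
                   harvest_count = 10L)
  tr <- assign_barcodes(cl, lib1, seed = 1)
  expect_equal(tr$clones$barcode, "ACGTACGT")

  # no transduced clones -> empty ground truth
  cl0 <- data.frame(clone_id = "c1", well = 1L, transduced = FALSE,
                    harvest_count = 10L)
  expect_equal(nrow(assign_barcodes(cl0, lib1, seed = 1)$clones), 0L)

  expect_error(assign_barcodes(cl, structure(list(barcodes = character(0)),
                                            class = "barcode_library")),
               "empty")

  # collision count matches the occupancy closed form:
  # E[#barcodes with >= 2 clones] = N (1 - (1-1/N)^m - m/N (1-1/N)^(m-1))
  lib <- tiny_library(n = 100, seed = 3)
  m <- 50
  clm <- data.frame(clone_id = paste0("c", 1:m), well = 1L,
                    transduced = TRUE, harvest_count = 10L)
  n_coll <- vapply(1:200, function(s) {
    assign_barcodes(clm, lib, seed = s)$n_collisions
  }, numeric(1))
  N <- 100
  expected <- N * (1 - (1 - 1 / N)^m - m / N * (1 - 1 / N)^(m - 1))
  se <- stats::sd(n_coll) / sqrt(length(n_coll))
  expect_lt(abs(mean(n_coll) - expected), 3 * se + 1e-9)
})

test_that("recipient splitting thins harvests per design", {
  lib <- tiny_library(n = 200, seed = 7)
  m <- expansion_model(n_cells_per_well = 30, n_wells = 1,
                       transduction_efficiency = 1, seed = 2)
  cl <- simulate_clone_sizes(m)
  tr <- assign_barcodes(cl, lib, seed = 2)

  # one recipient taking everything at full engraftment: identity
  des1 <- clonetrackr:::new_split_design(data.frame(
    recipient = "R1", role = "plain", well_of_origin = NA_integer_,
    frac_well_1 = 1.0, stringsAsFactors = FALSE))
  tr1 <- split_recipients(tr, des1, engraftment_fraction = 1, seed = 2)
  expect_equal(unname(tr1$engrafted[, "R1"]), tr$clones$harvest_count)

  # pre-culture design: exactly 5 parental + 5 daughter recipients
  des <- pre_culture_design()
  expect_equal(sum(des$role == "parental"), 5L)
  expect_equal(sum(des$role == "daughter"), 5L)

  # daughter expectation: harvest x 0.5 x 1/5 x engraftment over replicates
  m5 <- expansion_model(n_cells_per_well = 20, n_wells = 5,
                        transduction_efficiency = 1,
                        log_expansion_mean = log(500),
                        log_expansion_sd = 0, seed = 3)
  cl5 <- simulate_clone_sizes(m5)
  tr5 <- assign_barcodes(cl5, lib, seed = 3)
  q <- 0.4
  draws <- vapply(1:200, function(s) {
    mean(split_recipients(tr5, des, engraftment_fraction = q,
                          seed = s)$engrafted[, "D1"])
  }, numeric(1))
  expected <- mean(cl5$harvest_count) * 0.5 * (1 / 5) * q
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected), 3 * se)

  # fractions summing above one are rejected
  expect_error(clonetrackr:::new_split_design(data.frame(
    recipient = c("A", "B"), role = "plain", well_of_origin = NA_integer_,
    frac_well_1 = c(0.7, 0.7), stringsAsFactors = FALSE)), "sum")
})

test_that("clones never appear in recipients they were not allocated to", {
  lib <- tiny_library(n = 500, seed = 13)
  m <- expansion_model(n_cells_per_well = 50, n_wells = 3,
                       reads_per_recipient = 2000, seed = 8)
  des <- pre_culture_design(n_wells = 3, n_daughters = 2)
  sim <- simulate_experiment(m, design = des, library = lib)
  tr <- sim$truth
  fr <- clonetrackr:::design_fractions(des)
  for (j in seq_len(nrow(des))) {
    zero_wells <- which(fr[j, ] == 0)
    off <- tr$clones$well %in% zero_wells
    expect_true(all(tr$engrafted[off, j] == 0))
  }
  expect_true(all(tr$engrafted <= tr$clones$harvest_count))
})

test_that("clone-size dispersion is non-decreasing in sigma", {
  iqr_over_median <- function(sig) {
    m <- expansion_model(n_cells_per_well = 500, n_wells = 1,
                         transduction_efficiency = 1,
                         log_expansion_sd = sig, seed = 21)
    x <- simulate_clone_sizes(m)$harvest_count
    unname(diff(stats::quantile(x, c(0.25, 0.75)))) / stats::median(x)
  }
  vals <- vapply(c(0, 0.5, 1.0, 1.5), iqr_over_median, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("read generation respects the noise model and FASTQ contract", {
  lib <- tiny_library(n = 10, seed = 5)
  dir <- withr::local_tempdir()

  # single clone, no errors: every read is flank5 + barcode + flank3 + pad
  cm <- cm_fixture(matrix(50, 1, 1, dimnames = list(lib$barcodes[1], "R1")))
  m <- expansion_model(seq_error_rate = 0, seed = 4)
  fq <- generate_reads(cm, m, lib, dir)
  lines <- readLines(fq[["R1"]])
  expect_equal(length(lines), 4 * 50)
  seqs <- lines[seq(2, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  expect_true(all(grepl(paste0(lib$flank5, lib$barcodes[1], lib$flank3),
                        seqs, fixed = TRUE)))
  expect_true(all(nchar(seqs) == 100))
  expect_true(all(nchar(quals) == nchar(seqs)))

  # byte-identical under the same model and seed
  dir2 <- withr::local_tempdir()
  fq2 <- generate_reads(cm, m, lib, dir2)
  expect_identical(readLines(fq[["R1"]]), readLines(fq2[["R1"]]))

  # 900:100 cells at dispersion -> 0, error 0: read fractions -> 0.9 / 0.1
  m0 <- expansion_model(pcr_dispersion = 0, seq_error_rate = 0,
                        reads_per_recipient = 2e5, seed = 9)
  eng <- matrix(c(900L, 100L), 2, 1,
                dimnames = list(c("c1", "c2"), "R1"))
  tr <- structure(list(
    clones = data.frame(clone_id = c("c1", "c2"), well = 1L,
                        barcode = lib$barcodes[1:2],
                        harvest_count = c(900L, 100L)),
    engrafted = eng,
    design = clonetrackr:::new_split_design(data.frame(
      recipient = "R1", role = "plain", well_of_origin = NA_integer_,
      frac_well_1 = 1, stringsAsFactors = FALSE)),
    n_collisions = 0L, library = lib), class = "ground_truth")
  counts <- simulate_read_counts(tr, m0)
  frac <- counts$counts[, 1] / sum(counts$counts[, 1])
  expect_equal(unname(frac[lib$barcodes[1]]), 0.9, tolerance = 0.01)
  expect_equal(unname(frac[lib$barcodes[2]]), 0.1, tolerance = 0.1)
})

test_that("extracted frequencies converge to engrafted cell fractions", {
  # noise-free limit: error 0, dispersion 0, deep reads -> KL < 0.01
  lib <- tiny_library(n = 400, seed = 31)
  m <- expansion_model(n_cells_per_well = 100, n_wells = 1,
                       transduction_efficiency = 1,
                       pcr_dispersion = 0, seq_error_rate = 0,
                       reads_per_recipient = 1e6,
                       log_expansion_sd = 1.0, seed = 17)
  des <- clonetrackr:::new_split_design(data.frame(
    recipient = "R1", role = "plain", well_of_origin = NA_integer_,
    frac_well_1 = 1, stringsAsFactors = FALSE))
  cl <- simulate_clone_sizes(m)
  tr <- assign_barcodes(cl, lib, seed = 17)
  tr <- split_recipients(tr, des, engraftment_fraction = 1, seed = 17)
  counts <- simulate_read_counts(tr, m)
  cells <- rowsum(tr$engrafted[, 1], tr$clones$barcode)[, 1]
  cells <- cells[rownames(counts$counts)]
  p <- cells / sum(cells)
  q <- counts$counts[, 1] / sum(counts$counts[, 1])
  keep <- p > 0 & q > 0
  kl <- sum(p[keep] * log(p[keep] / q[keep]))
  expect_lt(kl, 0.01)
})
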