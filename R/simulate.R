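#' Simulate heterogeneous clonal expansion
#'
#' Draws per-clone cell counts at harvest for every founder HSC in every
#' well. Clone sizes are i.i.d. lognormal(`log_expansion_mean`,
#' `log_expansion_sd`), rounded to integers; `log_expansion_sd = 0` makes
#' all expected sizes equal. Each founder is independently transduced
#' (carries a barcode) with probability `transduction_efficiency`.
#'
#' @param model An [expansion_model()].
#' @param seed Optional seed overriding `model$seed`.
#' @return Data frame with columns `clone_id`, `well`, `transduced`,
#'   `harvest_count`.
#' @export
#' @examples
#' m <- expansion_model(n_cells_per_well = 10, n_wells = 2, seed = 7)
#' simulate_clone_sizes(m)
simulate_clone_sizes <- function(model, seed = NULL) {
  stopifnot(inherits(model, "expansion_model"))
  seed <- seed %||% model$seed
  n <- model$n_cells_per_well * model$n_wells
  with_seed(substream_seed(seed, 1L), {
    sizes <- stats::rlnorm(n, meanlog = model$log_expansion_mean,
                           sdlog = model$log_expansion_sd)
    transduced <- stats::runif(n) < model$transduction_efficiency
    data.frame(
      clone_id = sprintf("W%dC%04d",
                         rep(seq_len(model$n_wells),
                             each = model$n_cells_per_well),
                         rep(seq_len(model$n_cells_per_well), model$n_wells)),
      well = rep(seq_len(model$n_wells), each = model$n_cells_per_well),
      transduced = transduced,
      harvest_count = as.integer(round(sizes)),
      stringsAsFactors = FALSE
    )
  })
}

#' Assign library barcodes to transduced clones
#'
#' Each transduced clone draws one barcode uniformly *with replacement* from
#' the library, so two clones can collide on the same barcode (the realistic
#' failure mode that the downstream multi-parental exclusion rule targets).
#' Untransduced clones are dropped: they carry no amplifiable barcode and
#' are invisible to sequencing.
#'
#' @param clones Output of [simulate_clone_sizes()].
#' @param library A [barcode_library()].
#' @param seed Integer seed.
#' @return An object of class `ground_truth`: list with `clones` (data frame
#'   `clone_id`, `well`, `barcode`, `harvest_count`), `n_collisions`
#'   (number of barcodes carried by more than one clone) and `library`.
#' @export
assign_barcodes <- function(clones, library, seed = 1L) {
  stopifnot(inherits(library, "barcode_library"))
  if (length(library$barcodes) == 0L) stop("empty barcode library")
  keep <- clones[clones$transduced, , drop = FALSE]
  bc <- with_seed(substream_seed(seed, 2L), {
    if (nrow(keep) == 0L) character(0) else
      sample(library$barcodes, nrow(keep), replace = TRUE)
  })
  clones_df <- data.frame(
    clone_id = keep$clone_id,
    well = keep$well,
    barcode = bc,
    harvest_count = keep$harvest_count,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      clones = clones_df,
      n_collisions = sum(table(bc) > 1L),
      library = library
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d barcoded clones in %d well(s), %d barcode collision(s)\n",
              nrow(x$clones), length(unique(x$clones$well)), x$n_collisions))
  if (!is.null(x$engrafted)) {
    cat(sprintf("  engrafted counts for %d recipients\n", ncol(x$engrafted)))
  }
  invisible(x)
}

#' Split harvested clones across transplant recipients
#'
#' Allocates each clone's harvested cells to the recipients of a
#' [split_design][pre_culture_design] and thins them by the engraftment
#' probability. The allocation is a single multinomial draw per clone over
#' (recipient_1, ..., recipient_k, not-engrafted), with recipient
#' probabilities `split fraction x engraftment_fraction`; marginally each
#' recipient's count is Binomial(harvest, fraction x engraftment), and the
#' engrafted counts of a clone can never exceed its harvest count.
#'
#' @param truth A `ground_truth` from [assign_barcodes()].
#' @param design A split design ([pre_culture_design()] /
#'   [post_culture_design()]).
#' @param engraftment_fraction Per-cell engraftment probability.
#' @param seed Integer seed.
#' @return The `ground_truth` with an added `engrafted` integer matrix
#'   (clones x recipients) and the `design`.
#' @export
split_recipients <- function(truth, design, engraftment_fraction = 0.1,
                             seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(design, "split_design"),
            is_fraction(engraftment_fraction), engraftment_fraction > 0)
  fr <- design_fractions(design)
  if (ncol(fr) < max(truth$clones$well, 0)) {
    stop("design covers fewer wells than present in the ground truth")
  }
  clones <- truth$clones
  n_rec <- nrow(design)
  eng <- matrix(0L, nrow(clones), n_rec,
                dimnames = list(clones$clone_id, design$recipient))
  with_seed(substream_seed(seed, 3L), {
    for (w in unique(clones$well)) {
      idx <- which(clones$well == w)
      p <- fr[, w] * engraftment_fraction   # per-recipient cell probability
      remaining <- clones$harvest_count[idx]
      p_left <- 1
      # sequential binomial splitting == one multinomial draw per clone
      for (j in seq_len(n_rec)) {
        if (p[j] <= 0 || p_left <= 0) next
        take <- stats::rbinom(length(idx), remaining, min(1, p[j] / p_left))
        eng[idx, j] <- take
        remaining <- remaining - take
        p_left <- p_left - p[j]
      }
    }
  })
  truth$engrafted <- eng
  truth$design <- design
  truth
}

#' Simulate sequencing read counts per recipient
#'
#' Converts engrafted cell counts into barcode read counts. Within each
#' recipient, clones sharing a barcode are merged; each barcode's read count
#' is negative-binomial with mean `reads_per_recipient x (cells / total
#' cells)` and dispersion `pcr_dispersion` (Poisson when the dispersion is
#' 0), so PCR jackpots are overdispersed relative to pure multinomial
#' sampling but the multinomial case is recoverable as the dispersion -> 0
#' limit.
#'
#' @param truth A `ground_truth` after [split_recipients()].
#' @param model An [expansion_model()].
#' @param seed Optional seed overriding `model$seed`.
#' @return A [count_matrix()] (unassigned reads are 0 at the count level;
#'   sequencing errors only arise when FASTQ is generated).
#' @export
simulate_read_counts <- function(truth, model, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(model, "expansion_model"))
  if (is.null(truth$engrafted)) {
    stop("run split_recipients() before simulating reads")
  }
  seed <- seed %||% model$seed
  design <- truth$design
  # merge colliding clones per barcode
  cells <- rowsum(truth$engrafted, truth$clones$barcode)
  barcodes <- rownames(cells)
  counts <- matrix(0, length(barcodes), nrow(design),
                   dimnames = list(barcodes, design$recipient))
  for (j in seq_len(nrow(design))) {
    tot <- sum(cells[, j])
    if (tot == 0) next
    mu <- model$reads_per_recipient * cells[, j] / tot
    counts[, j] <- with_seed(substream_seed(seed, 100L + j), {
      if (model$pcr_dispersion > 0) {
        stats::rnbinom(length(mu), mu = mu, size = 1 / model$pcr_dispersion)
      } else {
        stats::rpois(length(mu), mu)
      }
    })
  }
  keep <- rowSums(counts) > 0
  count_matrix(counts[keep, , drop = FALSE],
               roles = design[, c("recipient", "role", "well_of_origin")])
}

#' Simulate a complete barcoding experiment
#'
#' Convenience wrapper chaining [simulate_clone_sizes()],
#' [assign_barcodes()], [split_recipients()] and [simulate_read_counts()],
#' and optionally writing per-recipient FASTQ files via [generate_reads()].
#'
#' @inheritParams simulate_read_counts
#' @param design A split design; defaults to [pre_culture_design()].
#' @param library A [barcode_library()]; defaults to a synthetic 5737 x 8 bp
#'   library drawn from the model seed.
#' @param fastq_dir If non-`NULL`, write one FASTQ per recipient here.
#' @return List with `truth` (`ground_truth`), `counts` ([count_matrix()])
#'   and `fastq` (named file paths or `NULL`).
#' @export
#' @examples
#' m <- expansion_model(n_cells_per_well = 50, n_wells = 2,
#'                      reads_per_recipient = 1000, seed = 42)
#' sim <- simulate_experiment(m, design = pre_culture_design(n_wells = 2))
#' sim$counts
simulate_experiment <- function(model, design = pre_culture_design(),
                                library = NULL, fastq_dir = NULL) {
  stopifnot(inherits(model, "expansion_model"))
  if (is.null(library)) {
    library <- random_barcode_library(5737L, 8L, seed = model$seed)
  }
  clones <- simulate_clone_sizes(model)
  truth <- assign_barcodes(clones, library, seed = model$seed)
  truth <- split_recipients(truth, design,
                            engraftment_fraction = model$engraftment_fraction,
                            seed = model$seed)
  counts <- simulate_read_counts(truth, model)
  fq <- NULL
  if (!is.null(fastq_dir)) {
    fq <- generate_reads(counts, model, library, fastq_dir)
  }
  list(truth = truth, counts = counts, fastq = fq)
}

#' Write or read simulator ground truth as TSV
#'
#' Long format: one row per (clone, recipient) with the engrafted count,
#' plus the clone's well, barcode and harvest count.
#'
#' @param truth A `ground_truth` after [split_recipients()].
#' @param path File path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns a data frame.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"), !is.null(truth$engrafted))
  long <- data.frame(
    clone_id = rep(truth$clones$clone_id, ncol(truth$engrafted)),
    well = rep(truth$clones$well, ncol(truth$engrafted)),
    barcode = rep(truth$clones$barcode, ncol(truth$engrafted)),
    harvest_count = rep(truth$clones$harvest_count, ncol(truth$engrafted)),
    recipient = rep(colnames(truth$engrafted), each = nrow(truth$clones)),
    engrafted_count = as.vector(truth$engrafted),
    stringsAsFactors = FALSE
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
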