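#' Generate amplicon FASTQ files from barcode read counts
#'
#' Materialises each recipient's barcode read counts as single-end 100 nt
#' amplicon reads: `flank5 + barcode + flank3`, padded with a constant
#' filler sequence to the full read length, with independent per-base
#' substitution errors at `model$seq_error_rate`. Qualities are Phred+33
#' with a constant quality matching the substitution rate. One FASTQ file is
#' written per recipient; output is byte-identical for identical model and
#' seed.
#'
#' @param counts A [count_matrix()] of read counts (e.g. from
#'   [simulate_read_counts()]).
#' @param model An [expansion_model()] (supplies `seq_error_rate` and seed).
#' @param library A [barcode_library()] (supplies the flanks).
#' @param dir Output directory (created if needed).
#' @param read_length Total read length in nt.
#' @return Named character vector of FASTQ paths, one per recipient.
#' @export
generate_reads <- function(counts, model, library, dir, read_length = 100L) {
  stopifnot(inherits(counts, "count_matrix"),
            inherits(model, "expansion_model"),
            inherits(library, "barcode_library"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  amplicon_len <- nchar(library$flank5) + library$length + nchar(library$flank3)
  if (amplicon_len > read_length) {
    stop("flank5 + barcode + flank3 exceeds the read length")
  }
  filler <- paste(rep("TCGA", ceiling(read_length / 4)), collapse = "")
  pad <- substr(filler, 1L, read_length - amplicon_len)
  qual_char <- rawToChar(as.raw(
    33L + min(40L, as.integer(round(-10 * log10(max(model$seq_error_rate,
                                                    1e-4)))))))
  qual_string <- strrep(qual_char, read_length)

  paths <- character(ncol(counts$counts))
  names(paths) <- colnames(counts$counts)
  for (j in seq_len(ncol(counts$counts))) {
    rec <- colnames(counts$counts)[j]
    n_per_bc <- stats::setNames(counts$counts[, j], rownames(counts$counts))
    n_per_bc <- n_per_bc[n_per_bc > 0]
    seqs <- rep(paste0(library$flank5, names(n_per_bc), library$flank3, pad),
                times = n_per_bc)
    seqs <- with_seed(substream_seed(model$seed, 500L + j),
                      mutate_bases(seqs, model$seq_error_rate))
    path <- file.path(dir, paste0(rec, ".fastq"))
    n <- length(seqs)
    if (n > 0) {
      ids <- sprintf("@%s_read%d", rec, seq_len(n))
      writeLines(as.vector(rbind(ids, seqs, "+",
                                 rep(qual_string, n))), path)
    } else {
      file.create(path)
    }
    paths[rec] <- path
  }
  paths
}

# Apply i.i.d. per-base substitutions at rate `rate` to a character vector of
# equal-length sequences. Substitutions draw uniformly from the three
# alternative bases; no indels (fixed-position amplicon reads).
mutate_bases <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  L <- nchar(seqs[1])
  n_err <- stats::rbinom(length(seqs), L, rate)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(L, n_err[i])
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      s[p] <- sample(setdiff(bases, s[p]), 1L)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}
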