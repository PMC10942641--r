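#' Extract and count barcodes from an amplicon FASTQ file
#'
#' For each read, the constant 5' anchor (`library$flank5`) is located by
#' exact search (first occurrence); the next `library$length` bases are the
#' candidate barcode, matched against the library at Hamming distance at
#' most `max_mismatch`. A read is assigned to a barcode only when the
#' nearest library barcode is unique at that distance; reads without the
#' anchor, with a truncated candidate, or with an ambiguous (tied) match are
#' counted as unassigned. Amplicon orientation is fixed by the PCR primers,
#' so no reverse-complement search is attempted.
#'
#' The default `max_mismatch = 0` reflects that both library designs are
#' defined sets read out without an error-correction step; `max_mismatch =
#' 1` rescues reads with a single sequencing substitution inside the
#' barcode.
#'
#' @param fastq Path to a single-end FASTQ file (one recipient).
#' @param library A [barcode_library()].
#' @param max_mismatch 0 (exact) or 1 (single-substitution rescue).
#' @param recipient Recipient id for the resulting column (defaults to the
#'   FASTQ basename).
#' @param role Recipient role: `"parental"`, `"daughter"` or `"plain"`.
#' @param well_of_origin Well of origin (parental recipients only).
#' @return A one-recipient [count_matrix()] whose rows are the library
#'   barcodes with at least one assigned read; assigned + unassigned always
#'   equals the number of reads in the file.
#' @export
extract_barcodes <- function(fastq, library, max_mismatch = 0L,
                             recipient = NULL, role = "plain",
                             well_of_origin = NA_integer_) {
  stopifnot(inherits(library, "barcode_library"))
  if (!max_mismatch %in% c(0L, 1L)) stop("max_mismatch must be 0 or 1")
  recipient <- recipient %||% sub("\\.(fastq|fq)(\\.gz)?$", "",
                                  basename(fastq))
  seqs <- read_fastq_sequences(fastq)
  if (length(seqs) == 0L) {
    warning("empty FASTQ file: ", fastq)
    empty <- matrix(numeric(0), 0, 1, dimnames = list(character(0), recipient))
    return(count_matrix(empty,
                        roles = data.frame(recipient = recipient, role = role,
                                           well_of_origin = well_of_origin)))
  }
  L <- library$length
  pos <- regexpr(library$flank5, seqs, fixed = TRUE)
  start <- ifelse(pos > 0, pos + nchar(library$flank5), NA_integer_)
  cand <- ifelse(is.na(start), NA_character_,
                 substr(seqs, start, start + L - 1L))
  cand[!is.na(cand) & nchar(cand) < L] <- NA_character_

  assigned <- match(cand, library$barcodes)   # exact matches
  if (max_mismatch == 1L) {
    miss <- which(!is.na(cand) & is.na(assigned))
    if (length(miss) > 0) {
      libmat <- library_char_matrix(library)
      uniq <- unique(cand[miss])
      hit <- vapply(uniq, nearest_unique_barcode, integer(1),
                    library = library, max_mismatch = 1L, libmat = libmat)
      assigned[miss] <- hit[match(cand[miss], uniq)]
      assigned[which(assigned == 0L)] <- NA_integer_
    }
  }
  tab <- table(factor(assigned[!is.na(assigned)],
                      levels = seq_along(library$barcodes)))
  keep <- which(tab > 0)
  cm <- matrix(as.numeric(tab[keep]), ncol = 1,
               dimnames = list(library$barcodes[keep], recipient))
  count_matrix(
    cm,
    roles = data.frame(recipient = recipient, role = role,
                       well_of_origin = well_of_origin),
    unassigned = stats::setNames(sum(is.na(assigned)), recipient)
  )
}

# Index of the unique library barcode within Hamming distance <= max_mismatch
# of `cand`, or 0L when no match or the nearest match is tied.
nearest_unique_barcode <- function(cand, library, max_mismatch,
                                   libmat = library_char_matrix(library)) {
  cc <- strsplit(cand, "", fixed = TRUE)[[1]]
  if (length(cc) != library$length || any(!cc %in% c("A", "C", "G", "T"))) {
    return(0L)
  }
  d <- colSums(libmat != cc)
  dmin <- min(d)
  if (dmin > max_mismatch || sum(d == dmin) > 1L) 0L else which.min(d)
}

library_char_matrix <- function(library) {
  matrix(unlist(strsplit(library$barcodes, "", fixed = TRUE)),
         nrow = library$length)
}

# Parse a FASTQ file into a character vector of read sequences. Records are
# structurally validated first so a malformed record is reported with its
# index; the sequences themselves are parsed by Biostrings.
read_fastq_sequences <- function(path) {
  if (!file.exists(path)) stop("no such FASTQ file: ", path)
  if (file.size(path) == 0L) return(character(0))
  lines <- readLines(path, warn = FALSE)
  n_rec <- ceiling(length(lines) / 4)
  for (i in seq_len(n_rec)) {
    rec <- lines[(4 * i - 3):min(4 * i, length(lines))]
    ok <- length(rec) == 4L && startsWith(rec[1], "@") &&
      startsWith(rec[3], "+") && nchar(rec[2]) == nchar(rec[4])
    if (is.na(ok) || !ok) {
      stop("malformed FASTQ record ", i, " in ", path)
    }
  }
  res <- tryCatch(
    as.character(Biostrings::readDNAStringSet(path, format = "fastq")),
    error = function(e) {
      stop("failed to parse FASTQ ", path, ": ", conditionMessage(e))
    }
  )
  unname(res)
}
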