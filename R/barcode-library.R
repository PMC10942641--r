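#' Barcode library
#'
#' A lentiviral barcode library: the set of semi-random oligo barcodes that
#' can be integrated into a transduced cell, plus the constant flanking
#' sequences that anchor the barcode inside the amplicon read. Two library
#' designs are relevant for HSC expansion experiments: a ~5,700-member 8 bp
#' library used to label cells before culture, and a ~10,000-member 21 bp
#' library (a repurposed gRNA library) used after culture. Any positive
#' barcode length is accepted.
#'
#' @param barcodes Character vector of barcode sequences. Must be unique,
#'   of identical length, and restricted to the A/C/G/T alphabet.
#' @param flank5,flank3 Constant anchor sequences immediately 5' and 3' of
#'   the barcode in the amplicon.
#' @return An object of class `barcode_library` with elements `barcodes`,
#'   `length`, `flank5`, `flank3`.
#' @seealso [random_barcode_library()] to draw a synthetic library.
#' @export
#' @examples
#' lib <- barcode_library(c("ACGTACGT", "TTTTAAAA"))
#' lib$length
barcode_library <- function(barcodes,
                            flank5 = "CTAGCTTGGCTGCAGG",
                            flank3 = "TGGAATTCTCGAGGCT") {
  barcodes <- toupper(as.character(barcodes))
  if (length(barcodes) == 0L) {
    stop("barcode library must contain at least one barcode")
  }
  lens <- unique(nchar(barcodes))
  if (length(lens) != 1L || lens < 1L) {
    stop("all barcodes must have the same positive length")
  }
  if (anyDuplicated(barcodes)) {
    stop("barcodes must be unique")
  }
  if (any(grepl("[^ACGT]", barcodes))) {
    stop("barcodes must use only A, C, G, T")
  }
  for (fl in c(flank5, flank3)) {
    if (!is.character(fl) || length(fl) != 1L || nchar(fl) < 1L ||
        grepl("[^ACGT]", toupper(fl))) {
      stop("flanks must be non-empty A/C/G/T strings")
    }
  }
  structure(
    list(
      barcodes = barcodes,
      length = as.integer(lens),
      flank5 = toupper(flank5),
      flank3 = toupper(flank3)
    ),
    class = "barcode_library"
  )
}

#' Draw a synthetic barcode library
#'
#' Samples `n` distinct random barcodes of the requested length. Useful both
#' for simulation defaults that emulate the published library sizes (5737
#' barcodes of 8 bp pre-culture; 10,090 barcodes of 21 bp post-culture) and
#' for small test libraries.
#'
#' @param n Number of distinct barcodes.
#' @param length Barcode length in bp.
#' @param seed Integer seed; the library is a deterministic function of it.
#' @inheritParams barcode_library
#' @return A [barcode_library()].
#' @export
random_barcode_library <- function(n, length = 8L, seed = 1L,
                                   flank5 = "CTAGCTTGGCTGCAGG",
                                   flank3 = "TGGAATTCTCGAGGCT") {
  stopifnot(is_count(n), n >= 1, is_count(length), length >= 1)
  if (4^length < n) {
    stop("alphabet too small: cannot draw ", n, " distinct barcodes of length ",
         length)
  }
  bases <- c("A", "C", "G", "T")
  bc <- with_seed(seed, {
    out <- character(0)
    while (length(out) < n) {
      need <- n - length(out)
      draw <- vapply(
        seq_len(need * 2L),
        function(i) paste(sample(bases, length, replace = TRUE), collapse = ""),
        character(1)
      )
      out <- unique(c(out, draw))
    }
    out[seq_len(n)]
  })
  barcode_library(bc, flank5 = flank5, flank3 = flank3)
}

#' @export
print.barcode_library <- function(x, ...) {
  cat(sprintf("barcode_library: %d barcodes of %d bp (flank5 %s / flank3 %s)\n",
              length(x$barcodes), x$length, x$flank5, x$flank3))
  invisible(x)
}

#' Read or write a barcode library as TSV
#'
#' The on-disk format is a two-line header (`#flank5`, `#flank3`) followed by
#' one barcode per line.
#'
#' @param library A [barcode_library()].
#' @param path File path.
#' @return `write_barcode_library()` returns `path` invisibly;
#'   `read_barcode_library()` returns a [barcode_library()].
#' @export
write_barcode_library <- function(library, path) {
  stopifnot(inherits(library, "barcode_library"))
  writeLines(
    c(paste0("#flank5\t", library$flank5),
      paste0("#flank3\t", library$flank3),
      library$barcodes),
    path
  )
  invisible(path)
}

#' @rdname write_barcode_library
#' @export
read_barcode_library <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  get_field <- function(key) {
    row <- lines[hdr][startsWith(lines[hdr], paste0("#", key))]
    if (length(row) != 1L) stop("library file missing #", key, " header")
    strsplit(row, "\t", fixed = TRUE)[[1]][2]
  }
  barcode_library(lines[!hdr & nzchar(lines)],
                  flank5 = get_field("flank5"),
                  flank3 = get_field("flank3"))
}
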