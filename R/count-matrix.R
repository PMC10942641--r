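#' Barcode count matrix
#'
#' Raw barcode read counts per transplant recipient, together with each
#' recipient's role in the split design (`parental`, `daughter` or `plain`),
#' the well of origin for parental recipients, and per-recipient totals of
#' assigned and unassigned reads. Rows are barcodes, columns recipients.
#'
#' @param counts Non-negative integer matrix, barcodes x recipients, with
#'   unique rownames (barcode sequences) and colnames (recipient ids).
#' @param roles Data frame with columns `recipient`, `role` and optionally
#'   `well_of_origin`; one row per column of `counts`. Defaults to role
#'   `"plain"` for every recipient.
#' @param unassigned Named numeric vector of reads that could not be
#'   assigned to any library barcode, one entry per recipient (default 0).
#' @return An object of class `count_matrix` with elements `counts`,
#'   `roles`, `unassigned`, and `total_reads` (assigned + unassigned).
#' @export
count_matrix <- function(counts, roles = NULL, unassigned = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) {
    dimnames(counts) <- list(character(0), colnames(counts))
  }
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      is.null(colnames(counts))) {
    stop("counts must have barcode rownames and recipient colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("barcode rows must be unique")
  if (anyDuplicated(colnames(counts))) stop("recipient columns must be unique")
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and >= 0")
  }
  rec <- colnames(counts)
  if (is.null(roles)) {
    roles <- data.frame(recipient = rec, role = "plain",
                        well_of_origin = NA_integer_,
                        stringsAsFactors = FALSE)
  }
  if (!all(c("recipient", "role") %in% names(roles))) {
    stop("roles needs columns `recipient` and `role`")
  }
  if (!"well_of_origin" %in% names(roles)) roles$well_of_origin <- NA_integer_
  roles <- roles[match(rec, roles$recipient),
                 c("recipient", "role", "well_of_origin")]
  if (anyNA(roles$recipient)) stop("roles must cover every recipient column")
  if (!all(roles$role %in% c("parental", "daughter", "plain"))) {
    stop("role must be one of parental, daughter, plain")
  }
  rownames(roles) <- NULL
  if (is.null(unassigned)) {
    unassigned <- stats::setNames(numeric(length(rec)), rec)
  }
  unassigned <- unassigned[rec]
  names(unassigned) <- rec
  unassigned[is.na(unassigned)] <- 0
  structure(
    list(
      counts = counts,
      roles = roles,
      unassigned = unassigned,
      total_reads = colSums(counts) + unassigned
    ),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d barcodes x %d recipients (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%d %s", table(x$roles$role),
                            names(table(x$roles$role))), collapse = ", ")))
  cat(sprintf("  assigned reads: %s; unassigned: %s\n",
              paste(colSums(x$counts), collapse = "/"),
              paste(x$unassigned, collapse = "/")))
  invisible(x)
}

#' Merge per-recipient count matrices
#'
#' Column-binds count matrices from individual recipients (or groups of
#' recipients) into one, taking the union of their barcode rows; barcodes
#' absent from a recipient get count 0. Per-recipient totals are preserved
#' exactly.
#'
#' @param matrices List of [count_matrix()] objects with pairwise disjoint
#'   recipient ids.
#' @return A [count_matrix()].
#' @export
merge_recipients <- function(matrices) {
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, inherits, logical(1), "count_matrix")))
  recs <- unlist(lapply(matrices, function(m) colnames(m$counts)))
  if (anyDuplicated(recs)) {
    stop("duplicate recipient id across matrices: ",
         paste(unique(recs[duplicated(recs)]), collapse = ", "))
  }
  all_bc <- unique(unlist(lapply(matrices, function(m) rownames(m$counts))))
  out <- matrix(0, length(all_bc), length(recs),
                dimnames = list(all_bc, recs))
  for (m in matrices) {
    out[rownames(m$counts), colnames(m$counts)] <- m$counts
  }
  roles <- do.call(rbind, lapply(matrices, function(m) m$roles))
  unassigned <- do.call(c, lapply(matrices, function(m) m$unassigned))
  count_matrix(out, roles = roles, unassigned = unassigned)
}

#' Read or write a count matrix as TSV
#'
#' The TSV has barcodes as rows and recipients as columns. Metadata travel
#' in comment header lines: `#role` (one role per recipient), `#well` (well
#' of origin, `NA` when not applicable) and `#unassigned` (reads not
#' assigned to any barcode).
#'
#' @param x A [count_matrix()].
#' @param path File path.
#' @return `write_count_matrix()` returns `path` invisibly;
#'   `read_count_matrix()` returns a [count_matrix()].
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  rec <- colnames(x$counts)
  hdr <- c(
    paste(c("#role", x$roles$role), collapse = "\t"),
    paste(c("#well", x$roles$well_of_origin), collapse = "\t"),
    paste(c("#unassigned", x$unassigned), collapse = "\t"),
    paste(c("barcode", rec), collapse = "\t")
  )
  body <- paste(rownames(x$counts),
                apply(x$counts, 1, paste, collapse = "\t"),
                sep = "\t")
  if (nrow(x$counts) == 0L) body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_meta <- function(key) {
    row <- meta[startsWith(meta, paste0("#", key))]
    if (length(row) != 1L) stop("count matrix file missing #", key, " header")
    strsplit(row, "\t", fixed = TRUE)[[1]][-1]
  }
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  rec <- header[-1]
  if (length(body) > 1L) {
    parts <- strsplit(body[-1], "\t", fixed = TRUE)
    bc <- vapply(parts, `[[`, character(1), 1)
    cm <- t(vapply(parts, function(p) as.numeric(p[-1]),
                   numeric(length(rec))))
    if (length(rec) == 1L) cm <- matrix(cm, ncol = 1L)
    dimnames(cm) <- list(bc, rec)
  } else {
    cm <- matrix(numeric(0), 0, length(rec),
                 dimnames = list(character(0), rec))
  }
  roles <- data.frame(recipient = rec, role = get_meta("role"),
                      well_of_origin = suppressWarnings(as.integer(get_meta("well"))),
                      stringsAsFactors = FALSE)
  unassigned <- stats::setNames(as.numeric(get_meta("unassigned")), rec)
  count_matrix(cm, roles = roles, unassigned = unassigned)
}
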