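#' Background-filter barcode counts
#'
#' Zeroes, per recipient, every barcode whose read frequency among that
#' recipient's assigned reads is strictly below `threshold` (default 0.1%,
#' the conventional — and admittedly arbitrary — background cut-off for
#' amplicon barcode data). The rule is applied independently per recipient:
#' a barcode can survive in one recipient while being background in another.
#' Barcodes exactly at the threshold are kept (strict `<`).
#'
#' @param counts A [count_matrix()].
#' @param threshold Frequency cut-off in `[0, 1)`.
#' @return A [count_matrix()] with sub-threshold entries zeroed; the zeroed
#'   entries are recorded in `attr(, "background")` as a logical matrix.
#'   Unassigned totals are unchanged (filtering reclassifies counts as
#'   background, it does not un-sequence them).
#' @export
#' @examples
#' cm <- count_matrix(matrix(c(5000, 4, 996), 3, 1,
#'                    dimnames = list(c("A", "B", "C"), "R1")))
#' filter_background(cm, 0.001)$counts   # B zeroed: 4/6000 < 0.1%
filter_background <- function(counts, threshold = 0.001) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!is_fraction(threshold) || threshold >= 1) {
    stop("threshold must lie in [0, 1)")
  }
  cm <- counts$counts
  assigned <- colSums(cm)
  freq <- sweep(cm, 2, pmax(assigned, 1), "/")
  background <- freq < threshold & cm > 0
  cm[background] <- 0
  out <- count_matrix(cm, roles = counts$roles, unassigned = counts$unassigned)
  attr(out, "background") <- background
  out
}

#' Exclude barcodes shared across parental recipients
#'
#' A barcode detected (nonzero after background filtering) in two or more
#' *parental* recipients cannot be traced to a single founder clone: either
#' two HSCs in different wells were independently transduced with the same
#' barcode, or the barcode is over-represented in the library. Such barcodes
#' are removed from every recipient, parental and daughter alike. Sharing
#' between a parental and its daughters is the biological signal and never
#' triggers exclusion. With no parental recipients (post-culture design) the
#' matrix is returned unchanged with a warning.
#'
#' @param counts A [count_matrix()] (typically after [filter_background()]).
#' @return A [count_matrix()] without the excluded barcode rows; the
#'   exclusion log (barcode, parental ids) is in `attr(, "excluded")`.
#' @export
exclude_multi_parental <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  parental <- counts$roles$recipient[counts$roles$role == "parental"]
  if (length(parental) == 0L) {
    warning("no parental recipients: multi-parental exclusion is a no-op")
    attr(counts, "excluded") <- data.frame(barcode = character(0),
                                           parental_ids = character(0),
                                           stringsAsFactors = FALSE)
    return(counts)
  }
  pm <- counts$counts[, parental, drop = FALSE] > 0
  multi <- rowSums(pm) >= 2L
  excluded <- data.frame(
    barcode = (rownames(counts$counts) %||% character(0))[multi],
    parental_ids = if (any(multi)) {
      apply(pm[multi, , drop = FALSE], 1,
            function(r) paste(parental[r], collapse = ","))
    } else {
      character(0)
    },
    stringsAsFactors = FALSE
  )
  rownames(excluded) <- NULL
  out <- count_matrix(counts$counts[!multi, , drop = FALSE],
                      roles = counts$roles, unassigned = counts$unassigned)
  attr(out, "excluded") <- excluded
  out
}

#' Normalize counts to a fixed per-recipient total
#'
#' Rescales each recipient's surviving counts so they sum to `scale`
#' (default 1e6: reads per million). Values are real, not re-rounded. A
#' recipient left with no surviving reads gets a row of zeros and a warning.
#'
#' @param counts A [count_matrix()].
#' @param scale Target per-recipient total (> 0).
#' @param threshold,exclusions,input_assigned Provenance carried into the
#'   result (set by [run_pipeline()]): the background threshold, the
#'   exclusion log, and the per-recipient assigned totals *before*
#'   filtering (the denominator of the background rule).
#' @return A `clone_table`: list with `normalized` (barcodes x recipients
#'   real matrix), `kept_barcodes`, `exclusions` (data frame `barcode`,
#'   `reason`, `recipients`), `roles`, `assigned_reads` (pre-normalization
#'   totals), `threshold` and `scale`.
#' @export
#' @examples
#' cm <- count_matrix(matrix(c(50, 150), 2, 1,
#'                    dimnames = list(c("A", "C"), "R1")))
#' normalize_counts(cm)$normalized        # 250000 / 750000
normalize_counts <- function(counts, scale = 1e6, threshold = NA_real_,
                             exclusions = NULL, input_assigned = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("scale must be a positive number")
  }
  cm <- counts$counts
  keep <- rowSums(cm) > 0
  cm <- cm[keep, , drop = FALSE]
  tot <- colSums(cm)
  if (nrow(cm) > 0 && any(tot == 0)) {
    warning("recipient(s) with zero surviving reads: ",
            paste(colnames(cm)[tot == 0], collapse = ", "))
  }
  norm <- sweep(cm, 2, ifelse(tot > 0, tot / scale, 1), "/")
  if (is.null(exclusions)) {
    exclusions <- data.frame(barcode = character(0), reason = character(0),
                             recipients = character(0),
                             stringsAsFactors = FALSE)
  }
  structure(
    list(
      normalized = norm,
      kept_barcodes = rownames(norm) %||% character(0),
      exclusions = exclusions,
      roles = counts$roles,
      assigned_reads = tot,
      input_assigned_reads = input_assigned %||% tot,
      threshold = threshold,
      scale = scale
    ),
    class = "clone_table"
  )
}

#' @export
print.clone_table <- function(x, ...) {
  cat(sprintf("clone_table: %d kept barcodes x %d recipients (scale %g, threshold %s)\n",
              nrow(x$normalized), ncol(x$normalized), x$scale,
              format(x$threshold)))
  if (nrow(x$exclusions) > 0) {
    cat(sprintf("  %d excluded barcode(s): %s\n", nrow(x$exclusions),
                paste(utils::head(unique(x$exclusions$reason), 3),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Run the full barcode filtering pipeline
#'
#' Composition, in this order, of [filter_background()] (per-recipient 0.1%
#' background rule, strict `<` on raw read frequencies),
#' [exclude_multi_parental()] (barcodes detected in more than one parental
#' recipient removed everywhere) and [normalize_counts()] (reads per 1e6 per
#' recipient). Exclusion provenance is kept in the result: barcodes zeroed
#' everywhere by the background filter get reason `below_threshold`, cross-
#' parental barcodes get reason `multi_parental` with the parental ids.
#'
#' @param counts A [count_matrix()].
#' @param threshold Background frequency cut-off (default 0.001).
#' @param scale Normalization total (default 1e6).
#' @return A `clone_table` (see [normalize_counts()]).
#' @export
run_pipeline <- function(counts, threshold = 0.001, scale = 1e6) {
  filtered <- filter_background(counts, threshold)
  gone <- (rownames(filtered$counts) %||%
             character(0))[rowSums(filtered$counts) == 0 &
                             rowSums(counts$counts) > 0]
  background_excl <- if (length(gone) > 0) {
    bg <- attr(filtered, "background")
    data.frame(
      barcode = gone,
      reason = "below_threshold",
      recipients = apply(bg[gone, , drop = FALSE], 1, function(r)
        paste(colnames(bg)[r], collapse = ",")),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(barcode = character(0), reason = character(0),
               recipients = character(0), stringsAsFactors = FALSE)
  }
  kept <- suppressWarnings(exclude_multi_parental(filtered))
  mp <- attr(kept, "excluded")
  mp_excl <- data.frame(barcode = mp$barcode,
                        reason = rep("multi_parental", nrow(mp)),
                        recipients = mp$parental_ids,
                        stringsAsFactors = FALSE)
  exclusions <- rbind(background_excl, mp_excl)
  rownames(exclusions) <- NULL
  normalize_counts(kept, scale = scale, threshold = threshold,
                   exclusions = exclusions,
                   input_assigned = colSums(counts$counts))
}

#' Read or write a clone table as TSV
#'
#' `write_clone_table()` writes the normalized matrix in the same dialect as
#' [write_count_matrix()] (plus `#threshold`, `#scale` and `#assigned`
#' headers) and, when `exclusions_path` is given, an exclusions TSV
#' (barcode, reason, recipients).
#'
#' @param x A `clone_table`.
#' @param path Output TSV path for the normalized matrix.
#' @param exclusions_path Optional output TSV path for the exclusion log.
#' @return `write_clone_table()` returns `path` invisibly;
#'   `read_clone_table()` returns a `clone_table`.
#' @export
write_clone_table <- function(x, path, exclusions_path = NULL) {
  stopifnot(inherits(x, "clone_table"))
  rec <- colnames(x$normalized)
  hdr <- c(
    paste(c("#role", x$roles$role), collapse = "\t"),
    paste(c("#well", x$roles$well_of_origin), collapse = "\t"),
    paste(c("#assigned", x$assigned_reads), collapse = "\t"),
    paste(c("#input_assigned", x$input_assigned_reads), collapse = "\t"),
    paste0("#threshold\t", format(x$threshold, digits = 17)),
    paste0("#scale\t", format(x$scale, digits = 17)),
    paste(c("barcode", rec), collapse = "\t")
  )
  body <- paste(rownames(x$normalized),
                apply(format(x$normalized, digits = 17, trim = TRUE,
                             scientific = FALSE), 1, paste, collapse = "\t"),
                sep = "\t")
  if (nrow(x$normalized) == 0L) body <- character(0)
  writeLines(c(hdr, body), path)
  if (!is.null(exclusions_path)) {
    utils::write.table(x$exclusions, exclusions_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_clone_table
#' @export
read_clone_table <- function(path, exclusions_path = NULL) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_meta <- function(key) {
    row <- meta[startsWith(meta, paste0("#", key))]
    if (length(row) != 1L) stop("clone table file missing #", key, " header")
    strsplit(row, "\t", fixed = TRUE)[[1]][-1]
  }
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  rec <- header[-1]
  if (length(body) > 1L) {
    parts <- strsplit(body[-1], "\t", fixed = TRUE)
    bc <- vapply(parts, `[[`, character(1), 1)
    nm <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(length(rec))))
    if (length(rec) == 1L) nm <- matrix(nm, ncol = 1L)
    dimnames(nm) <- list(bc, rec)
  } else {
    nm <- matrix(numeric(0), 0, length(rec),
                 dimnames = list(character(0), rec))
  }
  exclusions <- if (!is.null(exclusions_path)) {
    utils::read.delim(exclusions_path, stringsAsFactors = FALSE,
                      colClasses = "character")
  } else {
    data.frame(barcode = character(0), reason = character(0),
               recipients = character(0), stringsAsFactors = FALSE)
  }
  structure(
    list(
      normalized = nm,
      kept_barcodes = rownames(nm),
      exclusions = exclusions,
      roles = data.frame(recipient = rec, role = get_meta("role"),
                         well_of_origin = suppressWarnings(as.integer(get_meta("well"))),
                         stringsAsFactors = FALSE),
      assigned_reads = stats::setNames(as.numeric(get_meta("assigned")), rec),
      input_assigned_reads = stats::setNames(
        as.numeric(get_meta("input_assigned")), rec),
      threshold = as.numeric(get_meta("threshold")[1]),
      scale = as.numeric(get_meta("scale")[1])
    ),
    class = "clone_table"
  )
}
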