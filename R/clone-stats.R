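#' Summarise clone sizes in a clone table
#'
#' Clone size is a barcode's normalized read frequency within a recipient,
#' expressed as percent of that recipient's normalized total. Nonzero
#' (barcode, recipient) frequencies are pooled across all recipients of the
#' requested role, matching how pre- vs post-culture clone-size
#' distributions are compared.
#'
#' @param table A `clone_table` from [run_pipeline()].
#' @param role Restrict to recipients of this role (`"parental"`,
#'   `"daughter"`, `"plain"`); `NULL` pools every recipient.
#' @return List with `n_barcodes` (barcodes detected in >= 1 selected
#'   recipient), `n_observations`, `min_pct`, `max_pct`, `median_pct`,
#'   `iqr_pct`, `q25_pct`, `q75_pct`, and the pooled vector
#'   `frequencies_pct`.
#' @export
clone_size_summary <- function(table, role = NULL) {
  stopifnot(inherits(table, "clone_table"))
  nm <- select_role(table, role)
  x <- 100 * nm[nm > 0] / table$scale
  if (length(x) == 0L) {
    stop("no nonzero clone sizes for role ",
         if (is.null(role)) "<all>" else role)
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(
    n_barcodes = sum(rowSums(nm > 0) > 0),
    n_observations = length(x),
    min_pct = min(x),
    max_pct = max(x),
    median_pct = q[2],
    iqr_pct = q[3] - q[1],
    q25_pct = q[1],
    q75_pct = q[3],
    frequencies_pct = unname(x)
  )
}

select_role <- function(table, role) {
  rec <- if (is.null(role)) {
    table$roles$recipient
  } else {
    table$roles$recipient[table$roles$role == role]
  }
  if (length(rec) == 0L) stop("no recipients with role ", role)
  table$normalized[, rec, drop = FALSE]
}

#' Parental-to-daughter barcode sharing
#'
#' For every barcode detected in a parental recipient, reports which
#' parental carries it, its clone size there (reads per `scale`), in how
#' many daughter recipients it is detected (nonzero normalized count, i.e.
#' it survived the background filter there), and its summed contribution
#' across daughters. Re-detection of a parental barcode in daughters
#' demonstrates shared clonal origin; robustly expanding clones are expected
#' to seed more daughters.
#'
#' @param table A `clone_table` with at least one parental and one daughter
#'   recipient.
#' @return Data frame with columns `barcode`, `parental_id`,
#'   `parental_clone_size`, `n_daughters_detected`,
#'   `daughter_total_contribution`; class `sharing_summary`. Barcodes absent
#'   from all parentals are omitted.
#' @export
sharing_analysis <- function(table) {
  stopifnot(inherits(table, "clone_table"))
  parental <- table$roles$recipient[table$roles$role == "parental"]
  daughters <- table$roles$recipient[table$roles$role == "daughter"]
  if (length(parental) == 0L || length(daughters) == 0L) {
    stop("sharing analysis needs both parental and daughter recipients")
  }
  pm <- table$normalized[, parental, drop = FALSE]
  dm <- table$normalized[, daughters, drop = FALSE]
  in_parental <- rowSums(pm > 0) > 0
  pm <- pm[in_parental, , drop = FALSE]
  dm <- dm[in_parental, , drop = FALSE]
  # multi-parental barcodes are excluded upstream; if several parentals are
  # nonzero anyway, attribute the barcode to the largest contribution
  pid <- parental[max.col(pm, ties.method = "first")]
  out <- data.frame(
    barcode = rownames(pm),
    parental_id = pid,
    parental_clone_size = pm[cbind(seq_len(nrow(pm)),
                                   match(pid, parental))],
    n_daughters_detected = as.integer(rowSums(dm > 0)),
    daughter_total_contribution = rowSums(dm),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("sharing_summary", "data.frame")
  out
}

#' Regress daughter contribution on parental clone size
#'
#' Ordinary least squares of the summed daughter contribution on the
#' parental clone size, with the Pearson correlation — the "red line" view
#' of parental/daughter sharing: larger parental clones contribute more
#' across daughters.
#'
#' @param summary A `sharing_summary` from [sharing_analysis()], or any data
#'   frame with `parental_clone_size` and `daughter_total_contribution`.
#' @return List with `slope`, `intercept`, `correlation`, `n`.
#' @export
sharing_regression <- function(summary) {
  x <- summary$parental_clone_size
  y <- summary$daughter_total_contribution
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (sum(x > 0) < 3L) stop("need >= 3 barcodes with nonzero parental size")
  if (stats::var(x) == 0) stop("degenerate regression: parental sizes constant")
  fit <- stats::lm(y ~ x)
  r <- if (stats::var(y) == 0) 0 else stats::cor(x, y)
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    correlation = r,
    n = length(x)
  )
}

#' Histogram of clone frequencies (dominance profile)
#'
#' Bins clone frequencies (percent) into user-supplied intervals to compare
#' how dominant the largest clones are between conditions (e.g. recipients
#' of pre- vs post-culture barcoded cells). Bins are left-closed
#' (`[e_i, e_{i+1})`), with the last bin closed on both sides, so a clone at
#' exactly an inner edge falls in the upper bin. Each kept barcode
#' contributes one observation: the mean of its nonzero frequencies across
#' the selected recipients.
#'
#' @param table A `clone_table`.
#' @param breaks Strictly increasing bin edges, in percent (e.g.
#'   `c(0, 0.5, 1, 5, 100)`).
#' @param role Optional role filter as in [clone_size_summary()].
#' @return List with `counts` (barcodes per bin), `fractions`, `breaks`, and
#'   `dominant_fraction` (fraction of barcodes in the top bin).
#' @export
dominance_profile <- function(table, breaks = c(0, 0.1, 1, 5, 100),
                              role = NULL) {
  stopifnot(inherits(table, "clone_table"))
  if (any(diff(breaks) <= 0)) stop("bin edges must be strictly increasing")
  nm <- select_role(table, role)
  detected <- rowSums(nm > 0) > 0
  freq <- vapply(which(detected), function(i) {
    v <- nm[i, ]
    mean(100 * v[v > 0] / table$scale)
  }, numeric(1))
  bin <- findInterval(freq, breaks, rightmost.closed = TRUE)
  if (any(bin == 0 | bin >= length(breaks))) {
    stop("clone frequencies fall outside the bin range")
  }
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  names(counts) <- paste0("[", breaks[-length(breaks)], ",",
                          breaks[-1], ")")
  list(
    counts = counts,
    fractions = counts / sum(counts),
    breaks = breaks,
    dominant_fraction = counts[length(counts)] / sum(counts)
  )
}
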