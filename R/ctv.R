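#' Assign division counts from dye-dilution intensities
#'
#' A proliferation dye such as CellTrace Violet halves in fluorescence with
#' each cell division, so divisions appear as unit steps in log2 intensity
#' below an undivided anchor population (e.g. co-transplanted CD4+ spleen
#' cells). Each cell is assigned the nearest integer number of divisions,
#'
#' `d = round(anchor_mean - log2(intensity))`, clipped to `[0, d_max]`,
#'
#' so a cell is called undivided exactly when its log2 intensity lies within
#' half a division of the anchor. Halfway points go to the higher division.
#' Cells at or beyond the detection limit — more than `d_max` divisions of
#' dilution, or below an explicit negative-control floor — are censored at
#' `d_max` and flagged (`>= d_max` divisions).
#'
#' @param intensities Linear-scale fluorescence intensities (> 0).
#' @param anchor_mean Mean (or median) log2 intensity of the undivided
#'   control population.
#' @param anchor_sd Spread (log2) of the undivided control; must be > 0
#'   (recorded for provenance; the nearest-bin rule itself does not use it).
#' @param d_max Detection limit in divisions (default 6, a typical dye
#'   limit).
#' @param intensity_floor Optional linear intensity below which cells are considered
#'   beyond the detection limit regardless of the rounding rule (e.g. the
#'   negative-control autofluorescence level).
#' @return Object of class `division_assignment`: data frame with columns
#'   `log2_intensity`, `division` (integer, capped at `d_max`) and
#'   `censored` (TRUE when the true division number may exceed `d_max`),
#'   with `anchor_mean`, `anchor_sd`, `d_max` as attributes.
#' @export
#' @examples
#' assign_divisions(2^c(10, 9, 6.9), anchor_mean = 10, anchor_sd = 0.2)
assign_divisions <- function(intensities, anchor_mean, anchor_sd,
                             d_max = 6L, intensity_floor = NULL) {
  if (any(!is.finite(intensities)) || any(intensities <= 0)) {
    stop("intensities must be positive and finite (linear scale)")
  }
  stopifnot(is.numeric(anchor_sd), anchor_sd > 0, is_count(d_max))
  l2 <- log2(intensities)
  # floor(x + 0.5): nearest integer with halves rounding up, so the
  # undivided bin is exactly |log2 - anchor| < 0.5
  d_raw <- floor(anchor_mean - l2 + 0.5)
  d <- pmin(pmax(d_raw, 0L), d_max)
  censored <- d_raw > d_max
  if (!is.null(intensity_floor)) {
    below <- intensities < intensity_floor
    d[below] <- d_max
    censored <- censored | below
  }
  out <- data.frame(log2_intensity = l2, division = as.integer(d),
                    censored = censored)
  attr(out, "anchor_mean") <- anchor_mean
  attr(out, "anchor_sd") <- anchor_sd
  attr(out, "d_max") <- as.integer(d_max)
  class(out) <- c("division_assignment", "data.frame")
  out
}

#' Division histograms per group
#'
#' Fraction of cells per division bin for each group (e.g. time point or
#' graft type), plus the "fewer than three divisions" summary (bins 0-2)
#' used to describe how quiescent transplanted cHSCs remain.
#'
#' @param assignment A `division_assignment` (or data frame with a
#'   `division` column).
#' @param groups Factor/character vector, one entry per cell; `NULL` treats
#'   all cells as one group.
#' @param d_max Number of division bins (defaults to the assignment's
#'   `d_max` attribute, else the maximum observed).
#' @return List with `fractions` (groups x divisions matrix, rows summing
#'   to 1), `counts`, and `fewer_than_three` (per-group fraction of cells in
#'   bins 0, 1 and 2).
#' @export
division_histogram <- function(assignment, groups = NULL, d_max = NULL) {
  div <- assignment$division
  if (length(div) == 0L) stop("no cells in the assignment")
  d_max <- d_max %||% attr(assignment, "d_max") %||% max(div)
  groups <- groups %||% rep("all", length(div))
  if (length(groups) != length(div)) {
    stop("groups must have one entry per cell")
  }
  counts <- table(group = groups,
                  division = factor(div, levels = 0:d_max))
  counts <- unclass(counts)
  fractions <- counts / rowSums(counts)
  low_bins <- intersect(as.character(0:2), colnames(fractions))
  fewer <- rowSums(fractions[, low_bins, drop = FALSE])
  colnames(fractions)[ncol(fractions)] <- paste0(">=", d_max)
  list(
    fractions = fractions,
    counts = counts,
    fewer_than_three = fewer
  )
}
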