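#' Repopulating units from competitive chimerism
#'
#' In a competitive repopulation assay, test cells are co-transplanted with
#' a known dose of whole-bone-marrow (WBM) competitor cells, and the percent
#' of blood or marrow cells deriving from the test graft (chimerism) is
#' measured per lineage. One repopulating unit (RU) is the average
#' reconstitution activity of 1e5 WBM cells, so
#'
#' `RU = test_pct / (100 - test_pct) * competitor_cells / 1e5`.
#'
#' At 50% chimerism the test graft equals the competitor dose exactly. At
#' 100% chimerism activity is unquantifiable (the assay saturates, as
#' happens when expanded grafts vastly outcompete standard competitor
#' doses); such records return `Inf` with a warning and should be flagged
#' via `saturation_pct` in cohort summaries.
#'
#' @param test_pct Test-cell chimerism, percent in `[0, 100]`.
#' @param competitor_cells WBM competitor dose (cells, > 0).
#' @param input_equivalents Number of input cells (e.g. cHSCs) whose
#'   expansion product was transplanted; the "expansion equivalent" EE10
#'   means the culture output of 10 input cells, so `input_equivalents =
#'   10`. Used for per-input-cell activity.
#' @param lineage,recipient_id Optional annotations carried through.
#' @return Data frame with columns `recipient_id`, `lineage`, `test_pct`,
#'   `ru` and `ru_per_input_cell`. Vectorised over its arguments.
#' @export
#' @examples
#' repopulating_units(50, 5e5)$ru                 # 5: equal to competitor
#' repopulating_units(96.68, 2e6, 10)$ru          # ~583
repopulating_units <- function(test_pct, competitor_cells,
                               input_equivalents = 1,
                               lineage = NA_character_,
                               recipient_id = NA_character_) {
  if (any(test_pct < 0 | test_pct > 100, na.rm = TRUE)) {
    stop("test_pct must lie in [0, 100]")
  }
  if (any(competitor_cells <= 0, na.rm = TRUE)) {
    stop("competitor_cells must be > 0")
  }
  if (any(input_equivalents <= 0, na.rm = TRUE)) {
    stop("input_equivalents must be > 0")
  }
  if (any(test_pct == 100, na.rm = TRUE)) {
    warning("test_pct = 100: assay saturated, RU undefined (Inf)")
  }
  ru <- test_pct / (100 - test_pct) * competitor_cells / 1e5
  data.frame(
    recipient_id = recipient_id,
    lineage = lineage,
    test_pct = test_pct,
    ru = ru,
    ru_per_input_cell = ru / input_equivalents,
    stringsAsFactors = FALSE
  )
}

#' Invert the RU formula back to chimerism
#'
#' @param ru Repopulating units.
#' @param competitor_cells WBM competitor dose (cells).
#' @return Test chimerism percent such that [repopulating_units()] returns
#'   `ru` at that dose.
#' @export
chimerism_from_ru <- function(ru, competitor_cells) {
  stopifnot(all(ru >= 0), all(competitor_cells > 0))
  ru_comp <- competitor_cells / 1e5
  100 * ru / (ru + ru_comp)
}

#' Functional expansion fold from RU cohorts
#'
#' The fold increase in per-input-cell repopulating activity between a
#' cohort transplanted with freshly isolated cells and a cohort transplanted
#' with their ex vivo expanded equivalents:
#' `mean(RU per input cell, expanded) / mean(RU per input cell, fresh)`.
#' Recipients at or above `saturation_pct` chimerism are excluded from the
#' means by default, since their RUs fall out of the assay's quantifiable
#' range.
#'
#' @param fresh,expanded Data frames from [repopulating_units()] (columns
#'   `ru_per_input_cell` and `test_pct`).
#' @param mean_fun Averaging function over recipients: `"arithmetic"`
#'   (default) or `"geometric"`.
#' @param saturation_pct Chimerism at or above which a recipient is treated
#'   as saturated and dropped (default 99.9).
#' @return List with `fold`, `mean_fresh`, `mean_expanded`, `n_fresh`,
#'   `n_expanded`, `n_saturated_dropped`.
#' @export
functional_expansion_fold <- function(fresh, expanded,
                                      mean_fun = c("arithmetic", "geometric"),
                                      saturation_pct = 99.9) {
  mean_fun <- match.arg(mean_fun)
  avg <- function(x) {
    if (mean_fun == "arithmetic") mean(x) else exp(mean(log(x)))
  }
  usable <- function(d) {
    if (nrow(d) == 0L) stop("empty RU cohort")
    ok <- is.finite(d$ru_per_input_cell) & d$test_pct < saturation_pct
    d[ok, , drop = FALSE]
  }
  f <- usable(fresh); e <- usable(expanded)
  n_sat <- (nrow(fresh) - nrow(f)) + (nrow(expanded) - nrow(e))
  if (nrow(f) == 0L || nrow(e) == 0L) {
    stop("no quantifiable recipients left after saturation filtering")
  }
  mf <- avg(f$ru_per_input_cell)
  me <- avg(e$ru_per_input_cell)
  if (mf == 0) stop("fresh cohort has zero mean activity: fold undefined")
  list(fold = me / mf, mean_fresh = mf, mean_expanded = me,
       n_fresh = nrow(f), n_expanded = nrow(e), n_saturated_dropped = n_sat)
}

#' Phenotypic expansion fold
#'
#' Fold change in phenotypic candidate HSC numbers over a culture: final
#' total cell count times the cHSC frequency among them, divided by the
#' number of input cHSCs.
#'
#' @param total_cells Total cells at the end of culture.
#' @param chsc_frequency Fraction of those cells with the cHSC phenotype.
#' @param input_chsc Number of cHSCs that seeded the culture.
#' @return The fold expansion (vectorised).
#' @export
#' @examples
#' phenotypic_expansion_fold(13.6e6, 0.001, 50)   # 272
phenotypic_expansion_fold <- function(total_cells, chsc_frequency,
                                      input_chsc) {
  stopifnot(all(total_cells > 0), all(chsc_frequency >= 0),
            all(chsc_frequency <= 1), all(input_chsc > 0))
  total_cells * chsc_frequency / input_chsc
}

#' Read a chimerism table from CSV
#'
#' Expected columns: `recipient`, `lineage`, `test_pct`, `competitor_cells`,
#' `input_equivalents`.
#'
#' @param path CSV file path.
#' @return Data frame of [repopulating_units()] results, one row per input
#'   record.
#' @export
read_chimerism <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("recipient", "lineage", "test_pct", "competitor_cells",
            "input_equivalents")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0) {
    stop("chimerism CSV missing column(s): ", paste(missing, collapse = ", "))
  }
  repopulating_units(d$test_pct, d$competitor_cells, d$input_equivalents,
                     lineage = d$lineage, recipient_id = d$recipient)
}
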