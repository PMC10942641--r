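#' Generative model of a barcoded HSC expansion culture
#'
#' Parameters of the simulator: founder HSCs are seeded into wells,
#' transduced with a barcode library at a given efficiency, expanded ex vivo
#' with heterogeneous (lognormal) per-clone growth, split across transplant
#' recipients, and finally read out by amplicon sequencing with
#' PCR/sequencing noise.
#'
#' The clone-size law is lognormal: the log of a clone's cell count at
#' harvest is Normal(`log_expansion_mean`, `log_expansion_sd`). The standard
#' deviation `log_expansion_sd` (sigma) is the heterogeneity parameter: sigma
#' = 0 gives every clone the same expected size, while large sigma produces
#' the heavy-tailed, dominated clone-size distributions seen in real
#' expansion cultures.
#'
#' @param n_cells_per_well Founder cells sorted per well.
#' @param n_wells Number of culture wells.
#' @param transduction_efficiency Fraction of founders that receive a
#'   barcode (Bernoulli per founder).
#' @param log_expansion_mean Mean of log clone size (cells) at harvest.
#'   The default corresponds to roughly 1e4 cells per surviving clone after
#'   a 3-week culture; clone *frequencies*, the analysed quantity, are
#'   invariant to this absolute scale.
#' @param log_expansion_sd Heterogeneity sigma (>= 0) of log clone size.
#' @param engraftment_fraction Probability that a transplanted cell engrafts
#'   and contributes to the sequenced compartment.
#' @param reads_per_recipient Target sequencing depth per recipient.
#' @param pcr_dispersion Overdispersion of read counts given engrafted cell
#'   counts (negative-binomial dispersion; 0 recovers Poisson/multinomial
#'   sampling).
#' @param seq_error_rate Per-base substitution rate in simulated reads.
#' @param seed Master integer seed; all randomness flows from it.
#' @return An object of class `expansion_model`.
#' @export
#' @examples
#' expansion_model(log_expansion_sd = 1.5)
expansion_model <- function(n_cells_per_well = 1000L,
                            n_wells = 5L,
                            transduction_efficiency = 0.35,
                            log_expansion_mean = log(1e4),
                            log_expansion_sd = 1.0,
                            engraftment_fraction = 0.1,
                            reads_per_recipient = 1e6,
                            pcr_dispersion = 0.05,
                            seq_error_rate = 0.001,
                            seed = 1L) {
  stopifnot(is_count(n_cells_per_well), n_cells_per_well >= 1,
            is_count(n_wells), n_wells >= 1,
            is_count(reads_per_recipient), reads_per_recipient >= 1)
  if (!is_fraction(transduction_efficiency)) {
    stop("transduction_efficiency must lie in [0, 1]")
  }
  if (!is.numeric(log_expansion_sd) || length(log_expansion_sd) != 1L ||
      !is.finite(log_expansion_sd) || log_expansion_sd < 0) {
    stop("log_expansion_sd must be a finite value >= 0")
  }
  if (!is_fraction(engraftment_fraction) || engraftment_fraction <= 0) {
    stop("engraftment_fraction must lie in (0, 1]")
  }
  if (!is.numeric(pcr_dispersion) || pcr_dispersion < 0 ||
      !is.finite(pcr_dispersion)) {
    stop("pcr_dispersion must be a finite value >= 0")
  }
  if (!is_fraction(seq_error_rate) || seq_error_rate >= 1) {
    stop("seq_error_rate must lie in [0, 1)")
  }
  structure(
    list(
      n_cells_per_well = as.integer(n_cells_per_well),
      n_wells = as.integer(n_wells),
      transduction_efficiency = transduction_efficiency,
      log_expansion_mean = log_expansion_mean,
      log_expansion_sd = log_expansion_sd,
      engraftment_fraction = engraftment_fraction,
      reads_per_recipient = as.double(reads_per_recipient),
      pcr_dispersion = pcr_dispersion,
      seq_error_rate = seq_error_rate,
      seed = as.integer(seed)
    ),
    class = "expansion_model"
  )
}

#' @export
print.expansion_model <- function(x, ...) {
  cat(sprintf(
    paste0("expansion_model: %d wells x %d cells, transduction %.0f%%, ",
           "lognormal(meanlog=%.2f, sigma=%.2f), engraftment %.0f%%, ",
           "%g reads/recipient (dispersion %.3g, error %.3g), seed %d\n"),
    x$n_wells, x$n_cells_per_well, 100 * x$transduction_efficiency,
    x$log_expansion_mean, x$log_expansion_sd,
    100 * x$engraftment_fraction, x$reads_per_recipient,
    x$pcr_dispersion, x$seq_error_rate, x$seed))
  invisible(x)
}

#' Transplant split designs
#'
#' A split design names the transplant recipients, their roles, and the
#' fraction of each well's harvested cells that each recipient receives.
#'
#' `pre_culture_design()` encodes the parental/daughter scheme: each of the
#' five wells sends half of its cells to one dedicated "parental" recipient;
#' the remaining halves are pooled and each of five "daughter" recipients
#' receives one fifth of the pool (i.e. 0.5 x 1/5 = 0.1 of every well).
#'
#' `post_culture_design()` encodes labelling after expansion: one pooled
#' culture, half of which is split across five recipients of which four are
#' analysed (each analysed recipient holds 0.1 of the harvest); recipients
#' carry the role `"plain"` since no parental/daughter structure exists.
#'
#' @param n_wells Number of wells (parental recipients map 1:1 to wells in
#'   the pre-culture design).
#' @param n_daughters Number of daughter recipients.
#' @param n_recipients Number of analysed recipients (post-culture).
#' @return An object of class `split_design`: a data frame with columns
#'   `recipient`, `role`, `well_of_origin` (NA except parentals), and one
#'   `frac_well_<w>` column per well.
#' @export
pre_culture_design <- function(n_wells = 5L, n_daughters = 5L) {
  stopifnot(is_count(n_wells), n_wells >= 1, is_count(n_daughters))
  parental <- data.frame(
    recipient = paste0("P", seq_len(n_wells)),
    role = "parental",
    well_of_origin = seq_len(n_wells),
    stringsAsFactors = FALSE
  )
  daughter <- data.frame(
    recipient = paste0("D", seq_len(n_daughters)),
    role = "daughter",
    well_of_origin = NA_integer_,
    stringsAsFactors = FALSE
  )
  des <- rbind(parental, daughter)
  fr <- matrix(0, nrow(des), n_wells,
               dimnames = list(NULL, paste0("frac_well_", seq_len(n_wells))))
  for (w in seq_len(n_wells)) fr[w, w] <- 0.5
  if (n_daughters > 0) {
    fr[n_wells + seq_len(n_daughters), ] <- 0.5 / n_daughters
  }
  new_split_design(cbind(des, as.data.frame(fr)))
}

#' @rdname pre_culture_design
#' @export
post_culture_design <- function(n_recipients = 4L, n_wells = 1L) {
  stopifnot(is_count(n_recipients), n_recipients >= 1, is_count(n_wells))
  des <- data.frame(
    recipient = paste0("R", seq_len(n_recipients)),
    role = "plain",
    well_of_origin = NA_integer_,
    stringsAsFactors = FALSE
  )
  fr <- matrix(0.5 / 5, n_recipients, n_wells,
               dimnames = list(NULL, paste0("frac_well_", seq_len(n_wells))))
  new_split_design(cbind(des, as.data.frame(fr)))
}

new_split_design <- function(df) {
  fr_cols <- grep("^frac_well_", names(df), value = TRUE)
  fr <- as.matrix(df[, fr_cols, drop = FALSE])
  if (any(fr < 0)) stop("split fractions must be >= 0")
  if (any(colSums(fr) > 1 + 1e-12)) {
    stop("split fractions for a well must sum to <= 1")
  }
  if (anyDuplicated(df$recipient)) stop("duplicate recipient ids in design")
  structure(df, class = c("split_design", "data.frame"))
}

design_fractions <- function(design) {
  as.matrix(design[, grep("^frac_well_", names(design)), drop = FALSE])
}
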