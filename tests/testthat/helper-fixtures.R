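# Shared fixtures, all built in code at test time.

# A small deterministic library for extraction tests.
tiny_library <- function(n = 20, length = 8, seed = 11) {
  random_barcode_library(n, length, seed = seed)
}

# Build a count_matrix from a plain matrix with given roles.
cm_fixture <- function(mat, roles = NULL, wells = NULL) {
  if (is.null(roles)) roles <- rep("plain", ncol(mat))
  count_matrix(mat, roles = data.frame(
    recipient = colnames(mat), role = roles,
    well_of_origin = wells %||% rep(NA_integer_, ncol(mat)),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A clone_table with given normalized-like counts (threshold 0 keeps all).
ct_fixture <- function(mat, roles = NULL, wells = NULL) {
  run_pipeline(cm_fixture(mat, roles, wells), threshold = 0)
}

# Random count matrix with parental/daughter structure, for property tests.
random_count_matrix <- function(seed, n_barcodes = 40, n_parental = 3,
                                n_daughter = 3) {
  set.seed(seed)
  bc <- paste0("BC", sprintf("%03d", seq_len(n_barcodes)))
  rec <- c(paste0("P", seq_len(n_parental)), paste0("D", seq_len(n_daughter)))
  mat <- matrix(rnbinom(n_barcodes * length(rec), mu = 80, size = 0.4),
                n_barcodes, length(rec), dimnames = list(bc, rec))
  cm_fixture(mat, roles = rep(c("parental", "daughter"),
                              c(n_parental, n_daughter)),
             wells = c(seq_len(n_parental), rep(NA_integer_, n_daughter)))
}

# Exhaustive per-read substring-scan oracle for barcode extraction: for each
# read, scan every library barcode for an exact flank5+barcode occurrence.
naive_extraction_oracle <- function(seqs, library) {
  counts <- stats::setNames(integer(length(library$barcodes)),
                            library$barcodes)
  unassigned <- 0L
  for (s in seqs) {
    pos <- regexpr(library$flank5, s, fixed = TRUE)
    hit <- NA_character_
    if (pos > 0) {
      cand <- substr(s, pos + nchar(library$flank5),
                     pos + nchar(library$flank5) + library$length - 1L)
      if (nchar(cand) == library$length && cand %in% library$barcodes) {
        hit <- cand
      }
    }
    if (is.na(hit)) unassigned <- unassigned + 1L
    else counts[hit] <- counts[hit] + 1L
  }
  list(counts = counts, unassigned = unassigned)
}

# Exhaustive rank-enumeration oracle for the Mann-Whitney test: U computed
# by direct pairwise comparison, p by enumerating all group assignments.
mw_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  u_pairwise <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_pairwise(a, b)
  pooled <- c(a, b)
  idx <- utils::combn(n1 + n2, n1)
  mu <- n1 * n2 / 2
  u_all <- apply(idx, 2, function(i) u_pairwise(pooled[i], pooled[-i]))
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
  list(U = u_obs, p = p)
}
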