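# Translation efficiency from ribosome footprints and RNA abundance.
#
# Footprints of 29-35 nt are kept, each read contributes one count at its
# P-site (5' end + fixed offset, default 12 nt), abundances are expressed in
# TPM, and translation efficiency is quantified at two levels:
#   E_transcript = ribosome-bound TPM / whole-cell RNA TPM
#   E_codon      = 1 / dwell time, dwell being a codon's expression-weighted
#                  relative footprint coverage across genes.

#' Filter footprint reads by length
#'
#' Retains reads with lengths in `[min_len, max_len]` (inclusive), the
#' canonical 29-35 nt monosome footprint window.
#'
#' @param reads data frame `transcript_id, start, length`.
#' @param min_len,max_len inclusive bounds (defaults 29 and 35).
#' @return the filtered reads; the number removed is reported via `message`.
#' @export
filter_footprints <- function(reads, min_len = 29L, max_len = 35L) {
  keep <- reads$length >= min_len & reads$length <= max_len
  removed <- sum(!keep)
  if (removed > 0) {
    message("filter_footprints: removed ", removed, " of ", length(keep),
            " reads outside [", min_len, ", ", max_len, "] nt")
  }
  reads[keep, , drop = FALSE]
}

#' Per-nucleotide P-site coverage
#'
#' Each read contributes one count at `start + offset` along its transcript.
#' Reads whose P-site falls beyond the transcript end (or before position 1)
#' are dropped with a message.
#'
#' @param reads filtered footprint reads (`transcript_id, start, length`).
#' @param transcript_lengths named integer vector of mature lengths.
#' @param offset P-site offset from the 5' read end (default 12 nt).
#' @return named list of integer coverage vectors, one per transcript
#'   (all transcripts in `transcript_lengths` are present, zero-filled).
#' @export
psite_coverage <- function(reads, transcript_lengths, offset = 12L) {
  .assert(!is.null(names(transcript_lengths)), "transcript_lengths must be named")
  cov <- lapply(transcript_lengths, function(L) integer(L))
  psite <- reads$start + offset
  L <- transcript_lengths[reads$transcript_id]
  ok <- !is.na(L) & psite >= 1L & psite <= L
  if (any(!ok)) {
    message("psite_coverage: dropped ", sum(!ok),
            " reads with P-site outside the transcript")
  }
  r <- reads[ok, , drop = FALSE]
  psite <- psite[ok]
  for (id in unique(r$transcript_id)) {
    sel <- r$transcript_id == id
    cov[[id]] <- tabulate(psite[sel], nbins = transcript_lengths[[id]])
  }
  cov
}

#' Transcripts-per-million normalisation
#'
#' `TPM_i = 1e6 * (counts_i / len_i) / sum_j (counts_j / len_j)`; the result
#' sums to 1e6. All-zero counts are a degenerate input and raise an error.
#'
#' @param counts named numeric vector of read counts.
#' @param lengths named numeric vector of effective lengths (> 0), matched
#'   by name to `counts`.
#' @return named TPM vector.
#' @export
compute_tpm <- function(counts, lengths) {
  .assert(!is.null(names(counts)) && !is.null(names(lengths)),
          "counts and lengths must be named")
  lengths <- lengths[names(counts)]
  .assert(!anyNA(lengths) && all(lengths > 0), "lengths must be > 0 for all transcripts")
  rate <- counts / lengths
  total <- sum(rate)
  .assert(total > 0, "all counts are zero: TPM undefined")
  1e6 * rate / total
}

#' Transcript-level translation efficiency
#'
#' `E_transcript = ribo_tpm / rna_tpm`, restricted to transcripts where both
#' abundances reach `min_tpm` (inclusive).
#'
#' @param ribo_tpm,rna_tpm named TPM vectors (ribosome-bound and whole-cell).
#' @param min_tpm abundance floor applied to both tables (default 1).
#' @return named vector of E_transcript over the passing transcripts.
#' @export
transcript_te <- function(ribo_tpm, rna_tpm, min_tpm = 1) {
  shared <- intersect(names(ribo_tpm), names(rna_tpm))
  rb <- ribo_tpm[shared]; rn <- rna_tpm[shared]
  keep <- rb >= min_tpm & rn >= min_tpm
  rb[keep] / rn[keep]
}

#' Codon dwell times from P-site coverage
#'
#' Per gene, a codon's coverage is the sum of P-site counts over its three
#' nucleotides and its relative coverage is that sum divided by the gene's
#' mean codon coverage (so relative coverages average 1 within each gene).
#' Per codon type, the dwell time is the expression-weighted mean of relative
#' coverages across genes, weighted by RNA TPM (or unweighted on request).
#' Start/stop codons and `trim` codons at each CDS end are excluded; genes
#' whose mean codon coverage falls below `min_codon_coverage` are skipped.
#'
#' @param coverage named list of per-nt P-site coverage ([psite_coverage()]).
#' @param models a `transcript_models` object (mature CDS coordinates).
#' @param rna_tpm named RNA TPM vector used as weights.
#' @param trim codons trimmed at each CDS end (default 5, on top of the
#'   start/stop codons).
#' @param min_codon_coverage per-gene floor on mean codon coverage.
#' @param weighted weight genes by RNA TPM (default) or equally.
#' @return named numeric vector of dwell times over the 61 sense codons
#'   (`NA` for codons never observed).
#' @export
codon_dwell <- function(coverage, models, rna_tpm, trim = 5L,
                        min_codon_coverage = 1, weighted = TRUE) {
  ct <- .codon_table()
  tx <- models$transcripts
  mseq <- mature_sequences(models)
  num <- stats::setNames(rep(0, length(ct$sense)), ct$sense)
  den <- stats::setNames(rep(0, length(ct$sense)), ct$sense)
  for (i in seq_len(nrow(tx))) {
    id <- tx$transcript_id[i]
    cv <- coverage[[id]]
    if (is.null(cv)) next
    ncod <- tx$cds_len[i] %/% 3L
    lo <- 2L + trim            # first kept codon (skip start + trim)
    hi <- ncod - 1L - trim     # last kept codon (skip stop + trim)
    if (hi - lo + 1L < 5L) next
    k <- lo:hi
    starts_nt <- tx$utr5_len[i] + 3L * (k - 1L) + 1L
    csum <- cv[starts_nt] + cv[starts_nt + 1L] + cv[starts_nt + 2L]
    mu <- mean(csum)
    if (mu < min_codon_coverage) next
    rel <- csum / mu
    codons <- substring(mseq[[id]], starts_nt, starts_nt + 2L)
    w <- if (weighted) rna_tpm[[id]] else 1
    if (is.null(w) || is.na(w)) next
    add <- rowsum(rel * w, codons)
    cnt <- rowsum(rep(w, length(rel)), codons)
    hit <- intersect(rownames(add), ct$sense)
    num[hit] <- num[hit] + add[hit, 1]
    den[hit] <- den[hit] + cnt[hit, 1]
  }
  dwell <- ifelse(den > 0, num / den, NA_real_)
  stats::setNames(dwell, ct$sense)
}

#' Codon-level translation efficiency
#'
#' `E_codon = 1 / dwell`: fast-decoded codons (short dwell) translate
#' efficiently.
#'
#' @param dwell named dwell-time vector from [codon_dwell()] (values > 0).
#' @return named vector of E_codon.
#' @export
codon_te <- function(dwell) {
  .assert(all(is.na(dwell) | dwell > 0), "dwell times must be positive")
  1 / dwell
}

#' Transcript TE from protein and RNA abundance
#'
#' The protein-abundance flavour of transcript-level translation efficiency:
#' protein abundance divided by RNA abundance, over transcripts present in
#' both tables with positive RNA abundance.
#'
#' @param protein,rna named abundance vectors.
#' @return named ratio vector.
#' @export
transcript_te_protein <- function(protein, rna) {
  shared <- intersect(names(protein), names(rna))
  keep <- rna[shared] > 0
  protein[shared][keep] / rna[shared][keep]
}
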