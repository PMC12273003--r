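# Psi site calling from BID-seq deletion pileups.
#
# BID-seq converts pseudouridine (Psi) into a reverse-transcription deletion,
# so the per-site "gap ratio" (deletion-bearing reads / total reads) reports
# modification stoichiometry once passed through a calibration curve built
# from spike-ins with known Psi fractions. Calling proceeds as: combine
# replicates -> gap ratio -> calibrate -> binomial test against the
# background deletion rate -> Benjamini-Hochberg filter.

#' Combine replicate pileups from one tissue
#'
#' Per-position total and deletion read counts are summed across replicates;
#' a position absent from a replicate contributes zero. Replicates from one
#' tissue are pooled before stoichiometry is computed so that low-depth sites
#' borrow depth across libraries.
#'
#' @param pileups a list of pileup data frames, each with columns
#'   `ref_id`, `pos`, `strand`, `total_reads`, `deletion_reads` and optionally
#'   `ref_base`.
#' @return a single pileup data frame with summed counts, ordered by
#'   (`ref_id`, `pos`, `strand`).
#' @export
combine_replicates <- function(pileups) {
  .assert(is.list(pileups) && length(pileups) >= 1L,
          "pileups must be a non-empty list of pileup data frames")
  if (length(pileups) == 1L) return(validate_pileup(pileups[[1]]))
  pl <- lapply(pileups, validate_pileup)
  all <- do.call(rbind, pl)
  key <- paste(all$ref_id, all$pos, all$strand, sep = "\r")
  if (!is.null(all$ref_base)) {
    nb <- tapply(all$ref_base, key, function(b) length(unique(b)))
    if (any(nb > 1L)) {
      bad <- names(nb)[which(nb > 1L)[1]]
      stop("conflicting ref_base across replicates at ",
           gsub("\r", ":", bad), call. = FALSE)
    }
  }
  tot <- rowsum(cbind(total = all$total_reads, del = all$deletion_reads), key)
  parts <- do.call(rbind, strsplit(rownames(tot), "\r", fixed = TRUE))
  out <- data.frame(ref_id = parts[, 1], pos = as.integer(parts[, 2]),
                    strand = parts[, 3], total_reads = as.integer(tot[, "total"]),
                    deletion_reads = as.integer(tot[, "del"]),
                    stringsAsFactors = FALSE)
  if (!is.null(all$ref_base)) {
    first <- !duplicated(key)
    out$ref_base <- all$ref_base[first][match(rownames(tot), key[first])]
  }
  out[order(out$ref_id, out$pos, out$strand), , drop = FALSE]
}

#' Validate a pileup data frame
#'
#' Checks the column contract and the count invariant
#' `0 <= deletion_reads <= total_reads`, `pos >= 1`.
#' @param pileup a pileup data frame.
#' @return the pileup, invisibly unchanged.
#' @export
validate_pileup <- function(pileup) {
  need <- c("ref_id", "pos", "strand", "total_reads", "deletion_reads")
  miss <- setdiff(need, names(pileup))
  .assert(length(miss) == 0L,
          paste0("pileup missing columns: ", paste(miss, collapse = ", ")))
  bad <- which(pileup$deletion_reads > pileup$total_reads |
               pileup$deletion_reads < 0 | pileup$total_reads < 0)
  if (length(bad)) {
    stop("pileup row ", bad[1], ": deletion_reads (", pileup$deletion_reads[bad[1]],
         ") exceeds total_reads (", pileup$total_reads[bad[1]], ")", call. = FALSE)
  }
  .assert(all(pileup$pos >= 1L), "pileup positions must be >= 1 (1-based)")
  .assert(all(pileup$strand %in% c("+", "-")), "strand must be '+' or '-'")
  pileup
}

#' Gap ratio of a site
#'
#' The raw BID-seq signal: deletion-bearing reads over total reads. Sites with
#' zero depth are undefined and return `NA` (callers skip them).
#'
#' @param deletion_reads,total_reads integer vectors.
#' @return numeric vector in `[0, 1]`, `NA` where `total_reads == 0`.
#' @export
compute_gap_ratio <- function(deletion_reads, total_reads) {
  .assert(all(deletion_reads <= total_reads), "deletion_reads > total_reads")
  ifelse(total_reads > 0, deletion_reads / total_reads, NA_real_)
}

#' Construct a calibration curve
#'
#' A monotone piecewise-linear map from observed gap ratio to Psi fraction,
#' anchored at (0, 0), in the style of spike-in calibration: control RNAs with
#' known Psi fractions give (gap ratio, fraction) control points.
#'
#' @param gap_ratio,fraction numeric vectors of equal length in `[0, 1]`,
#'   strictly increasing, containing the anchor point (0, 0).
#' @return an object of class `calibration_curve`.
#' @export
calibration_curve <- function(gap_ratio, fraction) {
  .assert(length(gap_ratio) == length(fraction) && length(gap_ratio) >= 2L,
          "need >= 2 control points of equal length")
  .assert(all(gap_ratio >= 0 & gap_ratio <= 1) && all(fraction >= 0 & fraction <= 1),
          "control points must lie in [0, 1]")
  .assert(all(diff(gap_ratio) > 0) && all(diff(fraction) > 0),
          "control points must be strictly increasing in both coordinates")
  .assert(gap_ratio[1] == 0 && fraction[1] == 0,
          "calibration curve must contain the anchor point (0, 0)")
  structure(list(gap_ratio = as.numeric(gap_ratio),
                 fraction = as.numeric(fraction)),
            class = "calibration_curve")
}

#' Identity calibration curve (gap ratio taken as the Psi fraction)
#' @return a `calibration_curve`.
#' @export
identity_curve <- function() calibration_curve(c(0, 1), c(0, 1))

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Calibration curve with", length(x$gap_ratio), "control points\n")
  print(data.frame(gap_ratio = x$gap_ratio, fraction = x$fraction))
  invisible(x)
}

#' Calibrate gap ratios to Psi fractions
#'
#' Monotone piecewise-linear interpolation through the curve's control points;
#' inputs beyond the terminal control point clamp to its fraction (1.0 for a
#' curve whose last point maps to 1).
#'
#' @param gap_ratio numeric vector in `[0, 1]`.
#' @param curve a [calibration_curve()].
#' @return Psi fractions in `[0, 1]`.
#' @export
calibrate_fraction <- function(gap_ratio, curve) {
  .assert(inherits(curve, "calibration_curve"), "curve must be a calibration_curve")
  stats::approx(curve$gap_ratio, curve$fraction, xout = gap_ratio,
                method = "linear", rule = 2, ties = "ordered")$y
}

# inverse map: fraction -> expected gap ratio (used by the simulator)
.uncalibrate_fraction <- function(fraction, curve) {
  stats::approx(curve$fraction, curve$gap_ratio, xout = fraction,
                method = "linear", rule = 2, ties = "ordered")$y
}

#' One-sided binomial site P value
#'
#' Upper-tail probability `P(X >= deletion_reads)` for
#' `X ~ Binomial(total_reads, background_rate)`: the chance of seeing at
#' least the observed number of deletions from background alone.
#'
#' @param deletion_reads,total_reads integer vectors.
#' @param background_rate background deletion probability in `[0, 1)`.
#' @return P values in `[0, 1]`.
#' @export
site_pvalue <- function(deletion_reads, total_reads, background_rate) {
  .assert(.is_prob(background_rate) && background_rate < 1,
          "background_rate must lie in [0, 1)")
  .assert(all(deletion_reads <= total_reads), "deletion_reads > total_reads")
  stats::pbinom(deletion_reads - 1L, total_reads, background_rate,
                lower.tail = FALSE)
}

#' Extract the sequence motif centred on a site
#'
#' Returns the k-mer (k = 3 or 5) centred on the queried position; minus-strand
#' sites return the reverse complement of the plus-strand window so the centre
#' base reads as the modified T. Windows falling off the sequence end return
#' an empty string.
#'
#' @param sequence reference sequence (character scalar).
#' @param position 1-based centre position.
#' @param k motif width, 3 or 5.
#' @param strand `"+"` or `"-"`.
#' @return character scalar k-mer, or `""` if the window is out of range.
#' @export
extract_motif <- function(sequence, position, k = 3L, strand = "+") {
  .assert(k %in% c(3L, 5L), "k must be 3 or 5")
  half <- (k - 1L) %/% 2L
  lo <- position - half
  hi <- position + half
  n <- nchar(sequence)
  if (lo < 1L || hi > n) return("")
  m <- substr(sequence, lo, hi)
  if (strand == "-") m <- .revcomp(m)
  m
}

#' Default Psi-calling thresholds
#'
#' @param min_depth minimum combined read depth at a site.
#' @param min_deletion_reads minimum deletion-bearing reads.
#' @param min_gap_ratio minimum gap ratio.
#' @param q_cutoff Benjamini-Hochberg adjusted P-value ceiling.
#' @return a named list of thresholds. All comparisons are inclusive: a site
#'   exactly at a threshold passes.
#' @export
psi_thresholds <- function(min_depth = 20L, min_deletion_reads = 5L,
                           min_gap_ratio = 0.02, q_cutoff = 0.05) {
  list(min_depth = min_depth, min_deletion_reads = min_deletion_reads,
       min_gap_ratio = min_gap_ratio, q_cutoff = q_cutoff)
}

#' Call Psi sites from a combined pileup
#'
#' Considers only positions whose reference base (on the site's strand) is T,
#' computes gap ratios, calibrates them to fractions, tests each candidate
#' against the background deletion rate with a one-sided binomial test, and
#' retains sites passing depth, deletion-count, gap-ratio and BH-adjusted
#' P-value thresholds. The background rate defaults to the median gap ratio
#' over covered non-T positions of the same pileup.
#'
#' @param pileup combined pileup data frame (see [combine_replicates()]).
#' @param sequences named character vector (or `DNAStringSet`) of reference
#'   sequences keyed by `ref_id`.
#' @param curve a [calibration_curve()].
#' @param thresholds see [psi_thresholds()].
#' @param background_rate background deletion rate; `NULL` to estimate from
#'   non-T positions.
#' @param tissue optional tissue label carried into the output.
#' @return a `PsiSite` data frame with columns `ref_id, pos, strand, depth,
#'   del, gap_ratio, fraction, p, q, motif3, motif5, tissue`.
#' @export
call_sites <- function(pileup, sequences, curve = identity_curve(),
                       thresholds = psi_thresholds(), background_rate = NULL,
                       tissue = NA_character_) {
  pileup <- validate_pileup(pileup)
  if (inherits(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  .assert(!is.null(names(sequences)), "sequences must be named by ref_id")
  miss <- setdiff(unique(pileup$ref_id), names(sequences))
  if (length(miss)) {
    stop("missing reference sequence for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  seqs <- sequences[pileup$ref_id]
  plus_base <- substr(seqs, pileup$pos, pileup$pos)
  base_on_strand <- ifelse(pileup$strand == "+", plus_base,
                           unname(.comp_base(plus_base)))
  is_t <- base_on_strand == "T"
  covered <- pileup$total_reads > 0

  if (is.null(background_rate)) {
    bg_pool <- compute_gap_ratio(pileup$deletion_reads[!is_t & covered],
                                 pileup$total_reads[!is_t & covered])
    background_rate <- if (length(bg_pool)) stats::median(bg_pool) else 0
  }

  cand <- pileup[is_t & covered, , drop = FALSE]
  if (nrow(cand) == 0L) return(.empty_sites(tissue))
  gr <- compute_gap_ratio(cand$deletion_reads, cand$total_reads)
  p <- site_pvalue(cand$deletion_reads, cand$total_reads, background_rate)
  q <- stats::p.adjust(p, method = "BH")
  keep <- cand$total_reads >= thresholds$min_depth &
    cand$deletion_reads >= thresholds$min_deletion_reads &
    gr >= thresholds$min_gap_ratio &
    q <= thresholds$q_cutoff
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(.empty_sites(tissue))
  gr <- gr[keep]; p <- p[keep]; q <- q[keep]
  motif3 <- mapply(extract_motif, sequences[cand$ref_id], cand$pos,
                   MoreArgs = list(k = 3L), strand = cand$strand,
                   USE.NAMES = FALSE)
  motif5 <- mapply(extract_motif, sequences[cand$ref_id], cand$pos,
                   MoreArgs = list(k = 5L), strand = cand$strand,
                   USE.NAMES = FALSE)
  data.frame(ref_id = cand$ref_id, pos = cand$pos, strand = cand$strand,
             depth = cand$total_reads, del = cand$deletion_reads,
             gap_ratio = gr, fraction = calibrate_fraction(gr, curve),
             p = p, q = q, motif3 = motif3, motif5 = motif5,
             tissue = tissue, stringsAsFactors = FALSE)
}

.empty_sites <- function(tissue = NA_character_) {
  data.frame(ref_id = character(0), pos = integer(0), strand = character(0),
             depth = integer(0), del = integer(0), gap_ratio = numeric(0),
             fraction = numeric(0), p = numeric(0), q = numeric(0),
             motif3 = character(0), motif5 = character(0),
             tissue = character(0), stringsAsFactors = FALSE)
}

#' Summarise motifs over called sites
#'
#' Per-motif site count, percentage of sites and mean Psi fraction, optionally
#' restricted to motifs whose mean fraction exceeds a cutoff (the convention
#' used for plotting high-stoichiometry motifs is a 20% floor).
#'
#' @param sites a `PsiSite` data frame.
#' @param k motif width, 3 or 5.
#' @param min_mean_fraction optional floor on the per-motif mean fraction
#'   (e.g. `0.20`); `NULL` keeps all motifs.
#' @return data frame with `motif, n, pct_sites, mean_fraction`, ordered by
#'   decreasing count.
#' @export
motif_summary <- function(sites, k = 3L, min_mean_fraction = NULL) {
  .assert(k %in% c(3L, 5L), "k must be 3 or 5")
  col <- if (k == 3L) "motif3" else "motif5"
  m <- sites[[col]]
  ok <- !is.na(m) & m != ""
  m <- m[ok]; fr <- sites$fraction[ok]
  if (!length(m)) {
    return(data.frame(motif = character(0), n = integer(0),
                      pct_sites = numeric(0), mean_fraction = numeric(0)))
  }
  n <- as.integer(table(m))
  names(n) <- names(table(m))
  mf <- tapply(fr, m, mean)
  out <- data.frame(motif = names(n), n = n,
                    pct_sites = 100 * n / sum(n),
                    mean_fraction = as.numeric(mf[names(n)]),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(min_mean_fraction)) {
    out <- out[out$mean_fraction > min_mean_fraction, , drop = FALSE]
  }
  out[order(-out$n, out$motif), , drop = FALSE]
}
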