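# Cross-species conservation of Psi sites.
#
# Orthologous sequences are aligned locally (Smith-Waterman, linear gap
# penalty), Psi positions of one species are walked through the alignment to
# their partner column, and each site is put in one of four classes:
#   1 no homologous site, 2 homologous but partner base not U,
#   3 one-to-one conserved U, 4 conserved U in a one-to-many context.
# Classes 3 + 4 count as conserved. A per-column conservation score over a
# multiple sequence alignment supports the density-vs-conservation test.

#' Alignment scoring scheme
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch score (<= 0).
#' @param gap linear gap score per gapped column (< 0).
#' @return an `alignment_scoring` list.
#' @export
alignment_scoring <- function(match = 2, mismatch = -1, gap = -2) {
  .assert(match > 0, "match reward must be positive")
  .assert(mismatch <= 0, "mismatch score must be <= 0")
  .assert(gap < 0, "gap score must be negative")
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "alignment_scoring")
}

#' Smith-Waterman local alignment
#'
#' Dynamic-programming local alignment with linear gap penalties. The
#' traceback starts at the highest-scoring cell (first in row-major order on
#' ties) and, within a cell, prefers diagonal over up over left, so results
#' are deterministic.
#'
#' @param seq_a,seq_b character scalars over `{A,C,G,T,N}` (N never matches).
#' @param scoring an [alignment_scoring()].
#' @return list with `score`, `start_a`, `end_a`, `start_b`, `end_b` and
#'   `columns`, a data frame of aligned column pairs (`pos_a`/`pos_b`, `NA`
#'   for a gap). A best score of 0 returns an empty alignment.
#' @export
smith_waterman <- function(seq_a, seq_b, scoring = alignment_scoring()) {
  .assert(is.character(seq_a) && nzchar(seq_a) &&
          is.character(seq_b) && nzchar(seq_b), "sequences must be non-empty")
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1L, m + 1L)
  # 0 stop, 1 diagonal, 2 up (gap in b), 3 left (gap in a)
  TB <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    ai <- a[i]
    srow <- ifelse(b == ai & ai != "N", scoring$match, scoring$mismatch)
    for (j in seq_len(m)) {
      diag <- H[i, j] + srow[j]
      up <- H[i, j + 1L] + scoring$gap
      left <- H[i + 1L, j] + scoring$gap
      best <- max(0, diag, up, left)
      H[i + 1L, j + 1L] <- best
      TB[i + 1L, j + 1L] <- if (best == 0) 0L else if (best == diag) 1L
                            else if (best == up) 2L else 3L
    }
  }
  score <- max(H)
  if (score == 0) {
    return(list(score = 0, start_a = NA_integer_, end_a = NA_integer_,
                start_b = NA_integer_, end_b = NA_integer_,
                columns = data.frame(pos_a = integer(0), pos_b = integer(0))))
  }
  # tie-break on the traceback start: first maximal cell in (row, col) order
  idx <- which(H == score, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  i <- idx[1, 1]; j <- idx[1, 2]
  end_a <- i - 1L; end_b <- j - 1L
  pa <- integer(0); pb <- integer(0)
  while (TB[i, j] != 0L) {
    mv <- TB[i, j]
    if (mv == 1L) {
      pa <- c(i - 1L, pa); pb <- c(j - 1L, pb); i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      pa <- c(i - 1L, pa); pb <- c(NA_integer_, pb); i <- i - 1L
    } else {
      pa <- c(NA_integer_, pa); pb <- c(j - 1L, pb); j <- j - 1L
    }
  }
  list(score = score,
       start_a = min(pa, na.rm = TRUE), end_a = end_a,
       start_b = min(pb, na.rm = TRUE), end_b = end_b,
       columns = data.frame(pos_a = pa, pos_b = pb))
}

#' Map Psi positions through a local alignment
#'
#' Each queried position in sequence A is looked up in the alignment columns:
#' inside the aligned block and matched to a residue it yields the partner
#' base; aligned to a gap or outside the block it has no homologous site.
#'
#' @param alignment result of [smith_waterman()].
#' @param psi_positions_a 1-based Psi positions in sequence A.
#' @param seq_b sequence B (for base lookup).
#' @return data frame `pos_a, pos_b, aligned_base_b` (`aligned_base_b` is
#'   `"gap"` for gap columns and `"none"` outside the alignment).
#' @export
map_homologous_sites <- function(alignment, psi_positions_a, seq_b) {
  nb <- nchar(seq_b)
  cols <- alignment$columns
  out <- data.frame(pos_a = as.integer(psi_positions_a),
                    pos_b = NA_integer_, aligned_base_b = "none",
                    stringsAsFactors = FALSE)
  if (nrow(cols) == 0L) return(out)
  .assert(all(psi_positions_a >= 1), "psi positions must be >= 1")
  hit <- match(out$pos_a, cols$pos_a)
  inside <- !is.na(hit)
  pb <- cols$pos_b[hit[inside]]
  out$pos_b[inside] <- pb
  out$aligned_base_b[inside] <- ifelse(
    is.na(pb), "gap", substring(seq_b, pb, pb))
  .assert(all(is.na(out$pos_b) | out$pos_b <= nb), "partner position out of range")
  out
}

#' Classify a cross-species site pair
#'
#' @param aligned_bases character vector of partner bases for one Psi site,
#'   one entry per orthologous partner gene (`"gap"`/`"none"` where the site
#'   has no homologous column in that partner).
#' @param context `"one_to_one"` or `"one_to_many"` orthology context.
#' @return integer class 1-4: 1 = no homologous site in any partner, 2 =
#'   homologous but no partner base is U, 3 = one-to-one conserved U, 4 =
#'   conserved U in a one-to-many context.
#' @export
classify_site_pair <- function(aligned_bases, context = c("one_to_one", "one_to_many")) {
  context <- match.arg(context)
  real <- !(aligned_bases %in% c("gap", "none"))
  if (!any(real)) return(1L)
  is_u <- aligned_bases %in% c("T", "U")
  if (!any(is_u)) return(2L)
  if (context == "one_to_one") 3L else 4L
}

#' Classify all Psi sites of one species against an orthologue set
#'
#' Aligns the query gene against each orthologous partner, maps every Psi
#' position, and assigns the four-class conservation label; the orthology
#' context is one-to-many whenever a gene has more than one partner.
#'
#' @param seq_a query sequence containing the Psi sites.
#' @param partner_seqs named character vector of orthologous partner
#'   sequences in the other species.
#' @param psi_positions_a Psi positions in `seq_a`.
#' @param scoring an [alignment_scoring()].
#' @return data frame `pos_a, class, conserved, n_partners`.
#' @export
classify_conservation <- function(seq_a, partner_seqs, psi_positions_a,
                                  scoring = alignment_scoring()) {
  .assert(length(partner_seqs) >= 1L, "need at least one partner sequence")
  context <- if (length(partner_seqs) > 1L) "one_to_many" else "one_to_one"
  base_mat <- sapply(partner_seqs, function(sb) {
    aln <- smith_waterman(seq_a, sb, scoring)
    map_homologous_sites(aln, psi_positions_a, sb)$aligned_base_b
  })
  base_mat <- matrix(base_mat, nrow = length(psi_positions_a))
  cls <- apply(base_mat, 1L, classify_site_pair, context = context)
  data.frame(pos_a = as.integer(psi_positions_a), class = as.integer(cls),
             conserved = cls %in% c(3L, 4L),
             n_partners = length(partner_seqs), stringsAsFactors = FALSE)
}

#' Per-column conservation score of a multiple sequence alignment
#'
#' Raw column score = mean pairwise identity over non-gap residue pairs
#' (columns with fewer than two residues score 0), smoothed with a centred
#' moving average and min-max scaled to `[0, 1]`. A constant smoothed track
#' scales to all zeros with a warning.
#'
#' @param msa character vector of aligned sequences (equal length, `-` gaps).
#' @param window moving-average width in columns (default 50).
#' @return data frame `column, raw, smoothed, scaled`.
#' @export
conservation_score <- function(msa, window = 50L) {
  .assert(length(msa) >= 2L, "need >= 2 aligned sequences")
  lens <- nchar(msa)
  .assert(length(unique(lens)) == 1L, "aligned sequences must have equal length")
  L <- lens[1]
  chars <- do.call(rbind, strsplit(toupper(msa), ""))
  raw <- apply(chars, 2L, function(col) {
    res <- col[col != "-"]
    k <- length(res)
    if (k < 2L) return(0)
    tab <- table(res)
    sum(tab * (tab - 1) / 2) / (k * (k - 1) / 2)
  })
  half <- window %/% 2L
  smoothed <- vapply(seq_len(L), function(i) {
    mean(raw[max(1L, i - half):min(L, i + half)])
  }, numeric(1))
  rng <- range(smoothed)
  if (rng[2] > rng[1]) {
    scaled <- (smoothed - rng[1]) / (rng[2] - rng[1])
  } else {
    warning("constant conservation track; scaled scores set to 0")
    scaled <- rep(0, L)
  }
  data.frame(column = seq_len(L), raw = raw, smoothed = smoothed,
             scaled = scaled)
}

#' Correlate Psi density with sequence conservation
#'
#' Tiles the molecule into windows, counts Psi sites and averages the scaled
#' conservation score per window, and tests the association with a two-sided
#' Pearson correlation test.
#'
#' @param profile result of [conservation_score()] (uses `scaled`).
#' @param psi_positions 1-based site positions on the same coordinate axis.
#' @param window window width in columns (default 50; at least 3 windows
#'   must fit).
#' @return list with `r`, `p`, `n_windows` and the per-window table.
#' @export
density_conservation_correlation <- function(profile, psi_positions,
                                             window = 50L) {
  L <- nrow(profile)
  n_win <- L %/% window
  .assert(n_win >= 3L, "fewer than 3 windows: correlation undefined")
  win <- pmin(n_win, 1L + (profile$column - 1L) %/% window)
  cons <- tapply(profile$scaled, win, mean)
  dens <- tabulate(pmin(n_win, 1L + (as.integer(psi_positions) - 1L) %/% window),
                   nbins = n_win)
  ct <- stats::cor.test(as.numeric(cons), dens, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n_windows = n_win,
       windows = data.frame(window = seq_len(n_win),
                            conservation = as.numeric(cons), n_sites = dens))
}

#' Naive centre-star multiple alignment (synthetic fixtures only)
#'
#' Aligns every sequence to the first (the "centre") with [smith_waterman()]
#' run in global-ish mode by padding, then stacks the pairwise alignments.
#' Intended only to build small synthetic MSAs for testing; real MSAs should
#' be supplied as aligned FASTA from a dedicated aligner.
#'
#' @param seqs character vector of >= 2 unaligned sequences.
#' @param scoring an [alignment_scoring()].
#' @return character vector of gapped sequences of equal length.
#' @export
center_star_msa <- function(seqs, scoring = alignment_scoring()) {
  .assert(length(seqs) >= 2L, "need >= 2 sequences")
  centre <- seqs[1]
  Lc <- nchar(centre)
  # per-sequence map: centre position -> partner base or gap
  maps <- lapply(seqs[-1], function(sb) {
    aln <- smith_waterman(centre, sb, scoring)
    out <- rep("-", Lc)
    if (nrow(aln$columns)) {
      cols <- aln$columns[!is.na(aln$columns$pos_a), , drop = FALSE]
      out[cols$pos_a] <- ifelse(is.na(cols$pos_b), "-",
                                substring(sb, cols$pos_b, cols$pos_b))
    }
    out
  })
  rows <- c(list(strsplit(centre, "")[[1]]), maps)
  vapply(rows, paste, character(1), collapse = "")
}
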