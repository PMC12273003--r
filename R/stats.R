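# The statistical layer: tissue-wise correlations between Psi stoichiometry
# and translation efficiency, quantile-group comparisons of lifetime and TE,
# and the sign odds-ratio test used for tRNA regions.

#' Pearson correlation with a two-sided test
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list `r, p, n, ok`; `ok = FALSE` (with `NA` estimates) when either
#'   vector has zero variance.
#' @export
pearson_r <- function(x, y) {
  .assert(length(x) == length(y), "x and y lengths differ")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, ok = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, ok = TRUE)
}

# vectorised two-sided p for Pearson r at sample size n (t transform)
.pearson_p <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r) & n >= 3 & abs(r) < 1
  t <- r[ok] * sqrt((n[ok] - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(abs(t), n[ok] - 2, lower.tail = FALSE)
  p[!is.na(r) & abs(r) == 1 & n >= 3] <- 0
  p
}

#' Correlate site stoichiometry with transcript TE across tissues
#'
#' For every (site, transcript) pair, computes the Pearson correlation over
#' tissues between the site's Psi fraction and the transcript's E_transcript,
#' requiring at least `min_tissues` tissues with both values and nonzero
#' variance. Per site, the summary is the median r over transcripts; the
#' overall sign tally counts sites with negative vs positive median.
#'
#' @param site_mat sites x tissues fraction matrix ([tissue_site_matrix()]).
#' @param te_mat transcripts x tissues E_transcript matrix.
#' @param min_tissues minimum shared tissues per pair (default 3).
#' @return list with `r` (sites x transcripts), `p`, `n`, `site_median`,
#'   `sign_tally` (`pos`, `neg`, `zero`, `skipped`) and `positive_share`.
#' @export
site_te_correlation <- function(site_mat, te_mat, min_tissues = 3L) {
  shared <- intersect(colnames(site_mat), colnames(te_mat))
  .assert(length(shared) >= min_tissues,
          "fewer shared tissues than min_tissues")
  s <- site_mat[, shared, drop = FALSE]
  e <- te_mat[, shared, drop = FALSE]
  r <- suppressWarnings(stats::cor(t(s), t(e), use = "pairwise.complete.obs"))
  n <- (!is.na(s)) %*% t(!is.na(e))
  r[n < min_tissues] <- NA_real_
  p <- matrix(.pearson_p(as.vector(r), as.vector(n)), nrow = nrow(r),
              dimnames = dimnames(r))
  site_median <- apply(r, 1L, stats::median, na.rm = TRUE)
  site_median[is.nan(site_median)] <- NA_real_
  defined <- !is.na(site_median)
  tally <- c(pos = sum(site_median[defined] > 0),
             neg = sum(site_median[defined] < 0),
             zero = sum(site_median[defined] == 0),
             skipped = sum(!defined))
  signed <- tally[["pos"]] + tally[["neg"]]
  list(r = r, p = p, n = n, site_median = site_median, sign_tally = tally,
       positive_share = if (signed > 0) tally[["pos"]] / signed else NA_real_)
}

# equal-size (+/-1) groups over a stably ordered vector; extras go to the
# earliest groups, ties broken by the id to keep group counts reproducible
.quantile_groups <- function(value, id, k) {
  ord <- order(value, id)
  n <- length(value)
  .assert(k >= 2L && n >= k, "need at least k observations")
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  grp <- integer(n)
  grp[ord] <- rep(seq_len(k), sizes)
  grp
}

#' Group transcripts by a structural feature into quantile bins
#'
#' Features: `relative_utr5_length` = 5'-UTR length / CDS length, or raw
#' `cds_length`. Groups are equal-sized (+/-1, extras in the lowest groups),
#' ordered by the feature, ties broken by transcript id.
#'
#' @param transcripts data frame with `transcript_id`, `utr5_len`, `cds_len`.
#' @param feature `"relative_utr5_length"` or `"cds_length"`.
#' @param k number of groups (default 5).
#' @return data frame `transcript_id, feature_value, group` (transcripts with
#'   `cds_len == 0` are excluded).
#' @export
group_by_feature <- function(transcripts,
                             feature = c("relative_utr5_length", "cds_length"),
                             k = 5L) {
  feature <- match.arg(feature)
  tx <- transcripts[transcripts$cds_len > 0, , drop = FALSE]
  val <- switch(feature,
                relative_utr5_length = tx$utr5_len / tx$cds_len,
                cds_length = tx$cds_len)
  grp <- .quantile_groups(val, tx$transcript_id, k)
  data.frame(transcript_id = tx$transcript_id, feature_value = val,
             group = grp, stringsAsFactors = FALSE)
}

#' Correlate tRNA-site stoichiometry with codon TE, grouped by tRNA region
#'
#' For each planted tRNA Psi site and each codon its tRNA decodes, computes
#' the Pearson correlation across tissues between site fraction and that
#' codon's E_codon. Records carry the site's cloverleaf region label so the
#' sign distribution can be compared between loops and stems.
#'
#' @param sites data frame `trna_id, position, region_label, codons`
#'   (comma-separated decoded codons), as from [simulate_trna_dataset()].
#' @param fractions site x tissue stoichiometry matrix (rows
#'   `trna_id:position`).
#' @param e_codon codon x tissue TE matrix.
#' @param min_tissues minimum tissues (default 3).
#' @return data frame `trna_id, position, region, codon, r, p, n`.
#' @export
trna_region_te_correlation <- function(sites, fractions, e_codon,
                                       min_tissues = 3L) {
  .assert(all(!is.na(sites$region_label)), "every site needs a region label")
  tissues <- intersect(colnames(fractions), colnames(e_codon))
  .assert(length(tissues) >= min_tissues, "not enough shared tissues")
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    key <- paste(sites$trna_id[i], sites$position[i], sep = ":")
    f <- fractions[key, tissues]
    for (cod in strsplit(sites$codons[i], ",", fixed = TRUE)[[1]]) {
      pr <- pearson_r(f, e_codon[cod, tissues])
      rows[[length(rows) + 1L]] <- data.frame(
        trna_id = sites$trna_id[i], position = sites$position[i],
        region = sites$region_label[i], codon = cod,
        r = pr$r, p = pr$p, n = pr$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Sign odds ratio with a one-tailed binomial test
#'
#' `OR = n_pos / n_neg` over the signs of a set of correlation coefficients
#' (exact zeros excluded); the P value is `P(X >= n_pos)` for
#' `X ~ Binomial(n_pos + n_neg, 0.5)`, the one-tailed test that positives
#' outnumber negatives.
#'
#' @param r numeric vector of correlation coefficients (`NA`s dropped).
#' @return list `or` (`Inf` when `n_neg == 0`), `p`, `n_pos`, `n_neg`,
#'   `n_zero`.
#' @export
sign_odds_ratio <- function(r) {
  r <- r[!is.na(r)]
  .assert(length(r) >= 1L, "need at least one correlation")
  n_pos <- sum(r > 0); n_neg <- sum(r < 0); n_zero <- sum(r == 0)
  or <- if (n_neg == 0) Inf else n_pos / n_neg
  p <- stats::pbinom(n_pos - 1L, n_pos + n_neg, 0.5, lower.tail = FALSE)
  list(or = or, p = p, n_pos = n_pos, n_neg = n_neg, n_zero = n_zero)
}

#' One-tailed Wilcoxon rank-sum test
#'
#' Exact null distribution (via the Mann-Whitney U distribution) when the
#' pooled sample is small (`n_a + n_b <= exact_limit`) and tie-free; a
#' tie-corrected normal approximation with continuity correction otherwise.
#'
#' @param a,b numeric samples.
#' @param alternative `"less"` (a shifted below b) or `"greater"`.
#' @param exact_limit largest pooled size for the exact path (default 12).
#' @return one-tailed P value.
#' @export
wilcoxon_one_tailed <- function(a, b, alternative = c("less", "greater"),
                                exact_limit = 12L) {
  alternative <- match.arg(alternative)
  .assert(length(a) >= 1L && length(b) >= 1L, "both samples must be non-empty")
  na <- length(a); nb <- length(b); N <- na + nb
  rk <- rank(c(a, b))
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (!ties && N <= exact_limit) {
    if (alternative == "less") {
      stats::pwilcox(U, na, nb)
    } else {
      stats::pwilcox(U - 1, na, nb, lower.tail = FALSE)
    }
  } else {
    tie_tab <- table(rk)
    mu <- na * nb / 2
    sigma <- sqrt((na * nb / 12) *
                    ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1))))
    if (alternative == "less") {
      stats::pnorm((U - mu + 0.5) / sigma)
    } else {
      stats::pnorm((U - mu - 0.5) / sigma, lower.tail = FALSE)
    }
  }
}

# shared machinery for ordered quantile-group comparisons
.group_compare <- function(value, outcome, id, k, direction) {
  grp <- .quantile_groups(value, id, k)
  nonempty <- sum(tabulate(grp, k) > 0)
  .assert(nonempty >= 2L, "fewer than 2 non-empty groups")
  summaries <- do.call(rbind, lapply(seq_len(k), function(g) {
    v <- outcome[grp == g]
    data.frame(group = g, n = length(v), median = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)))
  }))
  pairs <- utils::combn(seq_len(k), 2)
  contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    lo <- pairs[1, j]; hi <- pairs[2, j]
    # direction "decreasing": outcome in the higher-Psi group shifted below
    p <- wilcoxon_one_tailed(outcome[grp == hi], outcome[grp == lo],
                             alternative = if (direction == "decreasing")
                               "less" else "greater")
    data.frame(group_low = lo, group_high = hi, p = p)
  }))
  contrasts$p_adj <- stats::p.adjust(contrasts$p, method = "BH")
  list(groups = grp, summary = summaries, contrasts = contrasts)
}

#' Lifetime distributions across Psi-fraction quantile groups
#'
#' Splits transcripts into `k` equal-sized groups by summed Psi fraction and
#' compares lifetime distributions between groups with one-tailed Wilcoxon
#' rank-sum tests (default direction: higher Psi, shorter lifetime).
#' Benjamini-Hochberg adjusted P values accompany the raw one-tailed ones.
#'
#' @param summed_fractions data frame `transcript_id, summed_fraction`.
#' @param lifetimes data frame `transcript_id, lifetime_h`.
#' @param k number of quantile groups (default 4).
#' @param direction `"decreasing"` (lifetime falls with Psi) or
#'   `"increasing"`.
#' @return list `summary` (per-group n/median/IQR), `contrasts` (pairwise
#'   one-tailed P), `data` (merged table with group assignment).
#' @export
lifetime_group_analysis <- function(summed_fractions, lifetimes, k = 4L,
                                    direction = c("decreasing", "increasing")) {
  direction <- match.arg(direction)
  m <- merge(summed_fractions, lifetimes[, c("transcript_id", "lifetime_h")],
             by = "transcript_id")
  .assert(nrow(m) >= 2L * k, "too few matched transcripts")
  res <- .group_compare(m$summed_fraction, m$lifetime_h, m$transcript_id,
                        k, direction)
  m$group <- res$groups
  list(summary = res$summary, contrasts = res$contrasts, data = m)
}

#' Translation efficiency across Psi-fraction groups
#'
#' Tertile grouping (low/medium/high summed Psi fraction) with one-tailed
#' Wilcoxon comparisons of E_transcript (default direction: TE rises with
#' Psi). With `strata` given (e.g. the gene region carrying a transcript's
#' sites), groups are the strata labels instead and all pairwise one-tailed
#' comparisons are reported.
#'
#' @param summed_fractions data frame `transcript_id, summed_fraction`.
#' @param e_transcript named vector of transcript-level TE.
#' @param k number of fraction groups (default 3: low/medium/high).
#' @param direction `"increasing"` or `"decreasing"`.
#' @param strata optional named character vector (transcript id -> stratum).
#' @return as [lifetime_group_analysis()]; group labels are `low < ... <
#'   high` fraction tertiles or the sorted strata labels.
#' @export
te_group_analysis <- function(summed_fractions, e_transcript, k = 3L,
                              direction = c("increasing", "decreasing"),
                              strata = NULL) {
  direction <- match.arg(direction)
  ids <- intersect(summed_fractions$transcript_id, names(e_transcript))
  sf <- summed_fractions[match(ids, summed_fractions$transcript_id), ]
  te <- e_transcript[ids]
  if (is.null(strata)) {
    res <- .group_compare(sf$summed_fraction, te, ids, k, direction)
    lab <- if (k == 3L) c("low", "medium", "high") else as.character(seq_len(k))
    res$summary$label <- lab[res$summary$group]
    out <- data.frame(transcript_id = ids, summed_fraction = sf$summed_fraction,
                      e_transcript = unname(te), group = res$groups,
                      label = lab[res$groups], stringsAsFactors = FALSE)
    list(summary = res$summary, contrasts = res$contrasts, data = out)
  } else {
    st <- strata[ids]
    keep <- !is.na(st)
    te <- te[keep]; st <- st[keep]; ids <- ids[keep]
    labs <- sort(unique(st))
    .assert(length(labs) >= 2L, "need >= 2 strata")
    summaries <- do.call(rbind, lapply(labs, function(l) {
      v <- te[st == l]
      data.frame(label = l, n = length(v), median = stats::median(v),
                 q25 = unname(stats::quantile(v, 0.25)),
                 q75 = unname(stats::quantile(v, 0.75)))
    }))
    pairs <- utils::combn(labs, 2)
    contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- te[st == pairs[1, j]]; b <- te[st == pairs[2, j]]
      data.frame(stratum_a = pairs[1, j], stratum_b = pairs[2, j],
                 p_a_less = wilcoxon_one_tailed(a, b, "less"),
                 p_a_greater = wilcoxon_one_tailed(a, b, "greater"),
                 stringsAsFactors = FALSE)
    }))
    out <- data.frame(transcript_id = ids, e_transcript = unname(te),
                      label = st, stringsAsFactors = FALSE)
    list(summary = summaries, contrasts = contrasts, data = out)
  }
}
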