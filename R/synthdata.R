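# Synthetic-data generation with planted ground truth.
#
# Every pipeline input can be produced here: a toy transcriptome (5'-UTR /
# CDS / 3'-UTR, optional introns), planted Psi sites with per-tissue
# stoichiometries, BID-seq pileups with background deletions, ribosome
# footprints shaped by per-codon dwell times, RNA abundance, and mRNA
# lifetimes with a planted (negative) dependence on summed Psi fraction.
# All draws descend from one seed through named streams, so adding a tissue
# or replicate never perturbs the ones already generated.

#' Simulation configuration
#'
#' Collects every knob of the synthetic generator. Defaults emulate a small
#' multi-tissue BID-seq experiment: nine tissues, two replicates, mean site
#' depth 1000 with negative-binomial spread, 1% background deletions, and a
#' planted stoichiometry distribution with roughly 70% of fractions below
#' 0.2 plus a high-stoichiometry minority (a two-component Beta mixture).
#'
#' @param n_genes number of transcripts.
#' @param utr5_len_range,cds_len_range,utr3_len_range inclusive nucleotide
#'   length ranges; CDS lengths are rounded to multiples of 3 within range.
#' @param n_intron_range,intron_len_range intron count and length ranges
#'   (introns are retained in the pre-mRNA reference the pileups live on).
#' @param n_tissues,n_replicates experiment layout (`n_replicates >= 1`).
#' @param psi_site_rate probability that a U position carries a planted site.
#' @param n_psi_sites if non-`NULL`, plant exactly this many sites instead.
#' @param share_all_tissues share of planted sites present in all tissues;
#'   the remainder are tissue-unique.
#' @param fraction_mix parameters `w, a1, b1, a2, b2` of the planted-fraction
#'   mixture `w * Beta(a1, b1) + (1 - w) * Beta(a2, b2)`.
#' @param tissue_fraction_sd logit-scale spread of per-tissue stoichiometry
#'   around a site's base fraction (0 = identical across tissues).
#' @param background_deletion_rate per-read background deletion probability.
#' @param depth_mean,depth_dispersion negative-binomial depth model
#'   (`dispersion` is the NB size; larger = tighter).
#' @param calibration the [calibration_curve()] whose inverse shapes the
#'   simulated gap probabilities.
#' @param footprint_mean_coverage mean P-site reads per codon per gene.
#' @param dwell_noise_sd lognormal sd of per-codon coverage noise.
#' @param psite_offset nucleotides from a footprint 5' end to its P-site.
#' @param te_effect planted slope of log-TE on a transcript's summed Psi
#'   fraction (positive plants the Psi-promotes-translation direction).
#' @param te_noise_sd lognormal sd of transcript TE around the planted trend.
#' @param lifetime_effect planted slope of log-lifetime on summed Psi
#'   fraction (negative plants the destabilising direction).
#' @param lifetime_noise_sd,lifetime_baseline log-normal noise sd and
#'   baseline lifetime in hours.
#' @param seed integer master seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50L,
                       utr5_len_range = c(20L, 100L),
                       cds_len_range = c(120L, 600L),
                       utr3_len_range = c(30L, 150L),
                       n_intron_range = c(0L, 2L),
                       intron_len_range = c(50L, 150L),
                       n_tissues = 9L,
                       n_replicates = 2L,
                       psi_site_rate = 0.02,
                       n_psi_sites = NULL,
                       share_all_tissues = 0.5,
                       fraction_mix = list(w = 0.75, a1 = 1.2, b1 = 15,
                                           a2 = 5, b2 = 2.5),
                       tissue_fraction_sd = 0.3,
                       background_deletion_rate = 0.01,
                       depth_mean = 1000,
                       depth_dispersion = 10,
                       calibration = identity_curve(),
                       footprint_mean_coverage = 20,
                       dwell_noise_sd = 0.1,
                       psite_offset = 12L,
                       te_effect = 0.5,
                       te_noise_sd = 0.3,
                       lifetime_effect = -0.5,
                       lifetime_noise_sd = 0.3,
                       lifetime_baseline = 6,
                       seed = 1L) {
  rng <- function(r, what) {
    .assert(length(r) == 2L && r[1] <= r[2] && r[1] >= 0,
            paste0(what, " must be a non-empty non-negative range"))
  }
  rng(utr5_len_range, "utr5_len_range"); rng(cds_len_range, "cds_len_range")
  rng(utr3_len_range, "utr3_len_range"); rng(n_intron_range, "n_intron_range")
  rng(intron_len_range, "intron_len_range")
  .assert(cds_len_range[1] >= 9, "cds_len_range must allow start + stop codons")
  .assert(.is_prob(psi_site_rate), "psi_site_rate must lie in [0, 1]")
  .assert(.is_prob(share_all_tissues), "share_all_tissues must lie in [0, 1]")
  .assert(.is_prob(background_deletion_rate),
          "background_deletion_rate must lie in [0, 1]")
  .assert(n_replicates >= 1L, "n_replicates must be >= 1")
  .assert(n_tissues >= 1L, "n_tissues must be >= 1")
  .assert(dwell_noise_sd >= 0, "dwell_noise_sd must be non-negative")
  .assert(inherits(calibration, "calibration_curve"),
          "calibration must be a calibration_curve")
  structure(as.list(environment())[setdiff(names(formals(sim_config)), "")],
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic Psi experiment configuration\n")
  cat("  genes:", x$n_genes, " tissues:", x$n_tissues,
      " replicates:", x$n_replicates, "\n")
  cat("  depth ~ NB(mu =", x$depth_mean, ", size =", x$depth_dispersion,
      ")  background deletions:", x$background_deletion_rate, "\n")
  cat("  planted effects: TE", x$te_effect, " lifetime", x$lifetime_effect, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic transcriptome
#'
#' Each transcript has a 5'-UTR, a CDS that starts with ATG, contains only
#' sense codons and ends with a stop codon, and a 3'-UTR; optional GT..AG
#' introns are inserted between mature positions. The reference the pipeline
#' sees is the pre-mRNA (introns retained), with exon intervals recorded so
#' positions can be mapped to mature coordinates.
#'
#' @param config a [sim_config()].
#' @return an object of class `transcript_models`: a list with `transcripts`
#'   (per-transcript lengths), `exons` (1-based inclusive pre-mRNA intervals)
#'   and `sequences` (named pre-mRNA character vector).
#' @export
make_transcriptome <- function(config) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  ct <- .codon_table()
  .with_stream(config$seed, "transcriptome", expr = {
    n <- config$n_genes
    ids <- sprintf("TX%04d", seq_len(n))
    u5 <- .sample_range(config$utr5_len_range[1], config$utr5_len_range[2], n)
    u3 <- .sample_range(config$utr3_len_range[1], config$utr3_len_range[2], n)
    ncodon <- .sample_range(config$cds_len_range[1] %/% 3,
                            config$cds_len_range[2] %/% 3, n)
    sense_mid <- ct$sense  # internal ATG (methionine) codons are allowed
    tx_rows <- vector("list", n)
    exon_rows <- vector("list", n)
    seqs <- character(n)
    for (i in seq_len(n)) {
      rnt <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                                 collapse = "")
      cds <- paste0("ATG",
                    paste(sample(sense_mid, ncodon[i] - 2L, TRUE), collapse = ""),
                    sample(ct$stop, 1L))
      mature <- paste0(rnt(u5[i]), cds, rnt(u3[i]))
      mlen <- nchar(mature)
      n_intr <- .sample_range(config$n_intron_range[1],
                              config$n_intron_range[2], 1L)
      if (n_intr > 0L) {
        # insertion points between mature positions (never before position 1)
        at <- sort(sample(seq_len(mlen - 1L), n_intr))
        ilens <- .sample_range(config$intron_len_range[1],
                               config$intron_len_range[2], n_intr)
        introns <- vapply(ilens, function(L) {
          paste0("GT", if (L > 4) rnt(L - 4L) else "", "AG")
        }, character(1))
        pieces <- character(0)
        prev <- 1L
        for (j in seq_len(n_intr)) {
          pieces <- c(pieces, substr(mature, prev, at[j]), introns[j])
          prev <- at[j] + 1L
        }
        pieces <- c(pieces, substr(mature, prev, mlen))
        pre <- paste(pieces, collapse = "")
        # exon intervals in pre-mRNA coordinates
        ex_start <- integer(n_intr + 1L); ex_end <- integer(n_intr + 1L)
        shift <- 0L; prev <- 1L
        for (j in seq_len(n_intr)) {
          ex_start[j] <- prev + shift
          ex_end[j] <- at[j] + shift
          shift <- shift + nchar(introns[j])
          prev <- at[j] + 1L
        }
        ex_start[n_intr + 1L] <- prev + shift
        ex_end[n_intr + 1L] <- mlen + shift
      } else {
        pre <- mature
        ex_start <- 1L; ex_end <- mlen
      }
      seqs[i] <- pre
      tx_rows[[i]] <- data.frame(
        transcript_id = ids[i], gene_id = sub("TX", "G", ids[i]),
        strand = "+", utr5_len = u5[i], cds_len = 3L * ncodon[i],
        utr3_len = u3[i], mature_len = mlen, premrna_len = nchar(pre),
        stringsAsFactors = FALSE)
      exon_rows[[i]] <- data.frame(transcript_id = ids[i],
                                   start = ex_start, end = ex_end,
                                   stringsAsFactors = FALSE)
    }
    names(seqs) <- ids
    structure(list(transcripts = do.call(rbind, tx_rows),
                   exons = do.call(rbind, exon_rows),
                   sequences = seqs),
              class = "transcript_models")
  })
}

#' @export
print.transcript_models <- function(x, ...) {
  cat("Synthetic transcriptome:", nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons\n")
  cat("  mature length:", min(x$transcripts$mature_len), "-",
      max(x$transcripts$mature_len), "nt;",
      sum(x$transcripts$premrna_len - x$transcripts$mature_len),
      "intronic nt total\n")
  invisible(x)
}

#' Map a pre-mRNA position to its mature (spliced) coordinate
#'
#' @param models a `transcript_models` object.
#' @param transcript_id transcript identifier.
#' @param pos 1-based pre-mRNA positions.
#' @return 1-based mature coordinates, `NA` for intronic positions.
#' @export
premrna_to_mature <- function(models, transcript_id, pos) {
  ex <- models$exons[models$exons$transcript_id == transcript_id, , drop = FALSE]
  cum <- cumsum(c(0L, ex$end - ex$start + 1L))
  out <- rep(NA_integer_, length(pos))
  for (j in seq_len(nrow(ex))) {
    hit <- pos >= ex$start[j] & pos <= ex$end[j]
    out[hit] <- cum[j] + (pos[hit] - ex$start[j] + 1L)
  }
  out
}

#' Mature (spliced) sequences of a synthetic transcriptome
#' @param models a `transcript_models` object.
#' @return named character vector of spliced sequences.
#' @export
mature_sequences <- function(models) {
  vapply(names(models$sequences), function(id) {
    ex <- models$exons[models$exons$transcript_id == id, , drop = FALSE]
    paste(substring(models$sequences[[id]], ex$start, ex$end), collapse = "")
  }, character(1))
}

# logit-normal jitter of a base fraction, clamped away from {0, 1}
.jitter_fraction <- function(base, sd, n) {
  if (sd == 0) return(rep(base, n))
  b <- .clamp(base, 1e-4, 1 - 1e-4)
  stats::plogis(stats::qlogis(b) + stats::rnorm(n, 0, sd))
}

#' Plant Psi sites with per-tissue stoichiometries
#'
#' Psi positions are sampled from the U (T in DNA alphabet) positions of the
#' pre-mRNA references. A configurable share of sites is present in every
#' tissue; the remainder are tissue-unique. Each site draws a base fraction
#' from the configured Beta mixture, then per-tissue fractions jitter around
#' it on the logit scale.
#'
#' @param models a `transcript_models` object from [make_transcriptome()].
#' @param config the same [sim_config()].
#' @return a `psi_truth` data frame: one row per (tissue, transcript,
#'   position) with `true_fraction`, the site's `base_fraction` and its
#'   `sharing` label (`shared_all` or `unique`).
#' @export
plant_psi_sites <- function(models, config) {
  .assert(inherits(models, "transcript_models"), "models must be transcript_models")
  .with_stream(config$seed, "truth", expr = {
    upos <- lapply(models$sequences, .t_positions)
    all_sites <- data.frame(
      transcript_id = rep(names(upos), lengths(upos)),
      pos = unlist(upos, use.names = FALSE), stringsAsFactors = FALSE)
    if (nrow(all_sites) == 0L || config$psi_site_rate == 0 &&
        is.null(config$n_psi_sites)) {
      return(.empty_truth())
    }
    n_take <- if (!is.null(config$n_psi_sites)) {
      min(config$n_psi_sites, nrow(all_sites))
    } else {
      stats::rbinom(1L, nrow(all_sites), config$psi_site_rate)
    }
    if (n_take == 0L) return(.empty_truth())
    sel <- all_sites[sort(sample.int(nrow(all_sites), n_take)), , drop = FALSE]
    mx <- config$fraction_mix
    comp <- stats::runif(n_take) < mx$w
    base <- ifelse(comp, stats::rbeta(n_take, mx$a1, mx$b1),
                   stats::rbeta(n_take, mx$a2, mx$b2))
    shared <- stats::runif(n_take) < config$share_all_tissues
    home <- sample.int(config$n_tissues, n_take, TRUE)
    tissues <- .tissue_names(config$n_tissues)
    rows <- vector("list", n_take)
    for (i in seq_len(n_take)) {
      tis <- if (shared[i]) tissues else tissues[home[i]]
      fr <- .clamp(.jitter_fraction(base[i], config$tissue_fraction_sd,
                                    length(tis)), 0, 1)
      rows[[i]] <- data.frame(
        tissue = tis, transcript_id = sel$transcript_id[i], pos = sel$pos[i],
        true_fraction = fr, base_fraction = base[i],
        sharing = if (shared[i]) "shared_all" else "unique",
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("psi_truth", "data.frame")
    out
  })
}

.empty_truth <- function() {
  out <- data.frame(tissue = character(0), transcript_id = character(0),
                    pos = integer(0), true_fraction = numeric(0),
                    base_fraction = numeric(0), sharing = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("psi_truth", "data.frame")
  out
}

.tissue_names <- function(n) sprintf("tissue%02d", seq_len(n))

#' Simulate BID-seq pileups for every tissue and replicate
#'
#' Per position, depth is negative-binomial; the deletion count is
#' `Binomial(depth, p)` with `p` equal to the background rate at unmodified
#' positions and to `g(f) + background` at a planted site with fraction `f`,
#' where `g` is the inverse of the configured calibration curve. Every
#' (tissue, replicate) pair draws from its own named random stream.
#'
#' @param truth a `psi_truth` table from [plant_psi_sites()].
#' @param models the `transcript_models`.
#' @param config the [sim_config()].
#' @param tissues optional subset of tissue labels to simulate.
#' @return nested list `pileups[[tissue]][[replicate]]` of pileup data frames.
#' @export
simulate_bidseq_pileup <- function(truth, models, config, tissues = NULL) {
  tissues <- tissues %||% .tissue_names(config$n_tissues)
  lens <- nchar(models$sequences)
  ref_id <- rep(names(lens), lens)
  pos <- unlist(lapply(lens, seq_len), use.names = FALSE)
  npos <- length(pos)
  site_key <- paste(ref_id, pos)
  out <- vector("list", length(tissues))
  names(out) <- tissues
  for (tis in tissues) {
    tt <- truth[truth$tissue == tis, , drop = FALSE]
    p_del <- rep(config$background_deletion_rate, npos)
    if (nrow(tt)) {
      idx <- match(paste(tt$transcript_id, tt$pos), site_key)
      gap <- .uncalibrate_fraction(tt$true_fraction, config$calibration)
      p_del[idx] <- .clamp(gap + config$background_deletion_rate, 0, 1)
    }
    reps <- vector("list", config$n_replicates)
    for (r in seq_len(config$n_replicates)) {
      reps[[r]] <- .with_stream(config$seed, "pileup", tis, r, expr = {
        depth <- stats::rnbinom(npos, mu = config$depth_mean,
                                size = config$depth_dispersion)
        del <- stats::rbinom(npos, depth, p_del)
        data.frame(ref_id = ref_id, pos = pos, strand = "+",
                   total_reads = depth, deletion_reads = del,
                   stringsAsFactors = FALSE)
      })
    }
    names(reps) <- paste0("rep", seq_len(config$n_replicates))
    out[[tis]] <- reps
  }
  out
}

#' Simulate ribosome footprints and RNA abundance
#'
#' Plants a per-codon dwell time (log2-uniform on `[0.5, 2]`), a per-transcript
#' translation efficiency whose log responds to the transcript's summed Psi
#' fraction with slope `te_effect`, and an RNA abundance; expected P-site
#' counts per codon are proportional to `dwell * TE * abundance` with
#' lognormal noise of sd `dwell_noise_sd`. Footprint reads are emitted in
#' mature-transcript coordinates with lengths 29-35 nt (plus a small
#' out-of-range junk share to exercise length filtering).
#'
#' @param models the `transcript_models`.
#' @param truth a `psi_truth` table (summed fractions drive the TE trend).
#' @param config the [sim_config()].
#' @param tissue tissue label used for the random stream and TE jitter.
#' @return a list with `reads` (transcript_id, start, length), `rna`
#'   (transcript_id, count, length), and `truth` (per-codon `dwell`, per
#'   transcript `te`, `rna_tpm`, `summed_fraction`).
#' @export
simulate_footprints <- function(models, truth, config, tissue = "tissue01") {
  tx <- models$transcripts
  ct <- .codon_table()
  sf <- summed_fraction_by_transcript_truth(truth)
  s <- sf$summed_fraction[match(tx$transcript_id, sf$transcript_id)]
  s[is.na(s)] <- 0
  .with_stream(config$seed, "footprints", tissue, expr = {
    dwell <- 2 ^ stats::runif(length(ct$sense), -1, 1)
    names(dwell) <- ct$sense
    te <- exp(log(2) + config$te_effect * s +
                stats::rnorm(nrow(tx), 0, config$te_noise_sd))
    rna_w <- stats::rlnorm(nrow(tx), meanlog = 3, sdlog = 0.8)
    rna_tpm <- 1e6 * (rna_w / tx$mature_len) / sum(rna_w / tx$mature_len)
    mseq <- mature_sequences(models)
    reads <- vector("list", nrow(tx))
    for (i in seq_len(nrow(tx))) {
      ncod <- tx$cds_len[i] %/% 3L
      starts_nt <- tx$utr5_len[i] + 3L * (seq_len(ncod) - 1L) + 1L
      codons <- substring(mseq[[tx$transcript_id[i]]], starts_nt, starts_nt + 2L)
      d <- dwell[codons]
      d[is.na(d)] <- 1  # stop codon
      lam <- config$footprint_mean_coverage * (te[i] / 2) *
        (rna_w[i] / stats::median(rna_w)) * d *
        exp(stats::rnorm(ncod, 0, config$dwell_noise_sd))
      cnt <- stats::rpois(ncod, lam)
      tot <- sum(cnt)
      if (tot == 0L) next
      st <- rep(starts_nt - config$psite_offset, cnt)
      keep <- st >= 1L
      st <- st[keep]
      if (!length(st)) next
      reads[[i]] <- data.frame(
        transcript_id = tx$transcript_id[i], start = st,
        length = sample(29:35, length(st), TRUE), stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, reads)
    # junk reads outside the 29-35 nt window (degraded fragments)
    njunk <- max(1L, round(0.05 * nrow(reads)))
    junk_tx <- sample(tx$transcript_id, njunk, TRUE)
    junk_len <- sample(c(20:28, 36:45), njunk, TRUE)
    junk <- data.frame(
      transcript_id = junk_tx,
      start = pmax(1L, as.integer(stats::runif(njunk) *
                     (tx$mature_len[match(junk_tx, tx$transcript_id)] - 45L))),
      length = junk_len, stringsAsFactors = FALSE)
    reads <- rbind(reads, junk)
    rownames(reads) <- NULL
    rna_counts <- stats::rpois(nrow(tx), rna_w * 20)
    list(reads = reads,
         rna = data.frame(transcript_id = tx$transcript_id,
                          count = rna_counts, length = tx$mature_len,
                          stringsAsFactors = FALSE),
         truth = list(dwell = dwell, te = stats::setNames(te, tx$transcript_id),
                      rna_tpm = stats::setNames(rna_tpm, tx$transcript_id),
                      summed_fraction = stats::setNames(s, tx$transcript_id)))
  })
}

#' Tissue-averaged summed Psi fraction per transcript from a truth table
#' @param truth a `psi_truth` table.
#' @return data frame `transcript_id, summed_fraction` (sites averaged over
#'   the tissues they appear in, then summed within transcript).
#' @export
summed_fraction_by_transcript_truth <- function(truth) {
  if (nrow(truth) == 0L) {
    return(data.frame(transcript_id = character(0), summed_fraction = numeric(0)))
  }
  key <- paste(truth$transcript_id, truth$pos)
  site_mean <- tapply(truth$true_fraction, key, mean)
  site_tx <- truth$transcript_id[!duplicated(key)]
  names(site_tx) <- key[!duplicated(key)]
  agg <- tapply(as.numeric(site_mean), site_tx[names(site_mean)], sum)
  data.frame(transcript_id = names(agg), summed_fraction = as.numeric(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate mRNA lifetimes with a planted Psi dependence
#'
#' `log(lifetime) = log(baseline) + lifetime_effect * summed_fraction + noise`;
#' a negative effect plants the destabilising direction. Transcripts without
#' planted sites sit at the baseline.
#'
#' @param truth a `psi_truth` table.
#' @param config the [sim_config()].
#' @param models optional `transcript_models`; when given, transcripts without
#'   sites are included at summed fraction 0.
#' @return data frame `transcript_id, summed_fraction, lifetime_h`.
#' @export
simulate_lifetimes <- function(truth, config, models = NULL) {
  sf <- summed_fraction_by_transcript_truth(truth)
  if (!is.null(models)) {
    missing <- setdiff(models$transcripts$transcript_id, sf$transcript_id)
    if (length(missing)) {
      sf <- rbind(sf, data.frame(transcript_id = missing, summed_fraction = 0))
    }
    sf <- sf[order(sf$transcript_id), , drop = FALSE]
  }
  .with_stream(config$seed, "lifetimes", expr = {
    noise <- stats::rnorm(nrow(sf), 0, config$lifetime_noise_sd)
    lt <- exp(log(config$lifetime_baseline) +
                config$lifetime_effect * sf$summed_fraction + noise)
    data.frame(transcript_id = sf$transcript_id,
               summed_fraction = sf$summed_fraction,
               lifetime_h = lt, stringsAsFactors = FALSE, row.names = NULL)
  })
}
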