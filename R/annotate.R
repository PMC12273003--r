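# Region assignment, metagene / density profiles and tissue-sharing labels.
#
# Sites live on pre-mRNA references. Two classification schemes are reported:
# the transcript-structure scheme (5UTR / CDS / 3UTR for exonic positions,
# intron otherwise) and the coarse exon/intron scheme, mirroring how sites
# are stratified by gene region in downstream stability and TE analyses.

#' Assign a site to a gene region
#'
#' @param ref_id,pos site coordinates (pre-mRNA reference id, 1-based).
#' @param models a `transcript_models` object.
#' @return data frame with `region` (`5UTR`, `CDS`, `3UTR`, `intron` or
#'   `intergenic`), `scheme2` (`exon`, `intron`, `intergenic`) and the mature
#'   coordinate (`NA` for intronic/intergenic positions).
#' @export
assign_region <- function(ref_id, pos, models) {
  .assert(length(ref_id) == length(pos), "ref_id and pos lengths differ")
  tx <- models$transcripts
  region <- character(length(pos))
  scheme2 <- character(length(pos))
  mature_pos <- rep(NA_integer_, length(pos))
  for (id in unique(ref_id)) {
    sel <- which(ref_id == id)
    row <- match(id, tx$transcript_id)
    if (is.na(row)) {
      region[sel] <- "intergenic"; scheme2[sel] <- "intergenic"
      next
    }
    inside <- pos[sel] >= 1L & pos[sel] <= tx$premrna_len[row]
    region[sel][!inside] <- "intergenic"; scheme2[sel][!inside] <- "intergenic"
    mp <- premrna_to_mature(models, id, pos[sel][inside])
    mature_pos[sel][inside] <- mp
    intronic <- is.na(mp)
    r <- character(length(mp))
    r[intronic] <- "intron"
    u5 <- tx$utr5_len[row]; cds <- tx$cds_len[row]
    ex <- !intronic
    r[ex & mp <= u5] <- "5UTR"
    r[ex & mp > u5 & mp <= u5 + cds] <- "CDS"
    r[ex & mp > u5 + cds] <- "3UTR"
    region[sel][inside] <- r
    scheme2[sel][inside] <- ifelse(intronic, "intron", "exon")
  }
  data.frame(ref_id = ref_id, pos = pos, region = region, scheme2 = scheme2,
             mature_pos = mature_pos, stringsAsFactors = FALSE)
}

#' Metagene profile of site positions
#'
#' Maps each exonic site to its relative position within its region (5UTR,
#' CDS or 3UTR of the mature transcript) and bins the three regions onto a
#' common axis of `bins_per_region` bins each, displayed at equal width.
#' Densities sum to 1 over all bins when any site maps.
#'
#' @param sites a `PsiSite` data frame (`ref_id`, `pos`).
#' @param models a `transcript_models` object.
#' @param bins_per_region bins per region (default 30).
#' @return data frame `region, bin, axis_bin, count, density`.
#' @export
metagene_profile <- function(sites, models, bins_per_region = 30L) {
  regions <- c("5UTR", "CDS", "3UTR")
  grid <- expand.grid(bin = seq_len(bins_per_region), region = regions,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$region, regions), grid$bin), ]
  grid$axis_bin <- seq_len(nrow(grid))
  grid$count <- 0L
  if (nrow(sites)) {
    asg <- assign_region(sites$ref_id, sites$pos, models)
    tx <- models$transcripts
    row <- match(asg$ref_id, tx$transcript_id)
    keep <- asg$region %in% regions
    rel <- numeric(sum(keep))
    a <- asg[keep, , drop = FALSE]; row <- row[keep]
    u5 <- tx$utr5_len[row]; cds <- tx$cds_len[row]; u3 <- tx$utr3_len[row]
    rel <- ifelse(a$region == "5UTR", (a$mature_pos - 0.5) / u5,
           ifelse(a$region == "CDS", (a$mature_pos - u5 - 0.5) / cds,
                  (a$mature_pos - u5 - cds - 0.5) / u3))
    bin <- pmin(bins_per_region, 1L + floor(rel * bins_per_region))
    key <- paste(a$region, bin)
    tab <- table(key)
    idx <- match(names(tab), paste(grid$region, grid$bin))
    grid$count[idx] <- as.integer(tab)
  }
  total <- sum(grid$count)
  grid$density <- if (total > 0) grid$count / total else 0
  rownames(grid) <- NULL
  grid[, c("region", "bin", "axis_bin", "count", "density")]
}

#' Psi density per gene region
#'
#' Sites per nucleotide for each region, normalising counts by the total
#' length of that region across the supplied transcript models.
#'
#' @param sites a `PsiSite` data frame.
#' @param models a `transcript_models` object.
#' @return data frame `region, n_sites, total_nt, density`; regions with zero
#'   total length are omitted with a warning.
#' @export
region_density <- function(sites, models) {
  tx <- models$transcripts
  lens <- c(`5UTR` = sum(tx$utr5_len), CDS = sum(tx$cds_len),
            `3UTR` = sum(tx$utr3_len),
            intron = sum(tx$premrna_len - tx$mature_len))
  counts <- stats::setNames(rep(0L, length(lens)), names(lens))
  if (nrow(sites)) {
    asg <- assign_region(sites$ref_id, sites$pos, models)
    tab <- table(asg$region)
    hit <- intersect(names(tab), names(counts))
    counts[hit] <- as.integer(tab[hit])
  }
  zero <- lens == 0
  if (any(zero & counts > 0)) {
    warning("sites found in zero-length regions: ",
            paste(names(lens)[zero & counts > 0], collapse = ", "))
  }
  if (any(zero)) {
    warning("omitting zero-length region(s): ",
            paste(names(lens)[zero], collapse = ", "))
  }
  out <- data.frame(region = names(lens), n_sites = as.integer(counts),
                    total_nt = as.integer(lens), stringsAsFactors = FALSE)
  out <- out[!zero, , drop = FALSE]
  out$density <- out$n_sites / out$total_nt
  rownames(out) <- NULL
  out
}

#' Build a tissue-by-site stoichiometry matrix
#'
#' @param site_list named list of `PsiSite` data frames, one per tissue.
#' @return numeric matrix, rows `ref_id:pos:strand`, columns tissues, entries
#'   Psi fraction (`NA` where a site was not called in that tissue).
#' @export
tissue_site_matrix <- function(site_list) {
  .assert(is.list(site_list) && !is.null(names(site_list)),
          "site_list must be a named list of PsiSite tables")
  keys <- unique(unlist(lapply(site_list, function(s) {
    paste(s$ref_id, s$pos, s$strand, sep = ":")
  })))
  m <- matrix(NA_real_, nrow = length(keys), ncol = length(site_list),
              dimnames = list(keys, names(site_list)))
  for (tis in names(site_list)) {
    s <- site_list[[tis]]
    if (nrow(s)) {
      m[paste(s$ref_id, s$pos, s$strand, sep = ":"), tis] <- s$fraction
    }
  }
  m
}

#' Classify sites by tissue sharing
#'
#' A site called in every tissue is `shared_all`; called in exactly one is
#' `unique:<tissue>`; anything in between is `partial`. Labels partition the
#' site rows.
#'
#' @param mat a tissue-by-site matrix from [tissue_site_matrix()] (`NA` =
#'   not called).
#' @return list with `labels` (per-site data frame) and `counts` (named
#'   totals over `shared_all`, `unique`, `partial`).
#' @export
classify_tissue_sharing <- function(mat) {
  .assert(is.matrix(mat) && ncol(mat) >= 2L, "need a matrix with >= 2 tissues")
  called <- !is.na(mat)
  n_called <- rowSums(called)
  lab <- character(nrow(mat))
  lab[n_called == ncol(mat)] <- "shared_all"
  uniq <- n_called == 1L
  if (any(uniq)) {
    which_tis <- colnames(mat)[apply(called[uniq, , drop = FALSE], 1L, which)]
    lab[uniq] <- paste0("unique:", which_tis)
  }
  lab[n_called > 1L & n_called < ncol(mat)] <- "partial"
  labels <- data.frame(site = rownames(mat), n_tissues = n_called,
                       label = lab, stringsAsFactors = FALSE, row.names = NULL)
  counts <- c(shared_all = sum(lab == "shared_all"),
              unique = sum(startsWith(lab, "unique:")),
              partial = sum(lab == "partial"))
  list(labels = labels, counts = counts)
}

#' Summed Psi fraction per transcript
#'
#' The per-transcript sum of called-site fractions, the covariate used to
#' group transcripts for lifetime and TE comparisons. Transcripts without
#' sites are excluded.
#'
#' @param sites a `PsiSite` data frame whose `ref_id` is a transcript id.
#' @return data frame `transcript_id, n_sites, summed_fraction`.
#' @export
summed_fraction_per_transcript <- function(sites) {
  if (nrow(sites) == 0L) {
    return(data.frame(transcript_id = character(0), n_sites = integer(0),
                      summed_fraction = numeric(0)))
  }
  s <- tapply(sites$fraction, sites$ref_id, sum)
  n <- tapply(sites$fraction, sites$ref_id, length)
  data.frame(transcript_id = names(s), n_sites = as.integer(n[names(s)]),
             summed_fraction = as.numeric(s), stringsAsFactors = FALSE,
             row.names = NULL)
}
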