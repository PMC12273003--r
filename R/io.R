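# Readers and writers for the pipeline's plain-text formats.
#
# Conventions: all TSV coordinates are 1-based inclusive (rRNA site names
# such as Pt-23S:2702 are 1-based); BED6 / bedGraph exports are 0-based
# half-open. Every writer emits a header; every reader validates it.

.pileup_header <- c("ref_id", "pos_1based", "strand", "total_reads",
                    "deletion_reads")

#' Write a pileup table to TSV
#' @param pileup a pileup data frame (`pos` column is written as
#'   `pos_1based`).
#' @param path output file.
#' @export
write_pileup <- function(pileup, path) {
  out <- data.frame(ref_id = pileup$ref_id, pos_1based = pileup$pos,
                    strand = pileup$strand, total_reads = pileup$total_reads,
                    deletion_reads = pileup$deletion_reads)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pileup table from TSV
#'
#' Validates the header and every row; a line whose deletion count exceeds
#' its total count, or with a malformed field, raises an error naming the
#' line number (header = line 1).
#'
#' @param path pileup TSV path.
#' @return a pileup data frame with internal column names (`pos`).
#' @export
read_pileup <- function(path) {
  .assert(file.exists(path), paste0("no such file: ", path))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  .assert(identical(header, .pileup_header),
          paste0("unexpected pileup header in ", path, ": expected '",
                 paste(.pileup_header, collapse = "\t"), "'"))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "character",
                                         "character", "character"),
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(data.frame(ref_id = character(0), pos = integer(0),
                      strand = character(0), total_reads = integer(0),
                      deletion_reads = integer(0), stringsAsFactors = FALSE))
  }
  num <- function(x) suppressWarnings(as.integer(x))
  pos <- num(df$pos_1based); tot <- num(df$total_reads)
  del <- num(df$deletion_reads)
  bad <- which(is.na(pos) | is.na(tot) | is.na(del) | pos < 1 |
               !(df$strand %in% c("+", "-")))
  if (length(bad)) {
    stop("malformed pileup line ", bad[1] + 1L, " in ", path, call. = FALSE)
  }
  over <- which(del > tot)
  if (length(over)) {
    stop("pileup line ", over[1] + 1L, " in ", path,
         ": deletion_reads > total_reads", call. = FALSE)
  }
  data.frame(ref_id = df$ref_id, pos = pos, strand = df$strand,
             total_reads = tot, deletion_reads = del, stringsAsFactors = FALSE)
}

#' Write a called-site table to TSV
#' @param sites a `PsiSite` data frame.
#' @param path output file.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a called-site table from TSV
#' @param path site TSV path.
#' @return a `PsiSite` data frame.
#' @export
read_sites <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = list(motif3 = "character",
                                            motif5 = "character"))
  need <- c("ref_id", "pos", "strand", "depth", "del", "gap_ratio",
            "fraction", "p", "q", "motif3", "motif5", "tissue")
  miss <- setdiff(need, names(df))
  .assert(length(miss) == 0L,
          paste0("site table missing columns: ", paste(miss, collapse = ", ")))
  df
}

#' Export called sites as BED6
#'
#' 1-based inclusive internal coordinates become 0-based half-open; the BED
#' score is `round(1000 * fraction)`.
#'
#' @param sites a `PsiSite` data frame.
#' @param path output file.
#' @export
write_bed <- function(sites, path) {
  bed <- data.frame(chrom = sites$ref_id,
                    start = sites$pos - 1L, end = sites$pos,
                    name = paste0(sites$ref_id, ":", sites$pos),
                    score = as.integer(round(1000 * sites$fraction)),
                    strand = sites$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 site export back into coordinates
#' @param path BED6 path.
#' @return data frame `ref_id, pos, strand, fraction` (1-based inclusive).
#' @export
read_bed_sites <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  data.frame(ref_id = bed$V1, pos = bed$V2 + 1L, strand = bed$V6,
             fraction = bed$V5 / 1000, stringsAsFactors = FALSE)
}

#' Write reference sequences as FASTA
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write transcript annotation as the simple TSV dialect
#'
#' One row per region interval: `transcript_id, region, start, end`, 1-based
#' inclusive in pre-mRNA coordinates. Regions are `exon` intervals plus the
#' mature-space `5UTR`/`CDS`/`3UTR` segment lengths encoded as attributes of
#' a `structure` row.
#'
#' @param models a `transcript_models` object.
#' @param path output file.
#' @export
write_annotation <- function(models, path) {
  ex <- data.frame(transcript_id = models$exons$transcript_id,
                   region = "exon", start = models$exons$start,
                   end = models$exons$end)
  tx <- models$transcripts
  st <- data.frame(
    transcript_id = rep(tx$transcript_id, 3),
    region = rep(c("5UTR", "CDS", "3UTR"), each = nrow(tx)),
    start = c(rep(1L, nrow(tx)), tx$utr5_len + 1L,
              tx$utr5_len + tx$cds_len + 1L),
    end = c(tx$utr5_len, tx$utr5_len + tx$cds_len, tx$mature_len))
  out <- rbind(st, ex)
  out <- out[order(out$transcript_id, match(out$region,
                                            c("5UTR", "CDS", "3UTR", "exon")),
                   out$start), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GTF/GFF3 transcript structure into region tables
#'
#' Accepts features `five_prime_UTR`, `CDS`, `three_prime_UTR` and `exon`;
#' coordinates are taken as 1-based inclusive. Returns a plain region table
#' (not a full `transcript_models` object): downstream region assignment for
#' external annotations should use this table directly.
#'
#' @param path GTF or GFF3 path.
#' @return data frame `transcript_id, region, start, end, strand`.
#' @export
read_gff_regions <- function(path) {
  gff <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                           quote = "", stringsAsFactors = FALSE)
  .assert(ncol(gff) >= 9L, "not a 9-column GTF/GFF file")
  keep <- gff$V3 %in% c("five_prime_UTR", "CDS", "three_prime_UTR", "exon")
  gff <- gff[keep, , drop = FALSE]
  id <- sub('.*(transcript_id[ =]"?([^";]+)"?).*', "\\2", gff$V9)
  id2 <- sub(".*Parent=([^;]+).*", "\\1", gff$V9)
  tid <- ifelse(grepl("transcript_id", gff$V9), id, id2)
  region <- c(five_prime_UTR = "5UTR", CDS = "CDS",
              three_prime_UTR = "3UTR", exon = "exon")[gff$V3]
  data.frame(transcript_id = tid, region = unname(region),
             start = gff$V4, end = gff$V5, strand = gff$V7,
             stringsAsFactors = FALSE)
}

#' Write an MSA conservation track as bedGraph
#' @param profile result of [conservation_score()].
#' @param ref_id molecule name for column 1.
#' @param path output file.
#' @export
write_bedgraph <- function(profile, ref_id, path) {
  bg <- data.frame(chrom = ref_id, start = profile$column - 1L,
                   end = profile$column, value = profile$scaled)
  utils::write.table(bg, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write the pipeline configuration as YAML
#' @param config a list (e.g. from [sim_config()], minus the curve).
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  cfg <- config
  if (inherits(cfg$calibration, "calibration_curve")) {
    cfg$calibration <- list(gap_ratio = cfg$calibration$gap_ratio,
                            fraction = cfg$calibration$fraction)
  }
  class(cfg) <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$calibration)) {
    cfg$calibration <- calibration_curve(cfg$calibration$gap_ratio,
                                         cfg$calibration$fraction)
  }
  do.call(sim_config, cfg[intersect(names(cfg), names(formals(sim_config)))])
}
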