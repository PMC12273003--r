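# End-to-end orchestration over the synthetic experiment:
# simulate -> call -> annotate -> conserve -> translate -> correlate.
# Every run is reproducible from (config, seed) alone; outputs carry the
# config's md5 so tables can be traced back to the exact settings.

#' Run the full synthetic Psi pipeline
#'
#' Executes the requested stages in dependency order on a fully synthetic
#' experiment defined by `config`, optionally writing each stage's tables to
#' `outdir`. Stage outputs feed forward: calling uses the simulated pileups,
#' annotation and the stability/TE statistics use the called sites, and the
#' translation stage uses the simulated footprints.
#'
#' @param config a [sim_config()].
#' @param stages character subset of
#'   `c("simulate", "call", "annotate", "translate", "correlate")`
#'   (upstream stages are added automatically).
#' @param outdir optional output directory for TSV/FASTA/BED exports.
#' @return a `psi_pipeline` list with per-stage results, the config and its
#'   md5 hash.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "call", "annotate",
                                    "translate", "correlate"),
                         outdir = NULL) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  order_all <- c("simulate", "call", "annotate", "translate", "correlate")
  .assert(all(stages %in% order_all),
          paste0("unknown stage; valid: ", paste(order_all, collapse = ", ")))
  # pull in everything upstream of the latest requested stage
  stages <- order_all[seq_len(max(match(stages, order_all)))]
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  cfg_file <- tempfile(fileext = ".yaml")
  write_config(config, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  res <- list(config = config, config_md5 = cfg_hash, stages = stages)

  message("[simulate] transcriptome + truth (seed ", config$seed, ")")
  res$models <- make_transcriptome(config)
  res$truth <- plant_psi_sites(res$models, config)
  res$pileups <- simulate_bidseq_pileup(res$truth, res$models, config)
  res$lifetimes <- simulate_lifetimes(res$truth, config, res$models)
  if (!is.null(outdir)) {
    write_fasta(res$models$sequences, file.path(outdir, "reference.fasta"))
    write_annotation(res$models, file.path(outdir, "annotation.tsv"))
    utils::write.table(res$truth, file.path(outdir, "truth_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_config(config, file.path(outdir, "config.yaml"))
  }
  if (!"call" %in% stages) return(structure(res, class = "psi_pipeline"))

  message("[call] ", length(res$pileups), " tissues x ",
          config$n_replicates, " replicates")
  res$sites <- lapply(names(res$pileups), function(tis) {
    combined <- combine_replicates(res$pileups[[tis]])
    call_sites(combined, res$models$sequences, curve = config$calibration,
               background_rate = config$background_deletion_rate,
               tissue = tis)
  })
  names(res$sites) <- names(res$pileups)
  if (!is.null(outdir)) {
    all_sites <- do.call(rbind, res$sites)
    write_sites(all_sites, file.path(outdir, "sites.tsv"))
    write_bed(all_sites, file.path(outdir, "sites.bed"))
  }
  if (!"annotate" %in% stages) return(structure(res, class = "psi_pipeline"))

  message("[annotate] regions, metagene, tissue sharing")
  res$site_matrix <- tissue_site_matrix(res$sites)
  res$sharing <- if (ncol(res$site_matrix) >= 2L) {
    classify_tissue_sharing(res$site_matrix)
  } else NULL
  pooled <- unique(do.call(rbind, res$sites)[, c("ref_id", "pos", "strand")])
  res$metagene <- metagene_profile(pooled, res$models)
  res$density <- region_density(pooled, res$models)
  if (!is.null(outdir)) {
    utils::write.table(res$metagene, file.path(outdir, "metagene.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$density, file.path(outdir, "region_density.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!"translate" %in% stages) return(structure(res, class = "psi_pipeline"))

  message("[translate] footprints -> TPM -> E_transcript / E_codon")
  lens <- stats::setNames(res$models$transcripts$mature_len,
                          res$models$transcripts$transcript_id)
  res$te <- list()
  for (tis in .tissue_names(config$n_tissues)) {
    fp <- simulate_footprints(res$models, res$truth, config, tissue = tis)
    reads <- filter_footprints(fp$reads)
    cov <- psite_coverage(reads, lens, offset = config$psite_offset)
    ribo_counts <- vapply(cov, sum, numeric(1))
    ribo_tpm <- compute_tpm(ribo_counts, lens)
    rna_tpm <- compute_tpm(stats::setNames(fp$rna$count, fp$rna$transcript_id),
                           lens)
    dw <- codon_dwell(cov, res$models, rna_tpm)
    res$te[[tis]] <- list(
      e_transcript = transcript_te(ribo_tpm, rna_tpm),
      dwell = dw, e_codon = codon_te(dw),
      truth = fp$truth)
  }
  if (!is.null(outdir)) {
    et <- do.call(rbind, lapply(names(res$te), function(tis) {
      e <- res$te[[tis]]$e_transcript
      data.frame(tissue = tis, transcript_id = names(e), e_transcript = e)
    }))
    utils::write.table(et, file.path(outdir, "e_transcript.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!"correlate" %in% stages) return(structure(res, class = "psi_pipeline"))

  message("[correlate] stoichiometry vs TE and lifetime")
  te_ids <- Reduce(intersect, lapply(res$te, function(x) names(x$e_transcript)))
  te_mat <- sapply(res$te, function(x) x$e_transcript[te_ids])
  rownames(te_mat) <- te_ids
  res$site_te <- if (nrow(res$site_matrix) > 0 && ncol(res$site_matrix) >= 3) {
    site_te_correlation(res$site_matrix, te_mat)
  } else NULL
  pooled_sites <- do.call(rbind, res$sites)
  sf <- summed_fraction_per_transcript(pooled_sites)
  res$lifetime_groups <- if (nrow(sf) >= 8L) {
    lifetime_group_analysis(sf, res$lifetimes)
  } else NULL
  if (!is.null(outdir) && !is.null(res$lifetime_groups)) {
    utils::write.table(res$lifetime_groups$summary,
                       file.path(outdir, "lifetime_groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(res, class = "psi_pipeline")
}

#' @export
print.psi_pipeline <- function(x, ...) {
  cat("Psi pipeline run (config md5 ", substr(x$config_md5, 1, 8), ", seed ",
      x$config$seed, ")\n", sep = "")
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  cat("  transcripts:", nrow(x$models$transcripts),
      " planted site rows:", nrow(x$truth), "\n")
  if (!is.null(x$sites)) {
    cat("  called sites per tissue:",
        paste(vapply(x$sites, nrow, integer(1)), collapse = ", "), "\n")
  }
  if (!is.null(x$sharing)) {
    cat("  sharing:", paste(names(x$sharing$counts), x$sharing$counts,
                            sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
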