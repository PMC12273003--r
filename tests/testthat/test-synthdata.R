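# The generator: determinism, structural guarantees, planted distributions.

test_that("transcriptome generation is deterministic and structurally valid", {
  cfg <- sim_config(n_genes = 10L, seed = 5L)
  m1 <- make_transcriptome(cfg)
  m2 <- make_transcriptome(cfg)
  expect_identical(m1, m2)
  expect_equal(nrow(m1$transcripts), 10L)
  expect_true(all(m1$transcripts$cds_len %% 3 == 0))
  # CDS starts ATG and ends with a stop, checked on the mature sequence
  mat <- mature_sequences(m1)
  for (i in seq_len(10)) {
    tx <- m1$transcripts[i, ]
    cds <- substr(mat[[tx$transcript_id]], tx$utr5_len + 1,
                  tx$utr5_len + tx$cds_len)
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                  c("TAA", "TAG", "TGA"))
    # no in-frame internal stop
    codons <- substring(cds, seq(1, nchar(cds) - 3, 3),
                        seq(3, nchar(cds) - 1, 3))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }
  expect_true(all(grepl("^[ACGT]+$", m1$sequences)))
})

test_that("fixed-width CDS range forces exact lengths", {
  cfg <- sim_config(n_genes = 5L, cds_len_range = c(300L, 300L), seed = 2L)
  m <- make_transcriptome(cfg)
  expect_true(all(m$transcripts$cds_len == 300L))
})

test_that("splice mapping is consistent with exon intervals", {
  cfg <- sim_config(n_genes = 8L, n_intron_range = c(1L, 3L), seed = 9L)
  m <- make_transcriptome(cfg)
  mat <- mature_sequences(m)
  for (id in m$transcripts$transcript_id) {
    L <- m$transcripts$premrna_len[m$transcripts$transcript_id == id]
    mp <- premrna_to_mature(m, id, seq_len(L))
    # mature positions are 1..mature_len exactly once, introns NA
    expect_equal(sort(mp[!is.na(mp)]),
                 seq_len(m$transcripts$mature_len[m$transcripts$transcript_id == id]))
    # base identity between pre-mRNA exonic positions and the spliced sequence
    pre <- strsplit(m$sequences[[id]], "")[[1]]
    spl <- strsplit(mat[[id]], "")[[1]]
    ex <- which(!is.na(mp))
    expect_equal(pre[ex], spl[mp[ex]])
  }
})

test_that("planted sites are U positions with the configured tissue sharing", {
  cfg <- sim_config(n_genes = 20L, psi_site_rate = 0.03, n_tissues = 4L,
                    share_all_tissues = 1.0, seed = 3L)
  m <- make_transcriptome(cfg)
  tr <- plant_psi_sites(m, cfg)
  expect_gt(nrow(tr), 0)
  base <- substr(m$sequences[tr$transcript_id], tr$pos, tr$pos)
  expect_true(all(base == "T"))
  # share_all_tissues = 1: every site present in all tissues
  key <- paste(tr$transcript_id, tr$pos)
  expect_true(all(table(key) == 4L))
  expect_true(all(tr$sharing == "shared_all"))
  expect_true(all(tr$true_fraction >= 0 & tr$true_fraction <= 1))

  # rate 0 -> empty truth
  cfg0 <- sim_config(n_genes = 5L, psi_site_rate = 0, seed = 3L)
  expect_equal(nrow(plant_psi_sites(make_transcriptome(cfg0), cfg0)), 0L)
})

test_that("planted fractions follow the configured Beta mixture", {
  cfg <- sim_config(n_genes = 400L, n_psi_sites = 1000L, n_tissues = 1L,
                    tissue_fraction_sd = 0, seed = 21L)
  m <- make_transcriptome(cfg)
  tr <- plant_psi_sites(m, cfg)
  expect_equal(nrow(tr), 1000L)
  mx <- cfg$fraction_mix
  p_low <- mx$w * pbeta(0.2, mx$a1, mx$b1) + (1 - mx$w) * pbeta(0.2, mx$a2, mx$b2)
  share <- mean(tr$base_fraction < 0.2)
  # empirical share within 4 binomial standard errors of the mixture mass
  se <- sqrt(p_low * (1 - p_low) / 1000)
  expect_lt(abs(share - p_low), 4 * se)
  # and the distribution plants the low-stoichiometry majority
  expect_gt(share, 2 / 3)
})

test_that("pileup simulation recovers planted fractions at depth", {
  cfg <- sim_config(n_genes = 60L, n_psi_sites = 200L, n_tissues = 1L,
                    n_replicates = 1L, tissue_fraction_sd = 0,
                    background_deletion_rate = 0, depth_mean = 1000,
                    seed = 17L)
  m <- make_transcriptome(cfg)
  tr <- plant_psi_sites(m, cfg)
  pl <- simulate_bidseq_pileup(tr, m, cfg)[["tissue01"]][["rep1"]]
  idx <- match(paste(tr$transcript_id, tr$pos), paste(pl$ref_id, pl$pos))
  gr <- pl$deletion_reads[idx] / pl$total_reads[idx]
  err <- abs(gr - tr$true_fraction)
  # mean absolute error bounded by the mean binomial standard error
  se <- sqrt(tr$true_fraction * (1 - tr$true_fraction) / pl$total_reads[idx])
  expect_lt(mean(err), 2 * mean(se) + 1e-3)
  # with zero background and fraction 0 there are no deletions
  unmod <- setdiff(seq_len(nrow(pl)), idx)
  expect_true(all(pl$deletion_reads[unmod] == 0))
})

test_that("pileups are replicate-stable under the hierarchical seed", {
  cfg2 <- sim_config(n_genes = 6L, n_tissues = 2L, n_replicates = 2L, seed = 8L)
  cfg3 <- sim_config(n_genes = 6L, n_tissues = 2L, n_replicates = 3L, seed = 8L)
  m <- make_transcriptome(cfg2)
  tr <- plant_psi_sites(m, cfg2)
  p2 <- simulate_bidseq_pileup(tr, m, cfg2)
  p3 <- simulate_bidseq_pileup(tr, m, cfg3)
  # adding a replicate leaves earlier tissue/replicate draws untouched
  expect_identical(p2$tissue01$rep1, p3$tissue01$rep1)
  expect_identical(p2$tissue02$rep2, p3$tissue02$rep2)
})

test_that("footprint coverage is shaped by dwell times and uniform without them", {
  cfg <- sim_config(n_genes = 15L, n_tissues = 1L, dwell_noise_sd = 0,
                    footprint_mean_coverage = 50, utr5_len_range = c(20L, 40L),
                    seed = 4L)
  m <- make_transcriptome(cfg)
  tr <- plant_psi_sites(m, cfg)
  fp <- simulate_footprints(m, tr, cfg)
  expect_true(all(fp$reads$length >= 20 & fp$reads$length <= 45))
  expect_true(all(fp$reads$start >= 1))
  # dwell truth spans the configured [0.5, 2] range
  expect_true(all(fp$truth$dwell >= 0.5 & fp$truth$dwell <= 2))
  b <- c("T", "C", "A", "G")
  sense <- setdiff(as.vector(outer(outer(b, b, paste0), b, paste0)),
                   c("TAA", "TAG", "TGA"))
  expect_setequal(names(fp$truth$dwell), sense)
})

test_that("lifetime simulation plants the configured direction", {
  cfg <- sim_config(n_genes = 120L, psi_site_rate = 0.03,
                    lifetime_effect = -0.5, lifetime_noise_sd = 0, seed = 6L)
  m <- make_transcriptome(cfg)
  tr <- plant_psi_sites(m, cfg)
  lt <- simulate_lifetimes(tr, cfg, m)
  # noise-free: lifetime rank order exactly inverse to summed fraction
  expect_equal(order(lt$lifetime_h), order(-lt$summed_fraction))

  cfg0 <- sim_config(n_genes = 300L, psi_site_rate = 0.03,
                     lifetime_effect = 0, lifetime_noise_sd = 0.3, seed = 6L)
  m0 <- make_transcriptome(cfg0)
  tr0 <- plant_psi_sites(m0, cfg0)
  lt0 <- simulate_lifetimes(tr0, cfg0, m0)
  # zero effect: association within sampling error of zero
  r <- cor(lt0$summed_fraction, log(lt0$lifetime_h))
  expect_lt(abs(r), 3 / sqrt(nrow(lt0)))
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(psi_site_rate = 1.5), "psi_site_rate")
  expect_error(sim_config(n_replicates = 0L), "n_replicates")
  expect_error(sim_config(cds_len_range = c(600L, 300L)), "range")
  expect_error(sim_config(background_deletion_rate = -0.1), "background")
})
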