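# Correlation layer, sign odds ratios, grouped comparisons, Wilcoxon.

test_that("Pearson correlation matches the textbook formula and flags degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.4)
  got <- pearson_r(x, y)
  expect_equal(got$r, oracle_pearson(x, y), tolerance = 1e-12)
  # p agrees with the t-transform computed by hand
  t <- got$r * sqrt((5 - 2) / (1 - got$r^2))
  expect_equal(got$p, 2 * pt(abs(t), 3, lower.tail = FALSE), tolerance = 1e-12)
  expect_false(pearson_r(rep(1, 5), y)$ok)
})

test_that("site-TE correlation recovers planted coupling and skips degenerate rows", {
  set.seed(15)
  n_tis <- 8
  latent <- rnorm(n_tis)
  site_mat <- rbind(coupled = plogis(0.2 + 1.5 * latent + rnorm(n_tis, 0, 0.1)),
                    noise = runif(n_tis))
  colnames(site_mat) <- paste0("t", 1:n_tis)
  te_mat <- t(replicate(30, exp(0.8 * latent + rnorm(n_tis, 0, 0.3))))
  rownames(te_mat) <- paste0("g", 1:30)
  colnames(te_mat) <- colnames(site_mat)
  res <- site_te_correlation(site_mat, te_mat)
  expect_gt(res$site_median["coupled"], 0.5)
  expect_equal(sum(res$sign_tally), nrow(site_mat))
  # constant TE across tissues -> correlations undefined, site skipped
  te_const <- matrix(1, 3, n_tis,
                     dimnames = list(paste0("c", 1:3), colnames(site_mat)))
  res2 <- site_te_correlation(site_mat, te_const)
  expect_equal(unname(res2$sign_tally["skipped"]), 2L)
})

test_that("permuted tissue labels give a balanced sign tally", {
  set.seed(22)
  n_tis <- 9
  shares <- replicate(60, {
    sm <- matrix(runif(40 * n_tis), 40,
                 dimnames = list(paste0("s", 1:40), paste0("t", 1:n_tis)))
    tm <- matrix(exp(rnorm(50 * n_tis)), 50,
                 dimnames = list(paste0("g", 1:50), paste0("t", 1:n_tis)))
    site_te_correlation(sm, tm)$positive_share
  })
  # mean share over null replicates stays near 0.5
  expect_lt(abs(mean(shares) - 0.5), 0.05)
})

test_that("feature grouping uses the published relative-length definition", {
  tx <- data.frame(transcript_id = sprintf("t%02d", 1:10),
                   utr5_len = c(100, rep(50, 9)),
                   cds_len = c(400, seq(100, 900, 100)))
  g <- group_by_feature(tx, "relative_utr5_length", k = 5)
  expect_equal(g$feature_value[g$transcript_id == "t01"], 0.25)
  expect_equal(as.vector(table(g$group)), rep(2L, 5))
  # zero-CDS transcripts are excluded
  tx$cds_len[2] <- 0
  g2 <- group_by_feature(tx, "relative_utr5_length", k = 3)
  expect_false("t02" %in% g2$transcript_id)
  # tied feature values: stable assignment by transcript id
  tx3 <- data.frame(transcript_id = c("b", "a", "d", "c"),
                    utr5_len = c(10, 10, 10, 10), cds_len = c(100, 100, 100, 100))
  g3 <- group_by_feature(tx3, "relative_utr5_length", k = 2)
  expect_equal(g3$group[match(c("a", "b", "c", "d"), g3$transcript_id)],
               c(1L, 1L, 2L, 2L))
})

test_that("sign odds ratio and its binomial P match term-by-term summation", {
  r <- c(rep(0.5, 9), rep(-0.5, 3))
  so <- sign_odds_ratio(r)
  expect_equal(so$or, 3)
  expect_equal(so$p, oracle_binom_upper(9, 12, 0.5), tolerance = 1e-12)
  expect_equal(so$p, 0.073, tolerance = 1e-3)
  even <- sign_odds_ratio(c(rep(1, 6), rep(-1, 6)))
  expect_equal(even$or, 1)
  expect_equal(even$p, oracle_binom_upper(6, 12, 0.5), tolerance = 1e-12)
  inf <- sign_odds_ratio(c(0.1, 0.2))
  expect_equal(inf$or, Inf)
  expect_equal(inf$p, 0.25)
  # zeros excluded from both tallies but reported
  so0 <- sign_odds_ratio(c(1, -1, 0, 0))
  expect_equal(so0$n_zero, 2L)
  expect_equal(so0$n_pos + so0$n_neg, 2L)
})

# probability mass at the observed U statistic (for tail complementarity)
mean_u_mass <- function(a, b) {
  na <- length(a)
  rk <- rank(c(a, b))
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  dwilcox(U, na, length(b))
}

test_that("one-tailed Wilcoxon matches exhaustive enumeration for small n", {
  expect_equal(wilcoxon_one_tailed(c(1, 2), c(3, 4), "less"), 1 / 6)
  expect_equal(wilcoxon_one_tailed(c(1, 2), c(3, 4), "less"),
               oracle_wilcox_less(c(1, 2), c(3, 4)))
  # interleaved samples: exact p equals pwilcox(U = 3, 3, 3) = 7/20
  expect_equal(wilcoxon_one_tailed(c(1, 3, 5), c(2, 4, 6) - 1e-9, "less"), 0.35)
  # all splits with pooled n <= 10, tie-free
  set.seed(19)
  for (na in 1:5) {
    for (nb in 1:(10 - na)) {
      v <- sample(seq_len(40), na + nb)
      a <- v[seq_len(na)]; b <- v[-seq_len(na)]
      expect_equal(wilcoxon_one_tailed(a, b, "less"), oracle_wilcox_less(a, b),
                   tolerance = 1e-12, info = paste(na, nb))
      # the two tails are complementary through the discrete distribution
      expect_equal(wilcoxon_one_tailed(a, b, "greater"),
                   1 - oracle_wilcox_less(a, b) +
                     mean_u_mass(a, b), tolerance = 1e-12)
    }
  }
})

test_that("approximate Wilcoxon agrees with the exact path at boundary sizes", {
  set.seed(27)
  for (i in 1:30) {
    na <- sample(4:6, 1); nb <- sample(4:6, 1)
    v <- sample(seq_len(60), na + nb)
    a <- v[seq_len(na)]; b <- v[-seq_len(na)]
    exact <- wilcoxon_one_tailed(a, b, "less", exact_limit = 12L)
    approx <- wilcoxon_one_tailed(a, b, "less", exact_limit = 0L)
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("lifetime grouping recovers a planted negative effect", {
  cfg <- sim_config(n_genes = 400L, psi_site_rate = 0.02,
                    lifetime_effect = -1, lifetime_noise_sd = 0.25, seed = 33L)
  m <- make_transcriptome(cfg)
  tr <- plant_psi_sites(m, cfg)
  lt <- simulate_lifetimes(tr, cfg, m)
  sf <- data.frame(transcript_id = lt$transcript_id,
                   summed_fraction = lt$summed_fraction)
  res <- lifetime_group_analysis(sf, lt, k = 4)
  meds <- res$summary$median
  expect_true(all(diff(meds) < 0))  # monotone decreasing in Psi fraction
  bottom_top <- res$contrasts[res$contrasts$group_low == 1 &
                                res$contrasts$group_high == 4, ]
  expect_lt(bottom_top$p, 0.01)
  # quantile groups differ in size by at most one
  expect_lte(diff(range(res$summary$n)), 1)
})

test_that("zero planted effect yields no monotone lifetime trend", {
  cfg <- sim_config(n_genes = 300L, psi_site_rate = 0.02, lifetime_effect = 0,
                    seed = 41L)
  m <- make_transcriptome(cfg)
  tr <- plant_psi_sites(m, cfg)
  lt <- simulate_lifetimes(tr, cfg, m)
  sf <- data.frame(transcript_id = lt$transcript_id,
                   summed_fraction = lt$summed_fraction)
  res <- lifetime_group_analysis(sf, lt, k = 4)
  meds <- res$summary$median
  expect_false(all(diff(meds) < 0) || all(diff(meds) > 0))
})

test_that("TE grouping labels tertiles and handles strata", {
  cfg <- sim_config(n_genes = 200L, psi_site_rate = 0.03, te_effect = 1.5,
                    seed = 52L)
  m <- make_transcriptome(cfg)
  tr <- plant_psi_sites(m, cfg)
  fp <- simulate_footprints(m, tr, cfg)
  sf <- summed_fraction_by_transcript_truth(tr)
  res <- te_group_analysis(sf, fp$truth$te, k = 3)
  expect_equal(res$summary$label, c("low", "medium", "high"))
  expect_true(all(diff(res$summary$median) > 0))
  # identical TE everywhere: no trend, large p
  flat <- setNames(rep(2, nrow(sf)), sf$transcript_id)
  res_flat <- te_group_analysis(sf, flat, k = 3)
  expect_true(all(res_flat$contrasts$p > 0.4))
  # region-stratified variant
  strata <- setNames(sample(c("5UTR", "CDS"), nrow(sf), TRUE),
                     sf$transcript_id)
  res_st <- te_group_analysis(sf, fp$truth$te, strata = strata)
  expect_setequal(res_st$summary$label, c("5UTR", "CDS"))
  expect_true(all(c("p_a_less", "p_a_greater") %in% names(res_st$contrasts)))
})

test_that("tRNA region correlations carry one record per decoded codon", {
  td <- simulate_trna_dataset(n_trnas = 12L, n_tissues = 8L, seed = 5L)
  rec <- trna_region_te_correlation(td$sites, td$fractions, td$e_codon)
  # records per site equal the number of decoded codons
  for (i in seq_len(nrow(td$sites))) {
    n_cod <- length(strsplit(td$sites$codons[i], ",")[[1]])
    hit <- rec$trna_id == td$sites$trna_id[i] &
      rec$position == td$sites$position[i]
    expect_equal(sum(hit), n_cod)
  }
  # planted T-arm-loop coupling shifts that region's r distribution up
  expect_gt(median(rec$r[rec$region == "T-arm-loop"]), 0.3)
  expect_lt(abs(median(rec$r[rec$region == "D-arm-stem"])), 0.45)
})

test_that("wobble decoding follows standard pairing rules", {
  expect_setequal(decoded_codons("GAA"), c("TTC", "TTT"))  # Phe
  expect_setequal(decoded_codons("TAA"), c("TTA", "TTG"))  # Leu
  expect_equal(decoded_codons("CAT"), "ATG")               # Met
  # anticodon whose codons are all stops decodes nothing
  expect_equal(length(decoded_codons("TTA")), 0L)          # TAA/TAG stops
})
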