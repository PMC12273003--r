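# Smith-Waterman, homologous-site mapping, class assignment, conservation.

test_that("Smith-Waterman recovers identities and rejects disjoint sequences", {
  aln <- smith_waterman("ACGT", "ACGT", alignment_scoring(2, -1, -2))
  expect_equal(aln$score, 8)
  expect_equal(aln$columns$pos_a, 1:4)
  expect_equal(aln$columns$pos_b, 1:4)
  empty <- smith_waterman("GGG", "CCC", alignment_scoring(2, -1, -2))
  expect_equal(empty$score, 0)
  expect_equal(nrow(empty$columns), 0L)
  expect_error(smith_waterman("", "ACGT"), "non-empty")
})

test_that("Smith-Waterman matches exhaustive substring-pair scoring", {
  set.seed(99)
  for (i in 1:120) {
    a <- random_dna(sample(2:8, 1))
    b <- random_dna(sample(2:8, 1))
    got <- smith_waterman(a, b)$score
    expect_equal(got, oracle_local_score(a, b),
                 info = paste(a, b))
  }
})

test_that("Smith-Waterman score properties hold", {
  set.seed(4)
  for (i in 1:20) {
    a <- random_dna(12); b <- random_dna(12)
    s1 <- smith_waterman(a, b)$score
    # symmetric in its arguments
    expect_equal(s1, smith_waterman(b, a)$score)
    # never decreases when the match reward increases
    s2 <- smith_waterman(a, b, alignment_scoring(3, -1, -2))$score
    expect_gte(s2, s1)
  }
})

test_that("homologous-site mapping walks alignment columns correctly", {
  a <- "AATTTGG"
  b <- "CCAATTTGGCC"
  aln <- smith_waterman(a, b)
  mp <- map_homologous_sites(aln, c(3L, 4L), b)
  expect_equal(mp$pos_b, c(5L, 6L))
  expect_equal(mp$aligned_base_b, c("T", "T"))
  # a position outside the local alignment window has no homologous site
  aln2 <- smith_waterman("TTTTAAAA", "CCCCAAAA")
  outside <- map_homologous_sites(aln2, 2L, "CCCCAAAA")
  expect_equal(outside$aligned_base_b, "none")

  # random alignments: mapping equals an independent column-index walk
  set.seed(13)
  for (i in 1:15) {
    a <- random_dna(30); b <- random_dna(30)
    aln <- smith_waterman(a, b)
    if (nrow(aln$columns) == 0) next
    pos <- which(strsplit(a, "")[[1]] == "T")
    if (!length(pos)) next
    mp <- map_homologous_sites(aln, pos, b)
    for (k in seq_along(pos)) {
      hit <- which(aln$columns$pos_a == pos[k])
      if (!length(hit)) {
        expect_equal(mp$aligned_base_b[k], "none")
      } else if (is.na(aln$columns$pos_b[hit])) {
        expect_equal(mp$aligned_base_b[k], "gap")
      } else {
        expect_equal(mp$aligned_base_b[k],
                     substr(b, aln$columns$pos_b[hit], aln$columns$pos_b[hit]))
      }
    }
  }
})

test_that("Smith-Waterman agrees with an established local aligner", {
  set.seed(77)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1)
  for (i in 1:25) {
    a <- random_dna(sample(10:40, 1)); b <- random_dna(sample(10:40, 1))
    got <- smith_waterman(a, b, alignment_scoring(2, -1, -2))$score
    ref <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2,
                                         scoreOnly = TRUE)
    expect_equal(got, max(0, ref))
  }
})

test_that("site pairs get the four conservation classes", {
  expect_equal(classify_site_pair("T", "one_to_one"), 3L)
  expect_equal(classify_site_pair("C", "one_to_one"), 2L)
  expect_equal(classify_site_pair("none", "one_to_one"), 1L)
  expect_equal(classify_site_pair("gap", "one_to_one"), 1L)
  expect_equal(classify_site_pair(c("T", "T", "C"), "one_to_many"), 4L)
  expect_equal(classify_site_pair(c("C", "gap"), "one_to_many"), 2L)
  expect_equal(classify_site_pair(c("none", "none"), "one_to_many"), 1L)
  # one aligned U among partners suffices in a one-to-many context
  expect_equal(classify_site_pair(c("none", "T"), "one_to_many"), 4L)
})

test_that("classification over an orthologue set partitions the sites", {
  # planted design: a query with known fate for each Psi site
  query <- "AATTACGTACGTCCTGCA"
  psi <- which(strsplit(query, "")[[1]] == "T")
  partner_same <- query                              # every site class 3
  one <- classify_conservation(query, c(p1 = partner_same), psi)
  expect_true(all(one$class == 3L))
  partner_mut <- chartr("T", "C", query)             # homologous, never U
  two <- classify_conservation(query, c(p1 = partner_mut), psi)
  expect_true(all(two$class == 2L))
  # conserved + non-conserved counts always sum to the total
  expect_equal(sum(one$conserved) + sum(!one$conserved), length(psi))
  many <- classify_conservation(query, c(p1 = partner_same, p2 = partner_mut),
                                psi)
  expect_true(all(many$class == 4L))
})

test_that("conservation scores follow pairwise identity and min-max scaling", {
  # column letters A,A,C,C -> identical pairs / all pairs = 2/6
  msa <- c("A", "A", "C", "C")
  # a single column is necessarily a constant track, so a warning is expected
  expect_warning(cs <- conservation_score(msa, window = 1L), "constant")
  expect_equal(cs$raw, 2 / 6)
  # identical sequences: raw 1 everywhere, constant track scales to 0
  expect_warning(cs4 <- conservation_score(rep("ACGT", 4), window = 1L),
                 "constant")
  expect_true(all(cs4$raw == 1) && all(cs4$scaled == 0))
  # min-max scaling maps {0.2, 0.6, 1.0} onto {0, 0.5, 1}
  msa2 <- c("AAAAA", "AAAAA", "AACAA", "TTATA")  # engineered spread
  cs2 <- conservation_score(msa2, window = 1L)
  rng <- range(cs2$raw)
  expect_equal(cs2$scaled, (cs2$raw - rng[1]) / (rng[2] - rng[1]))
  # row order of the MSA does not matter
  expect_equal(conservation_score(msa2[c(3, 1, 4, 2)], window = 1L)$raw,
               cs2$raw)
  # all-gap columns score zero
  expect_equal(conservation_score(c("-A", "-A", "-C"), window = 1L)$raw[1], 0)
})

test_that("density-conservation correlation finds a constructed association", {
  set.seed(8)
  L <- 500L
  profile <- data.frame(column = 1:L, raw = 0, smoothed = 0,
                        scaled = rep(c(0.1, 0.9), each = 50, length.out = L))
  # place sites only in high-conservation windows
  high <- which(profile$scaled > 0.5)
  sites <- sample(high, 60, TRUE)
  res <- density_conservation_correlation(profile, sites, window = 50L)
  expect_gt(res$r, 0)
  expect_lt(res$p, 0.05)
  # hand-computable case matches the textbook Pearson formula
  prof5 <- data.frame(column = 1:50, raw = 0, smoothed = 0,
                      scaled = rep(c(0.1, 0.3, 0.5, 0.7, 0.9), each = 10))
  sites5 <- c(rep(5, 1), rep(15, 2), rep(25, 3), rep(35, 4), rep(45, 5))
  res5 <- density_conservation_correlation(prof5, sites5, window = 10L)
  expect_equal(res5$r, oracle_pearson(c(0.1, 0.3, 0.5, 0.7, 0.9), 1:5),
               tolerance = 1e-12)
  expect_error(density_conservation_correlation(prof5, sites5, window = 30L),
               "fewer than 3")
})

test_that("uniform sites on varying conservation give a null correlation", {
  set.seed(10)
  L <- 1000L
  profile <- data.frame(column = 1:L, raw = 0, smoothed = 0,
                        scaled = runif(L))
  pvals <- replicate(50, {
    sites <- sample.int(L, 100, TRUE)
    density_conservation_correlation(profile, sites, window = 50L)$p
  })
  # under the null, small p-values appear at roughly their nominal rate
  expect_lt(mean(pvals < 0.05), 0.2)
  expect_gt(mean(pvals), 0.25)
})

test_that("centre-star MSA stacks sequences to equal length", {
  seqs <- c("ACGTACGTAC", "ACGTACGTAC", "ACGTTCGTAC")
  msa <- center_star_msa(seqs)
  expect_equal(length(unique(nchar(msa))), 1L)
  expect_equal(gsub("-", "", msa[1]), seqs[1])
})
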