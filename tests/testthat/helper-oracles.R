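# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks: plain loops, term-by-term summation, exhaustive
# enumeration.

# upper-tail binomial P(X >= k) by term-by-term pmf summation
oracle_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  total <- 0
  for (x in k:n) total <- total + choose(n, x) * p^x * (1 - p)^(n - x)
  min(1, total)
}

# best local alignment score by exhaustive substring-pair evaluation:
# for every start cell, fill a no-floor prefix DP and take the global max
oracle_local_score <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  best <- 0
  for (i0 in seq_len(n)) {
    for (j0 in seq_len(m)) {
      M <- matrix(-Inf, n - i0 + 2L, m - j0 + 2L)
      M[1, 1] <- 0
      for (i in 2:(n - i0 + 2L)) M[i, 1] <- (i - 1) * gap
      for (j in 2:(m - j0 + 2L)) M[1, j] <- (j - 1) * gap
      for (i in 2:(n - i0 + 2L)) {
        for (j in 2:(m - j0 + 2L)) {
          s <- if (A[i0 + i - 2L] == B[j0 + j - 2L]) match else mismatch
          M[i, j] <- max(M[i - 1, j - 1] + s, M[i - 1, j] + gap,
                         M[i, j - 1] + gap)
        }
      }
      best <- max(best, max(M[-1, -1]))
    }
  }
  best
}

# exact one-tailed Wilcoxon ("a less than b") by enumerating every way the
# pooled ranks could be split between the two samples
oracle_wilcox_less <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  U_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  U_all <- apply(combos, 2, function(idx) sum(rk[idx]) - na * (na + 1) / 2)
  mean(U_all <= U_obs)
}

# naive per-position pileup summation across replicates
oracle_combine <- function(pileups) {
  keys <- unique(do.call(rbind, lapply(pileups, function(p) {
    p[, c("ref_id", "pos", "strand")]
  })))
  keys <- keys[order(keys$ref_id, keys$pos, keys$strand), , drop = FALSE]
  tot <- integer(nrow(keys)); del <- integer(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    for (p in pileups) {
      hit <- p$ref_id == keys$ref_id[i] & p$pos == keys$pos[i] &
        p$strand == keys$strand[i]
      tot[i] <- tot[i] + sum(p$total_reads[hit])
      del[i] <- del[i] + sum(p$deletion_reads[hit])
    }
  }
  data.frame(keys, total_reads = tot, deletion_reads = del,
             row.names = NULL, stringsAsFactors = FALSE)
}

# textbook Pearson product-moment formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
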