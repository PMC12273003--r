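# tRNA cloverleaf models and a coupled tRNA/codon-TE simulator.
#
# Region labels follow the canonical 76-position cloverleaf numbering:
# acceptor stem, D arm (stem/loop), anticodon arm (stem/loop, anticodon at
# 34-36), variable positions, T arm (stem/loop). Decoded codons derive from
# the anticodon by Watson-Crick pairing with standard wobble at position 34
# (G reads C/U, U reads A/G, A reads U, C reads G).

#' Canonical cloverleaf region labels for positions 1-76
#' @return character vector of length 76, named by position.
#' @export
trna_region_map <- function() {
  lab <- character(76)
  lab[1:7] <- "acceptor-stem"
  lab[8:9] <- "variable"
  lab[10:13] <- "D-arm-stem"
  lab[14:21] <- "D-arm-loop"
  lab[22:25] <- "D-arm-stem"
  lab[26] <- "variable"
  lab[27:31] <- "anticodon-arm-stem"
  lab[32:38] <- "anticodon-arm-loop"
  lab[39:43] <- "anticodon-arm-stem"
  lab[44:48] <- "variable"
  lab[49:53] <- "T-arm-stem"
  lab[54:60] <- "T-arm-loop"
  lab[61:65] <- "T-arm-stem"
  lab[66:76] <- "acceptor-stem"
  stats::setNames(lab, 1:76)
}

#' Codons decoded by an anticodon
#'
#' @param anticodon 3-mer written 5' to 3' (positions 34-36).
#' @return character vector of decoded codons (wobble included), stop codons
#'   removed.
#' @export
decoded_codons <- function(anticodon) {
  .assert(nchar(anticodon) == 3L, "anticodon must be a 3-mer")
  ac <- strsplit(toupper(anticodon), "")[[1]]
  third <- switch(ac[1],
                  G = c("C", "T"), T = c("A", "G"),
                  A = "T", C = "G",
                  stop("anticodon wobble base must be A/C/G/T"))
  first <- unname(.comp_base(ac[3]))
  second <- unname(.comp_base(ac[2]))
  setdiff(paste0(first, second, third), .codon_table()$stop)
}

#' Simulate a tRNA Psi dataset coupled to codon translation efficiency
#'
#' Builds a set of synthetic tRNAs with cloverleaf region labels, plants one
#' Psi site per tRNA in each of several regions, and generates per-tissue
#' codon TE together with per-tissue site stoichiometries. Sites in
#' `coupled_regions` co-vary across tissues with the TE of their tRNA's
#' decoded codons (positive coupling); sites elsewhere vary independently,
#' so their correlations sit on the null.
#'
#' @param n_trnas number of tRNAs.
#' @param n_tissues number of tissues.
#' @param coupled_regions regions whose sites track codon TE
#'   (default `"T-arm-loop"`).
#' @param coupling logit-scale slope of site fraction on the tissue's codon
#'   TE deviation (0 = no planted association).
#' @param site_regions regions that receive one planted site per tRNA.
#' @param tissue_sd tissue-to-tissue spread of log codon TE and of uncoupled
#'   site fractions.
#' @param seed integer seed.
#' @return list with `models` (trna_id, position, base, region_label,
#'   anticodon), `sites` (one row per planted site with decoded codons),
#'   `fractions` (site x tissue matrix), `e_codon` (codon x tissue matrix).
#' @export
simulate_trna_dataset <- function(n_trnas = 20L, n_tissues = 9L,
                                  coupled_regions = "T-arm-loop",
                                  coupling = 1.5,
                                  site_regions = c("T-arm-loop", "D-arm-stem",
                                                   "anticodon-arm-stem"),
                                  tissue_sd = 0.4, seed = 1L) {
  ct <- .codon_table()
  regmap <- trna_region_map()
  tissues <- .tissue_names(n_tissues)
  .with_stream(seed, "trna", expr = {
    # per-tissue codon TE: shared per-codon baseline plus tissue deviation
    z <- matrix(stats::rnorm(length(ct$sense) * n_tissues, 0, tissue_sd),
                nrow = length(ct$sense),
                dimnames = list(ct$sense, tissues))
    mu <- stats::rnorm(length(ct$sense), 0, 0.3)
    e_codon <- exp(mu + z)
    # anticodons whose decoded set is non-empty (stops excluded)
    acs <- replicate(n_trnas, {
      repeat {
        ac <- paste(sample(c("A", "C", "G", "T"), 3L, TRUE), collapse = "")
        if (length(decoded_codons(ac))) return(ac)
      }
    })
    model_rows <- vector("list", n_trnas)
    site_rows <- list()
    frac_rows <- list()
    for (i in seq_len(n_trnas)) {
      id <- sprintf("tRNA%03d", i)
      base <- sample(c("A", "C", "G", "T"), 76L, TRUE)
      base[34:36] <- strsplit(acs[i], "")[[1]]
      dec <- decoded_codons(acs[i])
      # tissue deviation of this tRNA's codons (mean over decoded codons)
      zbar <- colMeans(z[dec, , drop = FALSE])
      for (reg in site_regions) {
        pos <- sample(which(regmap == reg & seq_len(76) < 34 |
                            regmap == reg & seq_len(76) > 36), 1L)
        base[pos] <- "T"
        b0 <- stats::runif(1, 0.2, 0.6)
        f <- if (reg %in% coupled_regions) {
          stats::plogis(stats::qlogis(b0) + coupling * zbar)
        } else {
          stats::plogis(stats::qlogis(b0) +
                          stats::rnorm(n_tissues, 0, tissue_sd))
        }
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          trna_id = id, position = pos, region_label = unname(regmap[pos]),
          anticodon = acs[i], codons = paste(dec, collapse = ","),
          stringsAsFactors = FALSE)
        frac_rows[[length(frac_rows) + 1L]] <- f
      }
      model_rows[[i]] <- data.frame(
        trna_id = id, position = 1:76, base = base,
        region_label = unname(regmap), anticodon = acs[i],
        stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, site_rows)
    fractions <- do.call(rbind, frac_rows)
    dimnames(fractions) <- list(paste(sites$trna_id, sites$position, sep = ":"),
                                tissues)
    list(models = do.call(rbind, model_rows), sites = sites,
         fractions = fractions, e_codon = e_codon)
  })
}
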