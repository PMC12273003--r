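#' @keywords internal
"_PACKAGE"

# shared helpers: argument checks, coordinate conversions, seeded streams

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

.clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

.is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

# uniform draw from lo:hi that stays length-safe when lo == hi
# (sample() on a scalar would expand it to 1:x)
.sample_range <- function(lo, hi, n) {
  v <- lo:hi
  v[sample.int(length(v), n, replace = TRUE)]
}

# derive a reproducible sub-seed (< 2^31) for a named stream; keeps per
# tissue/replicate draws independent of how many other streams are consumed
.stream_seed <- function(seed, ...) {
  tokens <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(tokens)) h <- (h * 131 + v) %% 2147483629
  as.integer(h)
}

.with_stream <- function(seed, ..., expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.stream_seed(seed, ...))
  expr
}

# reverse complement for plain character vectors (delegates to Biostrings)
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]

# 1-based inclusive -> BED 0-based half-open
.to_bed_coords <- function(pos) list(start = pos - 1L, end = pos)

# all T positions of a sequence (character scalar), 1-based
.t_positions <- function(seq) {
  m <- gregexpr("T", seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

.codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  stops <- c("TAA", "TAG", "TGA")
  list(all = codons, stop = stops, sense = setdiff(codons, stops))
}
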