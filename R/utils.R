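# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators stay pure in (args, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * width, replace = TRUE), nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

# Pairwise-checked random barcode set with minimum Hamming distance.
random_barcodes <- function(n, width = 16L, min_dist = 3L) {
  acc <- matrix(integer(0), nrow = 0L, ncol = width)
  guard <- 0L
  while (nrow(acc) < n) {
    cand <- sample.int(4L, width, replace = TRUE)
    ok <- nrow(acc) == 0L ||
      min(rowSums(acc != matrix(cand, nrow(acc), width, byrow = TRUE))) >= min_dist
    if (ok) acc <- rbind(acc, cand)
    guard <- guard + 1L
    if (guard > 50L * n) stop("could not generate ", n, " barcodes at min_dist ", min_dist)
  }
  apply(matrix(DNA_BASES[acc], nrow = n), 1L, paste0, collapse = "")
}

is_dna <- function(x) grepl("^[ACGT]+$", x)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEnc = "UTF-8", eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
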