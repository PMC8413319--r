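# internal helpers shared across modules

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# numeric rank for chromosome labels; non-numeric labels sort last
chrom_rank <- function(chrom) {
  r <- suppressWarnings(as.integer(chrom))
  r[is.na(r)] <- .Machine$integer.max
  r
}

snp_order <- function(chrom, bp) {
  bp2 <- bp
  bp2[is.na(bp2)] <- .Machine$integer.max
  order(chrom_rank(chrom), bp2)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# connection that is transparent to ".gz" suffixes
open_input <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}
open_output <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

# contiguous block ids 1..B with sizes differing by at most one
block_ids <- function(n, n_blocks) {
  if (n_blocks < 2L) stop("n_blocks must be >= 2", call. = FALSE)
  if (n_blocks > n) stop("more jackknife blocks than observations", call. = FALSE)
  as.integer(ceiling(seq_len(n) * n_blocks / n))
}
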