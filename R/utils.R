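# internal helpers shared across modules

# canonical allele key: chrom:pos:ref:alt
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

position_key <- function(chrom, pos) {
  paste(chrom, pos, sep = ":")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_alltriage <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "alltriage_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# FNV-1a 32-bit hash over a character scalar; used for manifest config hashes.
# Plain R so manifests are reproducible without extra dependencies.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor in 16-bit halves: h can exceed bitwXor's integer range
    lo <- bitwXor(h %% 65536, b)
    h <- (h %/% 65536) * 65536 + lo
    # 32-bit modular multiply by the FNV prime 16777619, kept exact in
    # doubles by splitting h into 16-bit halves
    hi <- h %/% 65536
    lo2 <- h %% 65536
    h <- (lo2 * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# deterministic RNG scope: runs expr with a local seed, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# write a data.frame as plain TSV with LF endings (byte-stable across runs)
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n", na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE, ...)
}
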