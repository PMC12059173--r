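# internal helpers shared across modules

# Derive a per-module child seed from one global seed; offsets keep the
# generators independent while the whole run stays a function of one integer.
childSeed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((abs(as.numeric(seed)) + offset * 1000003) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Default TLS maturity labels: absent, immature, mature.
tlsStatuses <- function() c("nTLS", "imTLS", "mTLS")

assertColumns <- function(df, cols, what = "input table") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(df)
}

# Normalized Hamming distance between equal-length nucleotide strings.
normalizedHamming <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("normalizedHamming requires equal-length sequences")
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  mean(av != bv)
}

# All pairwise normalized Hamming distances among equal-length sequences,
# as a dist object (sequences kept in input order).
hammingDistMatrix <- function(seqs) {
  n <- length(seqs)
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    di <- colMeans(t(chars[(i + 1L):n, , drop = FALSE]) != chars[i, ])
    d[i, (i + 1L):n] <- di
    d[(i + 1L):n, i] <- di
  }
  stats::as.dist(d)
}
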