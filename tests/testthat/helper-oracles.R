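# Independent oracles, deliberately coded differently from the package paths
# they check.

# Direct-summation Jensen-Shannon divergence in bits: element-wise loop,
# natural log converted at the end.
jsd_oracle <- function(p, q, lambda = 0.5) {
  r <- lambda * p + (1 - lambda) * q
  acc_p <- 0
  acc_q <- 0
  for (i in seq_along(p)) {
    if (p[[i]] > 0) acc_p <- acc_p + p[[i]] * log(p[[i]] / r[[i]])
    if (q[[i]] > 0) acc_q <- acc_q + q[[i]] * log(q[[i]] / r[[i]])
  }
  (lambda * acc_p + (1 - lambda) * acc_q) / log(2)
}

# Brute-force global alignment oracle for tiny sequences: enumerates every
# global alignment recursively, scores it with BLOSUM62 + affine gap
# penalties (open 11, extend 1, charged per gap run as open + extend * len),
# and returns the identity (matches / alignment length) of the best-scoring
# alignment. Only usable for short strings.
nw_identity_oracle <- function(a, b, gap_open = 11, gap_extend = 1) {
  B62 <- cladesubs::load_substitution_matrix("BLOSUM62")
  best <- list(score = -Inf, identity = NA_real_)
  rec <- function(i, j, score, matches, len, prev) {
    if (i > nchar(a) && j > nchar(b)) {
      if (score > best$score) best <<- list(score = score,
                                            identity = matches / len)
      return(invisible())
    }
    if (i <= nchar(a) && j <= nchar(b)) {
      x <- substr(a, i, i); y <- substr(b, j, j)
      rec(i + 1L, j + 1L, score + B62[x, y], matches + (x == y), len + 1L, "m")
    }
    if (i <= nchar(a)) {
      pen <- if (prev == "da") gap_extend else gap_open + gap_extend
      rec(i + 1L, j, score - pen, matches, len + 1L, "da")
    }
    if (j <= nchar(b)) {
      pen <- if (prev == "db") gap_extend else gap_open + gap_extend
      rec(i, j + 1L, score - pen, matches, len + 1L, "db")
    }
  }
  rec(1L, 1L, 0, 0L, 0L, "m")
  best$identity
}

# Random residue distribution over the 20 standard amino acids.
random_distribution <- function() {
  x <- -log(runif(20))
  names(x) <- cladesubs:::AA20
  x / sum(x)
}
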