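# Independent oracles used across test files. Each is a deliberately
# naive implementation kept separate from the package code paths.

# Brute-force monopartite consensus scan: test every 4-residue window
# directly against K-(K/R)-X-(K/R).
oracleScanNLS <- function(residues, anchor = 1L) {
  n <- nchar(residues)
  hits <- integer()
  if (n >= 4L) {
    for (i in seq_len(n - 3L)) {
      w <- substr(residues, i, i + 3L)
      ok <- substr(w, 1, 1) == "K" &&
        substr(w, 2, 2) %in% c("K", "R") &&
        substr(w, 4, 4) %in% c("K", "R")
      if (ok) hits <- c(hits, i)
    }
  }
  anchor + hits - 1L
}

# Two-sided Fisher p for a 2x2 table by full hypergeometric enumeration:
# sum the point probabilities of every table with the same margins whose
# probability does not exceed the observed one (with the conventional
# relative-error guard).
oracleFisher2x2 <- function(tab) {
  m <- sum(tab[1L, ])
  n <- sum(tab[2L, ])
  k <- sum(tab[, 1L])
  x <- tab[1L, 1L]
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  pObs <- dhyper(x, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p at small n by enumerating every
# assignment of the pooled ranks to group A (no ties assumed).
oracleMannWhitney <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(a)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- combn(length(pooled), n1)
  uAll <- apply(idx, 2L, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  if (uObs == mu) return(1)
  if (uObs > mu) min(1, 2 * mean(uAll >= uObs)) else min(1, 2 * mean(uAll <= uObs))
}

# Random valid amino-acid sequence of length n.
randomResidues <- function(n, alphabet = BIRquant:::AA_ALPHABET_20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
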