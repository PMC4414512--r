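# Independent brute-force oracles. These deliberately re-derive results with
# naive full enumeration so they share no code path with the package.

# full-matrix affine-gap glocal DP, score only: read global, reference local
naive_glocal_score <- function(read, ref, match = 1, mism = 4, go = 6,
                               ge = 1) {
  a <- strsplit(read, "")[[1]]
  b <- strsplit(ref, "")[[1]]
  m <- length(a); n <- length(b)
  NEG <- -1e9
  H <- matrix(NEG, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)  # gap in read (deletion, consumes ref)
  F <- matrix(NEG, m + 1, n + 1)  # gap in ref (insertion, consumes read)
  H[1, ] <- 0
  for (i in 2:(m + 1)) {
    F[i, 1] <- max(H[i - 1, 1] - go - ge, F[i - 1, 1] - ge)
    H[i, 1] <- F[i, 1]
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - go - ge, E[i, j - 1] - ge)
      F[i, j] <- max(H[i - 1, j] - go - ge, F[i - 1, j] - ge)
      d <- H[i - 1, j - 1] + if (a[i - 1] == b[j - 1]) match else -mism
      H[i, j] <- max(d, E[i, j], F[i, j])
    }
  }
  max(H[m + 1, ])
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

iupac_compatible <- function(x, y) {
  length(intersect(IUPAC_SETS[[x]], IUPAC_SETS[[y]])) > 0
}

# scan every window, counting IUPAC-aware mismatches by set intersection
oracle_primer_scan <- function(reference, primer, max_mm) {
  p <- strsplit(primer, "")[[1]]
  r <- strsplit(reference, "")[[1]]
  hits <- list()
  for (s in seq_len(length(r) - length(p) + 1)) {
    mm <- 0
    for (k in seq_along(p))
      if (!iupac_compatible(p[k], r[s + k - 1])) mm <- mm + 1
    if (mm <= max_mm)
      hits[[length(hits) + 1]] <- c(start = s - 1, mm = mm)
  }
  do.call(rbind, hits)
}

# mismatch count of pattern vs prefix/suffix by direct character comparison
oracle_end_mismatch <- function(seq, pattern, from_end = FALSE) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  if (length(s) < length(p)) return(NA_integer_)
  w <- if (from_end) s[(length(s) - length(p) + 1):length(s)]
       else s[seq_along(p)]
  sum(w != p)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
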