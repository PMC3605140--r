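# Independent oracles used across the suite.  These deliberately avoid
# the code paths they check: the motif matcher is a position-by-position
# loop with its own IUPAC table, the zero-well probability is obtained by
# enumerating well draws, and the binomial CI comes from the beta-quantile
# form of the Clopper-Pearson bounds.

# IUPAC compatibility: a pattern code matches a base iff the base belongs
# to the code's set
.iupac <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

.revcompPattern <- function(pattern) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
            S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
            D = "H", H = "D", N = "N")
  paste(rev(comp[strsplit(pattern, "")[[1]]]), collapse = "")
}

# naive scan of one strand: a match at i requires every pattern position
# to be IUPAC-compatible with the sequence base (an N in the sequence
# matches any pattern code, mirroring degenerate matching)
naiveScanStrand <- function(seq, pattern) {
  ch <- strsplit(seq, "")[[1]]
  k <- nchar(pattern)
  L <- length(ch)
  if (L < k) return(integer())
  pat <- strsplit(pattern, "")[[1]]
  ok <- rep(TRUE, L - k + 1)
  for (j in seq_len(k)) {
    allowed <- .iupac[[pat[j]]]
    here <- ch[seq_len(L - k + 1) + j - 1]
    ok <- ok & (here %in% allowed | here == "N")
  }
  which(ok)
}

naiveScan <- function(seq, pattern) {
  fwd <- naiveScanStrand(seq, pattern)
  rev <- naiveScanStrand(seq, .revcompPattern(pattern))
  data.frame(position = c(fwd, rev),
             strand = rep(c("+", "-"), c(length(fwd), length(rev))))
}

# exact zero-well probability by enumerating every draw of W slots from
# N, the first R slots being recombinant (only feasible for tiny N)
enumeratePZero <- function(N, W, R) {
  draws <- utils::combn(N, W)
  mean(apply(draws, 2, function(d) all(d > R)))
}

# Clopper-Pearson bounds from beta quantiles
betaCI <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# genotype data.frame view of a simulated allele table, as consumed by
# callBreakpoints (one haploid allele per row)
allelesAsGenotypes <- function(alleles) {
  d <- alleles[, c("allele_id", "allele_kind", "source",
                   grep("^m[0-9]+$", names(alleles), value = TRUE))]
  names(d)[1] <- "sample_id"
  d
}
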