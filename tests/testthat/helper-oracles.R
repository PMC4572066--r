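# Independent oracles used across the suite.  These are deliberately naive
# re-implementations (double loops, exhaustive enumeration) kept separate
# from the package's code paths.

# standard nuclear genetic code, written out independently of the package
ORACLE_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

# enumeration oracle for Nei-Gojobori synonymous site counts
oracle_syn_sites <- function(codon) {
  aa <- ORACLE_CODE[[codon]]
  s <- 0
  for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                     substr(codon, pos, pos))) {
    mut <- codon
    substr(mut, pos, pos) <- b
    if (ORACLE_CODE[[mut]] != "*" && ORACLE_CODE[[mut]] == aa) s <- s + 1 / 3
  }
  s
}

# naive double-loop mean pairwise per-site diversity
oracle_pi <- function(seqs, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(seqs))
  m <- do.call(rbind, strsplit(seqs, ""))
  good <- m %in% c("A", "C", "G", "T")
  dim(good) <- dim(m)
  tot <- 0; n <- sum(weights)
  for (i in seq_along(seqs)) for (j in seq_along(seqs)) {
    if (j <= i) next
    use <- good[i, ] & good[j, ]
    tot <- tot + weights[i] * weights[j] * mean(m[i, use] != m[j, use])
  }
  tot / (n * (n - 1) / 2)
}

# brute-force chimera check: is v reproducible as A[1..b]+B[b+1..L] for any
# pair of other variants with support >= 2 and support(v) < min(supports)?
oracle_is_chimera <- function(v, v_sup, others, other_sup, max_mm = 0L) {
  L <- nchar(v)
  for (ai in seq_along(others)) for (bi in seq_along(others)) {
    if (ai == bi) next
    if (other_sup[ai] < 2L || other_sup[bi] < 2L) next
    if (v_sup >= min(other_sup[ai], other_sup[bi])) next
    for (b in seq_len(L - 1L)) {
      mosaic <- paste0(substr(others[ai], 1, b), substr(others[bi], b + 1, L))
      if (sum(strsplit(mosaic, "")[[1]] != strsplit(v, "")[[1]]) <= max_mm)
        return(TRUE)
    }
  }
  FALSE
}

# independently coded Tajima's D
oracle_tajima <- function(n, S, Pi) {
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (Pi - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# Fisher two-sided p by direct hypergeometric enumeration over tables with
# the observed margins
oracle_fisher2x2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) stats::dhyper(x, c1, n - c1, r1),
                  numeric(1))
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random equal-length ACGT alignment
random_alignment <- function(n, L, seed, pool = c("A", "C", "G", "T")) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(pool, L, replace = TRUE), collapse = ""), character(1))
  stats::setNames(seqs, paste0("s", seq_len(n)))
}
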