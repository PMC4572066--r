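# Diversity statistics over codon alignments: Nei-Gojobori synonymous /
# nonsynonymous site and difference counting with pathway averaging,
# haplotype and nucleotide diversity, Watterson's theta and Tajima's D.

STOP_CODONS <- c("TAA", "TAG", "TGA")

is_clean_codon <- function(codon) !grepl("[^ACGT]", codon)

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Nei-Gojobori counting: the synonymous site count is the sum over the three
#' codon positions of the fraction of the three possible single-nucleotide
#' changes that leave the amino acid unchanged (changes creating a stop codon
#' count as nonsynonymous); the nonsynonymous count is 3 minus that.
#'
#' @param codon 3-letter codon over A/C/G/T; stop codons are an error.
#' @return named numeric vector `c(s = ..., n = ...)` with `s + n == 3`.
#' @export
syn_nonsyn_sites <- function(codon) {
  if (!is_clean_codon(codon) || nchar(codon) != 3L)
    stop("codon must be a 3-mer over A/C/G/T: ", codon)
  if (codon %in% STOP_CODONS)
    stop("stop codon ", codon, " has no synonymous/nonsynonymous site counts;",
         " check the reading frame")
  aa <- translate_codon(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (!(mut %in% STOP_CODONS) && translate_codon(mut) == aa)
        s <- s + 1 / 3
    }
  }
  c(s = s, n = 3 - s)
}

#' Synonymous and nonsynonymous differences between two codons
#'
#' For k differing positions, counts are averaged over all k! orderings of
#' single-step mutational pathways between the codons, excluding pathways
#' that pass through a stop codon.  When at least one stop-free pathway
#' exists, `sd + nd == k`.
#'
#' @param codon_a,codon_b 3-mers over A/C/G/T.
#' @return named numeric vector `c(sd = ..., nd = ...)`; both `NA` when every
#'   pathway passes through a stop codon (the codon pair should then be
#'   excluded and reported as skipped).
#' @export
syn_nonsyn_diffs <- function(codon_a, codon_b) {
  if (!is_clean_codon(codon_a) || !is_clean_codon(codon_b))
    stop("codons must be over A/C/G/T")
  pos <- which(strsplit(codon_a, "")[[1L]] != strsplit(codon_b, "")[[1L]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- permutations_of(pos)
  sd_tot <- 0; nd_tot <- 0; n_ok <- 0L
  for (ordr in perms) {
    cur <- codon_a
    sd <- 0L; nd <- 0L; ok <- TRUE
    for (p in ordr) {
      nxt <- cur
      substr(nxt, p, p) <- substr(codon_b, p, p)
      if (nxt %in% STOP_CODONS) { ok <- FALSE; break }
      if (translate_codon(cur) == translate_codon(nxt)) sd <- sd + 1L
      else nd <- nd + 1L
      cur <- nxt
    }
    if (ok) { sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; n_ok <- n_ok + 1L }
  }
  if (n_ok == 0L) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = sd_tot / n_ok, nd = nd_tot / n_ok)
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in permutations_of(x[-i]))
      out[[length(out) + 1L]] <- c(x[[i]], rest)
  out
}

codon_columns <- function(aln) {
  check_in_frame(aln)
  n_codon <- (aln$length_nt - aln$frame_offset) %/% 3L
  lapply(seq_len(n_codon), function(ci)
    vapply(aln$seq, codon_at, character(1), ci, aln$frame_offset,
           USE.NAMES = TRUE))
}

# pairwise syn/nonsyn difference and site totals for one pair of sequences
pair_syn_nonsyn <- function(codons_a, codons_b) {
  sd <- 0; nd <- 0; s_a <- 0; s_b <- 0; n_codons <- 0L
  for (ci in seq_along(codons_a)) {
    ca <- codons_a[[ci]]; cb <- codons_b[[ci]]
    if (!is_clean_codon(ca) || !is_clean_codon(cb)) next
    if (ca %in% STOP_CODONS || cb %in% STOP_CODONS)
      stop("in-frame stop codon at codon ", ci,
           "; check frame_offset before requesting codon-aware statistics")
    dd <- syn_nonsyn_diffs(ca, cb)
    if (anyNA(dd)) next  # all pathways through stops: skip codon pair
    sd <- sd + dd[["sd"]]; nd <- nd + dd[["nd"]]
    s_a <- s_a + syn_nonsyn_sites(ca)[["s"]]
    s_b <- s_b + syn_nonsyn_sites(cb)[["s"]]
    n_codons <- n_codons + 1L
  }
  s_bar <- (s_a + s_b) / 2
  c(sd = sd, nd = nd, s_bar = s_bar, n_bar = 3 * n_codons - s_bar)
}

#' Positions of variable (segregating) nucleotide sites
#'
#' A site is variable when at least two distinct non-degenerate (A/C/G/T)
#' states are observed across the sequences.
#'
#' @param alignment a [codon_alignment()] or named character vector.
#' @return integer vector of 1-based site positions.
#' @export
variable_sites <- function(alignment) {
  m <- seq_char_matrix(alignment)
  which(apply(m, 2L, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")])) >= 2L
  }))
}

#' Indices of variable codons
#'
#' A codon column is variable when its gap/N-free codons include at least two
#' distinct codons.
#'
#' @param alignment a [codon_alignment()].
#' @return integer vector of 1-based codon indices.
#' @export
variable_codons <- function(alignment) {
  cols <- codon_columns(alignment)
  which(vapply(cols, function(col) {
    cl <- col[vapply(col, is_clean_codon, logical(1))]
    length(unique(cl)) >= 2L
  }, logical(1)))
}

# collapse sequences to unique haplotypes with summed weights
collapse_weighted <- function(seqs, weights) {
  u <- unique(seqs)
  w <- vapply(u, function(s) sum(weights[seqs == s]), numeric(1))
  list(seqs = u, w = unname(w))
}

a1_const <- function(n) sum(1 / seq_len(n - 1L))
a2_const <- function(n) sum(1 / seq_len(n - 1L)^2)

#' Diversity summary of a codon alignment
#'
#' Computes the standard haplotype-level and per-site summaries: number of
#' sequences and unique haplotypes, segregating sites S, haplotype diversity
#' Hd with small-sample correction, mean pairwise diversity per site over all
#' sites (pi), synonymous sites (pi_s) and nonsynonymous sites (pi_n, both by
#' pathway-averaged Nei-Gojobori counting), Watterson's theta per site and
#' Tajima's D.  Distances are uncorrected p-distances.
#'
#' `weights` turns unique-haplotype mode (default: every sequence counted
#' once) into frequency-weighted mode, e.g. per-individual dosage counts.
#'
#' @param alignment a [codon_alignment()].
#' @param weights optional per-sequence multiplicities (default 1 each).
#' @param codon_aware compute pi_s/pi_n (needs an in-frame alignment);
#'   default `TRUE`.
#' @return list of class `diversity_stats`: `n_sequences`, `length`, `S`,
#'   `Nhap`, `hap_diversity`, `pi`, `pi_s`, `pi_n`, `theta_w`, `tajima_d`,
#'   `mean_pairwise_diff` (the unscaled count used by Tajima's D).
#' @export
diversity <- function(alignment, weights = NULL, codon_aware = TRUE) {
  seqs <- alignment$seq
  if (is.null(weights)) weights <- rep(1, length(seqs))
  if (length(weights) != length(seqs))
    stop("weights length must match number of sequences")
  n <- sum(weights)
  if (n < 2) stop("need at least 2 sequences (after weighting)")
  cw <- collapse_weighted(unname(seqs), weights)
  u <- cw$seqs; w <- cw$w
  k <- length(u)
  L <- alignment$length_nt
  S <- length(variable_sites(stats::setNames(u, seq_len(k))))
  p_hap <- w / n
  hd <- n / (n - 1) * (1 - sum(p_hap^2))
  n_pairs <- n * (n - 1) / 2
  m <- seq_char_matrix(stats::setNames(u, seq_len(k)))
  good <- m == "A" | m == "C" | m == "G" | m == "T"
  cols <- if (codon_aware) codon_columns(alignment_from(u, alignment)) else NULL
  pi_sum <- 0; piS_sum <- 0; piN_sum <- 0; pidiff_sum <- 0
  if (k > 1L) for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    wp <- w[[i]] * w[[j]]
    use <- good[i, ] & good[j, ]
    ndiff <- sum(m[i, use] != m[j, use])
    pidiff_sum <- pidiff_sum + wp * ndiff
    pi_sum <- pi_sum + wp * ndiff / sum(use)
    if (codon_aware) {
      ps <- pair_syn_nonsyn(cols_of(cols, i), cols_of(cols, j))
      if (ps[["s_bar"]] > 0) piS_sum <- piS_sum + wp * ps[["sd"]] / ps[["s_bar"]]
      if (ps[["n_bar"]] > 0) piN_sum <- piN_sum + wp * ps[["nd"]] / ps[["n_bar"]]
    }
  }
  pi <- pi_sum / n_pairs
  mean_diff <- pidiff_sum / n_pairs
  theta_w <- S / (a1_const(n) * L)
  td <- tajima_d_from(n = n, S = S, mean_diff = mean_diff)
  structure(list(
    n_sequences = n, length = L, S = S, Nhap = k, hap_diversity = hd,
    pi = pi,
    pi_s = if (codon_aware) piS_sum / n_pairs else NA_real_,
    pi_n = if (codon_aware) piN_sum / n_pairs else NA_real_,
    theta_w = theta_w, tajima_d = td, mean_pairwise_diff = mean_diff),
    class = "diversity_stats")
}

# rebuild a codon_alignment around a unique-sequence set, keeping the frame
alignment_from <- function(seqs, template) {
  codon_alignment(stats::setNames(seqs, paste0("u", seq_along(seqs))),
                  frame_offset = template$frame_offset)
}

# codon vector of sequence i from precomputed codon columns
cols_of <- function(cols, i) vapply(cols, `[[`, character(1), i)

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf(
    "diversity_stats: n=%g Nhap=%d S=%d Hd=%.3f pi=%.4f pi_s=%.4f pi_n=%.4f theta_w=%.4f D=%s\n",
    x$n_sequences, x$Nhap, x$S, x$hap_diversity, x$pi, x$pi_s, x$pi_n,
    x$theta_w, ifelse(is.na(x$tajima_d), "NA", sprintf("%.3f", x$tajima_d))))
  invisible(x)
}

tajima_d_from <- function(n, S, mean_diff) {
  if (S == 0L || n < 2) return(NA_real_)
  a1 <- a1_const(n); a2 <- a2_const(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (mean_diff - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Tajima's D of an alignment
#'
#' Normalised difference between mean pairwise difference count and
#' S/a1, using the 1989 constants.  Undefined (NA) when S = 0.
#'
#' @inheritParams diversity
#' @return numeric scalar or `NA`.
#' @export
tajimas_d <- function(alignment, weights = NULL) {
  d <- diversity(alignment, weights, codon_aware = FALSE)
  d$tajima_d
}
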