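# Heterozygosity with exact Hardy-Weinberg tests, McDonald-Kreitman and HKA
# neutrality tests, and the counting-based per-codon selection scan.

#' Heterozygosity report for one locus
#'
#' Observed heterozygosity is the fraction of genotyped individuals carrying
#' at least two distinct haplotypes at the locus.  For the diploid-coded
#' statistics, individuals with a single haplotype contribute two copies of
#' it and individuals with two haplotypes one copy each; individuals with
#' more than two haplotypes cannot be represented under diploid inheritance
#' and are excluded from the expected-heterozygosity and HWE computations
#' (but still counted in `H_o` and in the homozygote-rule estimate).
#'
#' @param genotypes genotype list (see [read_genotype_table()]).
#' @param locus locus name, or `"all"` to pool haplotypes across loci (the
#'   multi-copy case, where 1 - proportion of single-haplotype individuals
#'   serves as the heterozygosity estimate).
#' @return list of class `heterozygosity_report`: `locus`, `n_genotyped`,
#'   `n_het`, `n_hom`, `H_o`, `H_e` (unbiased), `hwe_p`,
#'   `het_by_homozygote_rule`, `n_excluded_supernumerary`.
#' @export
heterozygosity <- function(genotypes, locus) {
  sets <- lapply(genotypes, function(g) {
    labs <- if (identical(locus, "all")) unlist(g) else g[[locus]]
    unique(labs)
  })
  sets <- sets[lengths(sets) > 0L]
  if (length(sets) == 0L) stop("no individual genotyped at locus ", locus)
  n_gen <- length(sets)
  het <- lengths(sets) >= 2L
  supern <- lengths(sets) > 2L
  # diploid coding for allele frequencies / HWE
  dip <- sets[!supern]
  geno_counts <- integer(0)
  if (length(dip)) {
    keys <- vapply(dip, function(s) {
      s <- sort(s)
      if (length(s) == 1L) paste(s, s, sep = "/") else paste(s, collapse = "/")
    }, character(1))
    geno_counts <- table(keys)
  }
  H_e <- NA_real_; hwe_p <- NA_real_
  if (length(dip)) {
    alleles <- unlist(lapply(dip, function(s) if (length(s) == 1L) c(s, s) else s))
    p <- table(alleles) / length(alleles)
    n2 <- length(alleles)
    H_e <- n2 / (n2 - 1) * (1 - sum(p^2))
    hwe_p <- hwe_exact(stats::setNames(as.integer(geno_counts),
                                       names(geno_counts)))$p
  }
  structure(list(
    locus = locus, n_genotyped = n_gen,
    n_het = sum(het), n_hom = sum(!het),
    H_o = mean(het), H_e = H_e, hwe_p = hwe_p,
    het_by_homozygote_rule = 1 - mean(lengths(sets) == 1L),
    n_excluded_supernumerary = sum(supern)),
    class = "heterozygosity_report")
}

# log probability of a genotype table conditional on its allele counts
# (Levene): P = n! 2^h prod(m_i!) / ((2n)! prod(n_ij!))
hwe_log_prob <- function(counts, allele_counts, n, het_mask) {
  lgamma(n + 1) + sum(het_mask * counts) * log(2) +
    sum(lgamma(allele_counts + 1)) - lgamma(2 * n + 1) -
    sum(lgamma(counts + 1))
}

parse_geno_names <- function(nm) {
  parts <- strsplit(nm, "/", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("genotype names must be 'allele/allele'")
  do.call(rbind, parts)
}

#' Exact test of Hardy-Weinberg proportions (multi-allelic)
#'
#' Conditional exact test in the Levene/Guo-Thompson formulation: among all
#' genotype tables with the observed allele counts, the p-value is the
#' probability mass of tables whose conditional probability does not exceed
#' that of the observed table.  Small problems are fully enumerated; larger
#' ones use Monte-Carlo sampling of allele pairings under a fixed seed.
#'
#' @param genotype_counts named integer vector of genotype counts; names are
#'   unordered allele pairs `"a/b"`.
#' @param method `"auto"` (default), `"enumerate"` or `"montecarlo"`.
#' @param B Monte-Carlo draws (default 1e5).
#' @param seed seed for the Monte-Carlo path.
#' @return list with `p`, `method`, and `n_tables` (enumeration) or `B`.
#' @export
hwe_exact <- function(genotype_counts, method = c("auto", "enumerate",
                                                  "montecarlo"),
                      B = 1e5L, seed = 1L) {
  method <- match.arg(method)
  if (length(genotype_counts) == 0L || sum(genotype_counts) == 0L)
    stop("need at least one genotype")
  pairs <- parse_geno_names(names(genotype_counts))
  alleles <- sort(unique(as.vector(pairs)))
  k <- length(alleles)
  if (k == 1L) return(list(p = 1.0, method = "monomorphic"))
  n <- sum(genotype_counts)
  # allele counts
  m <- stats::setNames(numeric(k), alleles)
  for (r in seq_len(nrow(pairs))) {
    m[pairs[r, 1L]] <- m[pairs[r, 1L]] + genotype_counts[[r]]
    m[pairs[r, 2L]] <- m[pairs[r, 2L]] + genotype_counts[[r]]
  }
  # canonical list of all unordered genotype categories
  cat_a <- integer(0); cat_b <- integer(0)
  for (i in seq_len(k)) for (j in i:k) {
    cat_a <- c(cat_a, i); cat_b <- c(cat_b, j)
  }
  het_mask <- as.numeric(cat_a != cat_b)
  obs <- numeric(length(cat_a))
  for (r in seq_len(nrow(pairs))) {
    i <- match(pairs[r, 1L], alleles); j <- match(pairs[r, 2L], alleles)
    idx <- which((cat_a == min(i, j)) & (cat_b == max(i, j)))
    obs[idx] <- obs[idx] + genotype_counts[[r]]
  }
  lp_obs <- hwe_log_prob(obs, m, n, het_mask)
  if (method == "auto")
    method <- if (k <= 3L || (k <= 4L && n <= 12L)) "enumerate" else "montecarlo"
  if (method == "enumerate") {
    acc <- new.env()
    acc$p <- 0; acc$tables <- 0L
    recurse <- function(idx, remaining, counts) {
      if (idx > length(cat_a)) {
        if (all(remaining == 0)) {
          lp <- hwe_log_prob(counts, m, n, het_mask)
          acc$tables <- acc$tables + 1L
          if (lp <= lp_obs + 1e-9) acc$p <- acc$p + exp(lp)
        }
        return(invisible())
      }
      i <- cat_a[[idx]]; j <- cat_b[[idx]]
      max_cnt <- if (i == j) remaining[[i]] %/% 2L
        else min(remaining[[i]], remaining[[j]])
      for (cnt in 0:max_cnt) {
        rem <- remaining
        rem[[i]] <- rem[[i]] - cnt * (if (i == j) 2L else 1L)
        if (i != j) rem[[j]] <- rem[[j]] - cnt
        counts[[idx]] <- cnt
        recurse(idx + 1L, rem, counts)
      }
    }
    recurse(1L, m, numeric(length(cat_a)))
    return(list(p = min(1, acc$p), method = "enumerate",
                n_tables = acc$tables))
  }
  # Monte Carlo: shuffle the 2n allele copies and pair consecutively
  set.seed(seed)
  allele_vec <- rep(seq_len(k), times = m)
  hits <- 0L
  for (b in seq_len(B)) {
    perm <- sample(allele_vec)
    i <- pmin(perm[c(TRUE, FALSE)], perm[c(FALSE, TRUE)])
    j <- pmax(perm[c(TRUE, FALSE)], perm[c(FALSE, TRUE)])
    counts <- numeric(length(cat_a))
    key <- match(paste(i, j), paste(cat_a, cat_b))
    tb <- table(key)
    counts[as.integer(names(tb))] <- as.integer(tb)
    if (hwe_log_prob(counts, m, n, het_mask) <= lp_obs + 1e-9) hits <- hits + 1L
  }
  list(p = (hits + 1) / (B + 1), method = "montecarlo", B = B)
}

#' McDonald-Kreitman test counts from a 2x2 table
#'
#' @param Ps,Pn polymorphic synonymous / nonsynonymous changes.
#' @param Ds,Dn fixed synonymous / nonsynonymous changes.
#' @return list of class `mk_result`: `table` (2x2), `fisher_p`,
#'   `neutrality_index` (`(Pn/Ps)/(Dn/Ds)`, `NA` on zero margins).
#' @export
mk_from_counts <- function(Ps, Pn, Ds, Dn) {
  tab <- matrix(c(Ps, Ds, Pn, Dn), nrow = 2,
                dimnames = list(c("polymorphic", "fixed"),
                                c("synonymous", "nonsynonymous")))
  p <- NA_real_
  if (sum(tab[1, ]) > 0 && sum(tab[2, ]) > 0 &&
      sum(tab[, 1]) > 0 && sum(tab[, 2]) > 0)
    p <- stats::fisher.test(round(tab))$p.value
  ni <- if (Ps > 0 && Dn > 0 && Ds > 0) (Pn / Ps) / (Dn / Ds) else NA_real_
  structure(list(table = tab, fisher_p = p, neutrality_index = ni),
            class = "mk_result")
}

#' McDonald-Kreitman neutrality test
#'
#' Classifies each variable nucleotide site as polymorphic (segregating
#' within the ingroup) or fixed (ingroup monomorphic but different from the
#' outgroup), and as synonymous or nonsynonymous in codon context.
#' Polymorphic changes are classified against the ingroup's most frequent
#' codon; fixed changes use pathway-averaged counting between the ingroup
#' consensus codon and that codon with the outgroup bases substituted, so
#' multiply-hit codons are handled consistently with [syn_nonsyn_diffs()].
#' Counts are rounded to integers for the two-sided Fisher exact test.
#'
#' @param ingroup a [codon_alignment()] of the within-population haplotypes.
#' @param outgroup a single aligned outgroup sequence (same length).
#' @return an `mk_result` (see [mk_from_counts()]) with an added `skipped`
#'   count of codons that could not be classified.
#' @export
mk_test <- function(ingroup, outgroup) {
  check_in_frame(ingroup)
  if (length(ingroup$seq) < 2L) stop("need >= 2 ingroup sequences")
  outgroup <- clean_dna(outgroup)
  if (nchar(outgroup) != ingroup$length_nt)
    stop("outgroup length does not match ingroup alignment")
  cols <- codon_columns(ingroup)
  og_aln <- codon_alignment(c(og = outgroup),
                            frame_offset = ingroup$frame_offset)
  og_cols <- codon_columns(og_aln)
  Ps <- 0; Pn <- 0; Ds <- 0; Dn <- 0; skipped <- 0L
  for (ci in seq_along(cols)) {
    ig <- cols[[ci]]
    ig <- ig[vapply(ig, is_clean_codon, logical(1))]
    og <- og_cols[[ci]][[1L]]
    if (length(ig) < 2L || !is_clean_codon(og)) { skipped <- skipped + 1L; next }
    if (any(ig %in% STOP_CODONS) || og %in% STOP_CODONS)
      stop("in-frame stop codon at codon ", ci, "; check frame_offset")
    cons <- names(sort(table(ig), decreasing = TRUE))[[1L]]
    bases <- do.call(rbind, strsplit(ig, ""))
    og_b <- strsplit(og, "")[[1L]]
    fixed_pos <- integer(0)
    for (pos in 1:3) {
      states <- unique(bases[, pos])
      if (length(states) >= 2L) {
        major <- substr(cons, pos, pos)
        for (s in setdiff(states, major)) {
          mut <- cons
          substr(mut, pos, pos) <- s
          if (mut %in% STOP_CODONS ||
              translate_codon(mut) != translate_codon(cons)) Pn <- Pn + 1
          else Ps <- Ps + 1
        }
      } else if (states != og_b[[pos]]) {
        fixed_pos <- c(fixed_pos, pos)
      }
    }
    if (length(fixed_pos)) {
      target <- cons
      for (pos in fixed_pos) substr(target, pos, pos) <- og_b[[pos]]
      dd <- syn_nonsyn_diffs(cons, target)
      if (anyNA(dd)) skipped <- skipped + 1L
      else { Ds <- Ds + dd[["sd"]]; Dn <- Dn + dd[["nd"]] }
    }
  }
  res <- mk_from_counts(Ps, Pn, Ds, Dn)
  res$skipped <- skipped
  res
}

#' @export
print.mk_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("Fisher p = %s; neutrality index = %s\n",
              format(x$fisher_p), format(x$neutrality_index)))
  invisible(x)
}

#' Hudson-Kreitman-Aguade multi-locus neutrality test
#'
#' Fits per-locus scaled mutation rates `theta_i` (per site) and a common
#' divergence time `T` to the observed segregating-site and divergence counts
#' by minimising the HKA goodness-of-fit statistic
#' `X^2 = sum_i (S_i - E[S_i])^2/Var[S_i] + (D_i - E[D_i])^2/Var[D_i]`
#' with `E[S_i] = theta_i a1(n_i) L_i`, `Var[S_i] = E[S_i] + (theta_i L_i)^2
#' a2(n_i)`, `E[D_i] = theta_i L_i_div (T + 1)` and `Var[D_i] = E[D_i] +
#' (theta_i L_i_div)^2`.  The statistic is referred to a chi-square with
#' (number of loci - 1) degrees of freedom.
#'
#' @param loci data.frame with columns `S` (segregating sites), `n` (sample
#'   size), `L` (sites surveyed for polymorphism), `D` (mean divergence count
#'   to the outgroup) and optionally `L_div` (sites surveyed for divergence;
#'   defaults to `L`).
#' @return list of class `hka_result`: `theta_hat` (per site), `T_hat`,
#'   `expected` (data.frame of E[S], E[D]), `chi_square`, `df`, `p`.
#' @export
hka_test <- function(loci) {
  need <- c("S", "n", "L", "D")
  if (!all(need %in% names(loci))) stop("loci needs columns S, n, L, D")
  if (nrow(loci) < 2L) stop("HKA needs >= 2 loci")
  if (is.null(loci$L_div)) loci$L_div <- loci$L
  a1 <- vapply(loci$n, a1_const, numeric(1))
  a2 <- vapply(loci$n, a2_const, numeric(1))
  nl <- nrow(loci)
  x2_of <- function(par) {
    theta <- exp(par[seq_len(nl)])
    Tdiv <- exp(par[[nl + 1L]])
    ES <- theta * a1 * loci$L
    VS <- ES + (theta * loci$L)^2 * a2
    ED <- theta * loci$L_div * (Tdiv + 1)
    VD <- ED + (theta * loci$L_div)^2
    sum((loci$S - ES)^2 / VS + (loci$D - ED)^2 / VD)
  }
  theta0 <- pmax(loci$S, 0.5) / (a1 * loci$L)
  T0 <- max(mean(loci$D / (theta0 * loci$L_div)) - 1, 0.05)
  par0 <- log(c(theta0, T0))
  fit <- stats::optim(par0, x2_of, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  fit <- stats::optim(fit$par, x2_of, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  if (!fit$convergence %in% c(0L)) {
    theta <- exp(fit$par[seq_len(nl)])
    stop("HKA fit did not converge; residual X^2 = ", signif(fit$value, 4),
         " at theta = ", paste(signif(theta, 3), collapse = ", "))
  }
  theta <- exp(fit$par[seq_len(nl)])
  Tdiv <- exp(fit$par[[nl + 1L]])
  ES <- theta * a1 * loci$L
  ED <- theta * loci$L_div * (Tdiv + 1)
  x2 <- fit$value
  df <- nl - 1L
  structure(list(theta_hat = theta, T_hat = Tdiv,
                 expected = data.frame(E_S = ES, E_D = ED),
                 chi_square = x2, df = df,
                 p = stats::pchisq(x2, df, lower.tail = FALSE)),
            class = "hka_result")
}

#' @export
print.hka_result <- function(x, ...) {
  cat(sprintf("HKA: X^2 = %.4f, df = %d, p = %.4f (T_hat = %.3f)\n",
              x$chi_square, x$df, x$p, x$T_hat))
  invisible(x)
}

#' Counting-based per-codon selection scan
#'
#' A transparent, SLAC-like analog of codon-model selection tests: for each
#' codon column, synonymous and nonsynonymous differences are summed over all
#' sequence pairs (pathway-averaged), the expected synonymous proportion is
#' taken from the column's mean Nei-Gojobori site counts, and a two-sided
#' binomial test compares the observed nonsynonymous count against that
#' expectation.  Codons with a nonsynonymous excess at `p <= alpha` are
#' classified `positive`, a synonymous excess `negative`, otherwise
#' `neutral`.  Counts are rounded to integers for the binomial test.
#'
#' @param alignment an in-frame [codon_alignment()] with >= 3 sequences.
#' @param annotations optional data.frame (`codon_index`, `is_hvr`,
#'   `is_abs`) joined onto the result; see [read_site_annotations()].
#' @param alpha significance level (default 0.05).
#' @param p_adjust multiple-testing adjustment passed to
#'   [stats::p.adjust()] (default `"none"`, matching per-site reporting).
#' @return data.frame: `codon_index`, `syn_diffs`, `nonsyn_diffs`,
#'   `expected_syn_prop`, `p`, `classification`, plus `is_hvr`/`is_abs` when
#'   annotations are given.
#' @export
site_selection_scan <- function(alignment, annotations = NULL, alpha = 0.05,
                                p_adjust = "none") {
  check_in_frame(alignment)
  if (length(alignment$seq) < 3L) stop("need >= 3 sequences")
  cols <- codon_columns(alignment)
  out <- data.frame(codon_index = seq_along(cols), syn_diffs = 0,
                    nonsyn_diffs = 0, expected_syn_prop = NA_real_,
                    p = 1, classification = "neutral",
                    stringsAsFactors = FALSE)
  for (ci in seq_along(cols)) {
    col <- cols[[ci]]
    clean <- col[vapply(col, is_clean_codon, logical(1))]
    if (any(clean %in% STOP_CODONS))
      stop("in-frame stop codon at codon ", ci, "; check frame_offset")
    if (length(clean) < 2L) next
    s_sites <- vapply(clean, function(cd) syn_nonsyn_sites(cd)[["s"]],
                      numeric(1))
    out$expected_syn_prop[[ci]] <- mean(s_sites) / 3
    sd_tot <- 0; nd_tot <- 0
    kk <- length(clean)
    for (i in seq_len(kk - 1L)) for (j in (i + 1L):kk) {
      dd <- syn_nonsyn_diffs(clean[[i]], clean[[j]])
      if (anyNA(dd)) next
      sd_tot <- sd_tot + dd[["sd"]]; nd_tot <- nd_tot + dd[["nd"]]
    }
    out$syn_diffs[[ci]] <- sd_tot
    out$nonsyn_diffs[[ci]] <- nd_tot
    total <- round(sd_tot + nd_tot)
    if (total > 0) {
      p0_nonsyn <- 1 - out$expected_syn_prop[[ci]]
      bt <- stats::binom.test(round(nd_tot), total, p0_nonsyn)
      out$p[[ci]] <- bt$p.value
    }
  }
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  tot <- out$syn_diffs + out$nonsyn_diffs
  exp_nonsyn <- (1 - out$expected_syn_prop) * tot
  out$classification <- ifelse(
    tot > 0 & out$p_adj <= alpha & out$nonsyn_diffs > exp_nonsyn, "positive",
    ifelse(tot > 0 & out$p_adj <= alpha & out$nonsyn_diffs < exp_nonsyn,
           "negative", "neutral"))
  if (!is.null(annotations)) {
    idx <- match(out$codon_index, annotations$codon_index)
    out$is_hvr <- annotations$is_hvr[idx]
    out$is_abs <- annotations$is_abs[idx]
    out$is_hvr[is.na(out$is_hvr)] <- FALSE
    out$is_abs[is.na(out$is_abs)] <- FALSE
  }
  out
}

#' Read a codon annotation table (hypervariable regions, antigen-binding
#' sites)
#'
#' @param path TSV with columns `codon_index`, `is_hvr`, `is_abs` (logical or
#'   0/1).
#' @return data.frame with those columns.
#' @export
read_site_annotations <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("codon_index", "is_hvr", "is_abs")
  if (!all(need %in% names(a)))
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  a$is_hvr <- as.logical(a$is_hvr)
  a$is_abs <- as.logical(a$is_abs)
  a[need]
}
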