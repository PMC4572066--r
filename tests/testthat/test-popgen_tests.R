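test_that("observed heterozygosity and the homozygote rule line up", {
  g <- list(i1 = list(L = c(1L, 2L)), i2 = list(L = 1L), i3 = list(L = 2L))
  h <- heterozygosity(g, "L")
  expect_equal(h$H_o, 1 / 3)
  expect_identical(h$n_het + h$n_hom, 3L)
  # alleles: {1,2},{1,1},{2,2} -> p = 0.5; unbiased He = (6/5)(1-0.5) = 0.6
  expect_equal(h$H_e, 0.6)
  # all individuals single-haplotype
  g2 <- list(i1 = list(L = 1L), i2 = list(L = 1L))
  expect_equal(heterozygosity(g2, "L")$H_o, 0)
  expect_error(heterozygosity(list(i1 = list(L = integer(0))), "L"),
               "no individual")
})

test_that("the Welsh cohort heterozygosity mirrors the published counts", {
  g <- welsh_genotypes()
  h_all <- heterozygosity(g, "all")
  # 2 of 18 individuals carried a single haplotype overall (11%)
  expect_equal(h_all$het_by_homozygote_rule, 16 / 18)
  expect_identical(h_all$n_hom, 2L)
  h_dab <- heterozygosity(g, "DAB")
  expect_identical(h_dab$n_genotyped, 18L)       # DAB present in everyone
  expect_identical(h_dab$n_excluded_supernumerary, 3L)  # three-haplotype frogs
})

test_that("supernumerary individuals are excluded from diploid He/HWE only", {
  g <- list(i1 = list(L = c(1L, 2L, 3L)), i2 = list(L = 1L),
            i3 = list(L = c(1L, 2L)))
  h <- heterozygosity(g, "L")
  expect_equal(h$H_o, 2 / 3)            # i1 and i3 are heterozygous
  expect_identical(h$n_excluded_supernumerary, 1L)
  # He from i2 (1,1) and i3 (1,2): p1 = 3/4
  expect_equal(h$H_e, (4 / 3) * (1 - (9 / 16 + 1 / 16)))
})

test_that("HWE exact p equals full enumeration on all 2-allele cases, n <= 6", {
  for (n in 2:6) {
    for (nAB in 0:n) for (nAA in 0:((n - nAB))) {
      nBB <- n - nAB - nAA
      counts <- c("A/A" = nAA, "A/B" = nAB, "B/B" = nBB)
      counts <- counts[counts > 0]
      if (length(counts) == 0) next
      alleles_present <- unique(unlist(strsplit(names(counts), "/")))
      res <- hwe_exact(counts, method = "enumerate")
      if (length(alleles_present) == 1) {
        expect_equal(res$p, 1.0)
        next
      }
      # independent enumeration over (nAA', nAB', nBB') with fixed margins
      mA <- 2 * nAA + nAB; mB <- 2 * nBB + nAB
      lp <- function(ab) {
        aa <- (mA - ab) / 2; bb <- (mB - ab) / 2
        lgamma(n + 1) + ab * log(2) + lgamma(mA + 1) + lgamma(mB + 1) -
          lgamma(2 * n + 1) - lgamma(aa + 1) - lgamma(ab + 1) - lgamma(bb + 1)
      }
      abs_ok <- Filter(function(ab) (mA - ab) >= 0 && (mB - ab) >= 0 &&
                         (mA - ab) %% 2 == 0, 0:min(mA, mB))
      probs <- vapply(abs_ok, lp, numeric(1))
      p_oracle <- sum(exp(probs[probs <= lp(nAB) + 1e-9]))
      expect_equal(res$p, p_oracle, tolerance = 1e-9,
                   info = sprintf("n=%d AA=%d AB=%d BB=%d", n, nAA, nAB, nBB))
    }
  }
})

test_that("Monte-Carlo HWE agrees with enumeration within 3 standard errors", {
  cases <- list(c("A/A" = 2, "A/B" = 1, "B/B" = 3),
                c("A/B" = 4),
                c("A/A" = 1, "B/B" = 2, "A/B" = 3))
  for (counts in cases) {
    pe <- hwe_exact(counts, method = "enumerate")$p
    B <- 2e4
    pm <- hwe_exact(counts, method = "montecarlo", B = B, seed = 3)$p
    se <- sqrt(pe * (1 - pe) / B)
    expect_lt(abs(pm - pe), 3 * se + 2 / B)
  }
  # three-allele case: enumeration still exact, MC consistent
  tri <- c("A/B" = 2, "B/C" = 2, "A/C" = 2)
  pe <- hwe_exact(tri, method = "enumerate")$p
  pm <- hwe_exact(tri, method = "montecarlo", B = 2e4, seed = 5)$p
  expect_lt(abs(pm - pe), 3 * sqrt(pe * (1 - pe) / 2e4) + 1e-4)
  expect_equal(hwe_exact(c("A/A" = 7))$p, 1.0)  # monomorphic
})

test_that("MK Fisher p equals hypergeometric enumeration and is symmetric", {
  res <- mk_from_counts(Ps = 7, Pn = 2, Ds = 2, Dn = 7)
  expect_equal(res$fisher_p, oracle_fisher2x2(7, 2, 2, 7), tolerance = 1e-12)
  expect_equal(res$neutrality_index, (2 / 7) / (7 / 2))
  # swapping the row labels leaves p unchanged
  expect_equal(mk_from_counts(2, 7, 7, 2)$fisher_p, res$fisher_p)
  set.seed(19)
  for (i in 1:10) {
    tb <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
    expect_equal(mk_from_counts(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])$fisher_p,
                 oracle_fisher2x2(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                 tolerance = 1e-9)
  }
  # empty margins leave the test undefined
  expect_true(is.na(mk_from_counts(0, 0, 2, 7)$fisher_p))
})

test_that("MK classification sees polymorphism vs fixation in codon context", {
  # ingroup monomorphic and identical to outgroup: all counts 0
  ig <- codon_alignment(c(a = "ATGTTT", b = "ATGTTT"))
  res0 <- mk_test(ig, "ATGTTT")
  expect_true(all(res0$table == 0))
  expect_true(is.na(res0$fisher_p))
  # one synonymous polymorphism, one nonsynonymous fixed difference
  ig2 <- codon_alignment(c(a = "TTTAAA", b = "TTCAAA"))
  res2 <- mk_test(ig2, "TTTGAA")   # AAA(K) vs GAA(E) fixed nonsyn
  expect_equal(res2$table["polymorphic", "synonymous"], 1)
  expect_equal(res2$table["fixed", "nonsynonymous"], 1)
  expect_equal(sum(res2$table), 2)
})

test_that("HKA gives a perfect fit X^2 of 0 and is order invariant", {
  n <- c(18, 18); L <- c(192, 500)
  theta <- c(0.02, 0.005); Tdiv <- 3
  a1 <- vapply(n, function(k) sum(1 / seq_len(k - 1)), numeric(1))
  loci <- data.frame(S = theta * a1 * L, n = n, L = L,
                     D = theta * L * (Tdiv + 1))
  res <- hka_test(loci)
  expect_lt(res$chi_square, 1e-8)
  expect_equal(res$p, 1, tolerance = 1e-4)
  expect_identical(res$df, 1L)
  expect_equal(res$theta_hat, theta, tolerance = 1e-3)
  res_rev <- hka_test(loci[2:1, ])
  expect_equal(res_rev$chi_square, res$chi_square, tolerance = 1e-6)
})

test_that("HKA type-I error is near nominal on neutral two-locus data", {
  # neutral simulation: S from the coalescent; D Poisson around theta*L*(T+t)
  # with t ~ Exp(1), matching the HKA divergence variance model
  set.seed(90)
  reps <- 500; Tdiv <- 5
  thetaL <- c(4, 8); L <- c(400, 800); n <- 12
  rej <- 0; used <- 0
  for (r in 1:reps) {
    S <- vapply(1:2, function(i)
      diversity(coalescent_sample(n, thetaL[i] / L[i], L[i],
                                  seed = 7000 + 2 * r + i),
                codon_aware = FALSE)$S, numeric(1))
    D <- vapply(1:2, function(i)
      stats::rpois(1, thetaL[i] * (Tdiv + stats::rexp(1))), numeric(1))
    res <- try(hka_test(data.frame(S = S, n = n, L = L, D = D)), silent = TRUE)
    if (inherits(res, "try-error")) next
    used <- used + 1
    if (res$p <= 0.05) rej <- rej + 1
  }
  expect_gt(used, 0.95 * reps)
  ci <- stats::binom.test(rej, used, 0.05)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2] || rej / used < 0.05,
              info = sprintf("rejections %d / %d", rej, used))
})

test_that("selection scan classifies constructed columns correctly", {
  # invariant alignment: all neutral, p = 1
  aln <- codon_alignment(stats::setNames(rep("ATGAAA", 4), paste0("s", 1:4)))
  scan <- site_selection_scan(aln)
  expect_true(all(scan$classification == "neutral"))
  expect_true(all(scan$p == 1))
  # third-position synonymous variation can never be called positive
  syn_col <- codon_alignment(c(a = "TTT", b = "TTC", c = "TTA", d = "TTG"))
  s2 <- site_selection_scan(syn_col)
  expect_false(any(s2$classification == "positive"))
  # strong nonsynonymous excess across a column is flagged positive
  pos_col <- codon_alignment(c(a = "CTTGCT", b = "ATTGCT", c = "GTTGCT",
                               d = "TTTGCT", e = "CCTGCT", f = "ACTGCT"))
  s3 <- site_selection_scan(pos_col)
  expect_identical(s3$classification[1], "positive")
  expect_identical(s3$classification[2], "neutral")
  # and a synonymous excess is flagged negative
  neg_col <- codon_alignment(stats::setNames(
    paste0(rep(c("TCT", "TCC", "TCA", "TCG"), 2), "GCT"), paste0("s", 1:8)))
  expect_identical(site_selection_scan(neg_col)$classification[1], "negative")
})

test_that("scan binomial p matches a direct tail computation", {
  # one codon column with 10 pairwise nonsyn differences, 0 syn; expectation
  # from the column's mean synonymous site fraction
  aln <- codon_alignment(c(a = "CAT", b = "GAT", c = "AAT", d = "TAT",
                           e = "CAT"))
  scan <- site_selection_scan(aln)
  x <- round(scan$nonsyn_diffs[1]); n <- round(scan$nonsyn_diffs[1] +
                                                 scan$syn_diffs[1])
  p0 <- 1 - scan$expected_syn_prop[1]
  expect_equal(scan$p[1], stats::binom.test(x, n, p0)$p.value,
               tolerance = 1e-12)
  # annotations join on codon index
  ann <- data.frame(codon_index = 1L, is_hvr = TRUE, is_abs = FALSE)
  s_ann <- site_selection_scan(aln, annotations = ann)
  expect_true(s_ann$is_hvr[1])
  expect_false(s_ann$is_abs[1])
})

test_that("in-frame stop codons abort codon-aware statistics loudly", {
  aln <- codon_alignment(c(a = "TAAAAA", b = "TACAAA", c = "TATAAA"))
  expect_error(site_selection_scan(aln), "stop codon")
  expect_error(mk_test(codon_alignment(c(a = "TAAAAA", b = "TAAAAA")),
                       "TACAAA"), "stop codon")
})
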