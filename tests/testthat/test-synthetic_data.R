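test_that("sim_config validates its parameters and presets pass", {
  expect_error(sim_config(5, list(list(name = "L", presence_prob = 1,
                                       allele_count = 2,
                                       within_divergence = 0.01)),
                          0.1, 10, 5, 10), "seed")
  expect_error(scenario_presets()$welsh_like$foo, NA)
  cfg <- scenario_presets(seed = 2)$welsh_like
  expect_s3_class(cfg, "sim_config")
  expect_identical(cfg$n_individuals, 18L)
  expect_identical(cfg$clones_min, 14L)
  expect_identical(cfg$clones_max, 21L)
  expect_identical(length(cfg$loci), 3L)
})

test_that("allele pools are deterministic, stop-free and locus-structured", {
  cfg <- scenario_presets(seed = 31)$welsh_like
  p1 <- generate_allele_pool(cfg)
  p2 <- generate_allele_pool(cfg)
  expect_identical(p1, p2)
  # no in-frame stops anywhere
  for (s in p1$alignment)
    expect_false(grepl("\\*", translate_dna(s)))
  # within_divergence = 0 collapses a locus to identical alleles
  cfg0 <- cfg
  cfg0$loci[[1]]$within_divergence <- 0
  p0 <- generate_allele_pool(cfg0)
  dab <- p0$alignment[p0$locus_of == "DAB"]
  expect_identical(length(unique(dab)), 1L)
  # between-locus exceeds within-locus distance
  d <- p_distance_matrix(p1$alignment)
  wb <- within_between_locus_distances(
    d, data.frame(haplotype = names(p1$locus_of),
                  locus = unname(p1$locus_of), stringsAsFactors = FALSE))
  expect_gt(min(wb[upper.tri(wb)]), max(diag(wb)))
})

test_that("between-locus divergence matches the substitution expectation", {
  # two sequences mutated independently from one ancestor at rate r differ
  # at a site unless both changed to the same base: expected p-distance
  # 2r(1-r) + r^2 * 2/3
  r <- 0.15
  exp_d <- 2 * r * (1 - r) + r^2 * 2 / 3
  cfg <- sim_config(2, list(
    list(name = "A", presence_prob = 1, allele_count = 1,
         within_divergence = 0),
    list(name = "B", presence_prob = 1, allele_count = 1,
         within_divergence = 0)),
    between_divergence = r, length_codons = 200, clones_min = 5,
    clones_max = 5, seed = 1)
  ds <- vapply(1:60, function(s) {
    cfg$seed <- s
    p <- generate_allele_pool(cfg)
    p_distance_matrix(p$alignment)[1, 2]
  }, numeric(1))
  expect_lt(abs(mean(ds) - exp_d) / exp_d, 0.1)
})

test_that("genotypes respect presence probabilities and HWE proportions", {
  cfg <- scenario_presets(seed = 8)$welsh_like
  cfg$loci[[2]]$presence_prob <- 0
  pool <- generate_allele_pool(cfg)
  g <- generate_genotypes(cfg, pool)
  expect_true(all(vapply(g, function(x) length(x$DBB) == 0, logical(1))))
  expect_true(all(vapply(g, function(x) length(x$DAB) > 0, logical(1))))
  # homozygote fraction at a 2-allele locus with p = 0.5 approaches 1/2
  cfg2 <- sim_config(800, list(
    list(name = "L", presence_prob = 1, allele_count = 2,
         within_divergence = 0.02)),
    between_divergence = 0.1, length_codons = 30, clones_min = 5,
    clones_max = 5, seed = 40)
  g2 <- generate_genotypes(cfg2, generate_allele_pool(cfg2))
  hom <- mean(vapply(g2, function(x) length(x$L) == 1, logical(1)))
  ci <- stats::binom.test(round(hom * 800), 800, 0.5)$conf.int
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
})

test_that("clones are faithful copies when chimera and error rates are zero", {
  cfg <- scenario_presets(seed = 14)$welsh_like
  cfg$chimera_rate <- 0; cfg$error_rate <- 0
  ch <- simulate_cohort(cfg)
  validate_truth(ch)
  for (id in names(ch$genotypes)) {
    tpl <- ch$pool$alignment[unique(unlist(ch$genotypes[[id]]))]
    cl <- ch$clones[ch$clone_map$clone_id[ch$clone_map$individual_id == id]]
    expect_true(all(cl %in% tpl), info = id)
    expect_true(length(cl) >= cfg$clones_min && length(cl) <= cfg$clones_max)
  }
  expect_true(all(ch$provenance$type == "template"))
})

test_that("chimera emission rate matches its binomial expectation", {
  n_chim <- 0; n_tot <- 0
  for (s in 1:8) {
    cfg <- scenario_presets(seed = 400 + s)$welsh_like
    cfg$chimera_rate <- 0.1
    ch <- simulate_cohort(cfg)
    n_chim <- n_chim + sum(ch$provenance$type == "chimera")
    n_tot <- n_tot + nrow(ch$provenance)
  }
  ci <- stats::binom.test(n_chim, n_tot, 0.1)$conf.int
  expect_true(ci[1] <= 0.1 && 0.1 <= ci[2],
              info = sprintf("%d / %d", n_chim, n_tot))
  # chimeric clones never reproduce a true haplotype of their individual
  cfg <- scenario_presets(seed = 26)$welsh_like
  cfg$chimera_rate <- 0.2
  ch <- simulate_cohort(cfg)
  chim <- ch$provenance[ch$provenance$type == "chimera", ]
  for (r in seq_len(nrow(chim))) {
    tpl <- ch$pool$alignment[unique(unlist(ch$genotypes[[chim$individual_id[r]]]))]
    expect_false(ch$clones[[chim$clone_id[r]]] %in% tpl)
  }
})

test_that("base errors are recorded in the provenance", {
  cfg <- scenario_presets(seed = 33)$welsh_like
  cfg$chimera_rate <- 0; cfg$error_rate <- 0.005
  ch <- simulate_cohort(cfg)
  errs <- ch$provenance$error_positions != ""
  expect_true(any(errs))
  r <- which(errs)[1]
  tpl <- ch$pool$alignment[[ch$provenance$source[r]]]
  emitted <- ch$clones[[ch$provenance$clone_id[r]]]
  pos <- as.integer(strsplit(ch$provenance$error_positions[r], ",")[[1]])
  diffs <- which(strsplit(tpl, "")[[1]] != strsplit(emitted, "")[[1]])
  expect_identical(diffs, pos)
})

test_that("same seed gives byte-identical cohorts", {
  cfg <- scenario_presets(seed = 99)$welsh_like
  cfg$error_rate <- 0.001
  ch1 <- simulate_cohort(cfg)
  ch2 <- simulate_cohort(cfg)
  expect_identical(ch1$clones, ch2$clones)
  expect_identical(ch1$provenance, ch2$provenance)
})

test_that("coalescent samples match Watterson and pairwise expectations", {
  # theta = 0: all identical
  aln0 <- coalescent_sample(6, 0, 60, seed = 1)
  expect_identical(length(unique(unname(aln0$seq))), 1L)
  n <- 18; L <- 500; thetaL <- 5
  a1 <- sum(1 / seq_len(n - 1))
  S <- numeric(400); Pi <- numeric(400)
  for (r in seq_len(400)) {
    d <- diversity(coalescent_sample(n, thetaL / L, L, seed = 5000 + r),
                   codon_aware = FALSE)
    S[r] <- d$S; Pi[r] <- d$mean_pairwise_diff
  }
  expect_lt(abs(mean(S) / (thetaL * a1) - 1), 0.05)
  expect_lt(abs(mean(Pi) / thetaL - 1), 0.05)
  # infinite-sites overflow is an error, not silent wrap-around
  expect_error(coalescent_sample(10, 10, 4, seed = 3), "infinite-sites")
})

test_that("truth validation catches broken cross-references", {
  cfg <- scenario_presets(seed = 3)$welsh_like
  ch <- simulate_cohort(cfg)
  broken <- ch
  broken$provenance$clone_id[1] <- "nonexistent|c99"
  expect_error(validate_truth(broken), "1:1")
  broken2 <- ch
  broken2$genotypes[[1]]$DAB <- c(broken2$genotypes[[1]]$DAB, "ZZZ_a9")
  expect_error(validate_truth(broken2), "unknown pool")
})
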