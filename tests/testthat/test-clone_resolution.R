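mk_clone_set <- function(id, seqs_with_counts) {
  seqs <- rep(names(seqs_with_counts), times = seqs_with_counts)
  clone_set(id, stats::setNames(seqs, sprintf("%s|c%02d", id, seq_along(seqs))))
}

test_that("collapse_clones groups exact sequences and orders by support", {
  cs <- mk_clone_set("i1", c(ACGTAC = 18))
  vt <- collapse_clones(cs)
  expect_identical(nrow(vt), 1L)
  expect_identical(vt$support, 18L)

  cs <- mk_clone_set("i2", c(AAAAAA = 10, CCCCCC = 5, GGGGGG = 1))
  vt <- collapse_clones(cs)
  expect_identical(vt$support, c(10L, 5L, 1L))
  # shuffled clone order gives an identical table
  set.seed(4)
  shuffled <- clone_set("i2", sample(cs$clones))
  expect_identical(as.data.frame(collapse_clones(shuffled)),
                   as.data.frame(vt))
})

test_that("a constructed single-crossover mosaic is called with its breakpoint", {
  L <- 192
  set.seed(9)
  A <- paste(sample(c("A", "C"), L, TRUE), collapse = "")
  B <- paste(sample(c("G", "T"), L, TRUE), collapse = "")
  v <- paste0(substr(A, 1, 96), substr(B, 97, L))
  vt <- collapse_clones(mk_clone_set("i1", stats::setNames(c(8, 7, 1),
                                                           c(A, B, v))))
  calls <- detect_chimeras(vt)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$sequence, v)
  expect_identical(calls$breakpoint_nt, 96L)
  expect_identical(calls$n_mismatches, 0L)
})

test_that("chimera detection needs a third sequence and respects support order", {
  vt <- collapse_clones(mk_clone_set("i1", c(AAAAAA = 9, TTTTTT = 9)))
  expect_identical(nrow(detect_chimeras(vt)), 0L)
  # the mosaic is not called when it out-supports a putative parent
  A <- "AAAAAA"; B <- "TTTTTT"; v <- "AAATTT"
  vt <- collapse_clones(mk_clone_set("i2", stats::setNames(c(8, 2, 5),
                                                           c(A, B, v))))
  expect_identical(nrow(detect_chimeras(vt)), 0L)
})

test_that("chimera calls agree with exhaustive breakpoint enumeration", {
  cfg <- scenario_presets(seed = 5)$welsh_like
  cfg$chimera_rate <- 0.1
  ch <- simulate_cohort(cfg)
  sets <- split_clone_sets(ch$clones, ch$clone_map)
  for (id in names(sets)) {
    vt <- collapse_clones(sets[[id]])
    calls <- detect_chimeras(vt)
    for (k in seq_len(nrow(vt))) {
      v <- vt$sequence[k]
      called <- v %in% calls$sequence
      oracle <- oracle_is_chimera(v, vt$support[k], vt$sequence[-k],
                                  vt$support[-k])
      # the pass exempts variants that themselves serve as parents
      if (!called && oracle)
        expect_true(paste0("v", k) %in% c(calls$parent_a, calls$parent_b),
                    info = paste(id, k))
      else expect_identical(called, oracle, info = paste(id, k))
    }
  }
})

test_that("singleton rule: lone variants need cross-individual support", {
  A <- "AAAAAA"; B <- "CCCCCC"; C <- "GGGGGG"
  vts <- list(
    collapse_clones(mk_clone_set("i1", stats::setNames(c(5, 1), c(A, B)))),
    collapse_clones(mk_clone_set("i2", stats::setNames(c(4, 3), c(A, C)))))
  cat <- call_haplotypes(vts)
  # B was a singleton seen only in i1: absent from the catalog
  expect_false(B %in% cat$haplotypes$sequence)
  expect_true(all(c(A, C) %in% cat$haplotypes$sequence))

  # singleton in i1 rescued by 3 clones in i2
  vts2 <- list(
    collapse_clones(mk_clone_set("i1", stats::setNames(c(5, 1), c(A, B)))),
    collapse_clones(mk_clone_set("i2", stats::setNames(c(4, 3), c(A, B)))))
  cat2 <- call_haplotypes(vts2)
  expect_true(B %in% cat2$haplotypes$sequence)
  expect_identical(cat2$per_individual$i1, cat2$per_individual$i2)
})

test_that("a cohort sharing one well-supported sequence yields one haplotype", {
  A <- "ACACAC"
  vts <- lapply(paste0("i", 1:5), function(id)
    collapse_clones(mk_clone_set(id, stats::setNames(18, A))))
  cat <- call_haplotypes(vts)
  expect_identical(nrow(cat$haplotypes), 1L)
  expect_true(all(vapply(cat$per_individual, identical, logical(1), 1L)))
})

test_that("catalog is invariant to individual and clone ordering and never
           contains a flagged sequence", {
  cfg <- scenario_presets(seed = 12)$welsh_like
  cfg$chimera_rate <- 0.08
  ch <- simulate_cohort(cfg)
  sets <- split_clone_sets(ch$clones, ch$clone_map)
  vts <- lapply(sets, collapse_clones)
  chim <- lapply(vts, detect_chimeras)
  cat1 <- call_haplotypes(vts, chim)
  flagged <- unlist(lapply(chim, function(cc) cc$sequence))
  expect_false(any(flagged %in% cat1$haplotypes$sequence))
  # reversed individual order
  cat2 <- call_haplotypes(rev(vts), rev(chim))
  expect_identical(cat1$haplotypes, cat2$haplotypes)
  expect_identical(cat1$per_individual[names(cat2$per_individual)],
                   cat2$per_individual)
})

test_that("saturation table handles degenerate and perfect cases", {
  A <- "AAAAAA"; B <- "CCCCCC"; C <- "GGGGGG"
  vts <- list(
    collapse_clones(mk_clone_set("i1", stats::setNames(c(3), A))),
    collapse_clones(mk_clone_set("i2", stats::setNames(c(3, 2), c(A, B)))),
    collapse_clones(mk_clone_set("i3", stats::setNames(c(3, 2, 2),
                                                       c(A, B, C)))))
  cat <- call_haplotypes(vts)
  sat <- saturation_table(cat, vts)
  expect_identical(sat$n_clones, c(3L, 5L, 7L))
  expect_identical(sat$n_haplotypes, c(1L, 2L, 3L))
  expect_equal(attr(sat, "rho"), 1.0)

  # all individuals identical: correlation undefined, flagged
  vts_same <- lapply(paste0("i", 1:4), function(id)
    collapse_clones(mk_clone_set(id, stats::setNames(4, A))))
  sat2 <- saturation_table(call_haplotypes(vts_same), vts_same)
  expect_true(is.na(attr(sat2, "rho")))
  expect_match(attr(sat2, "rho_note"), "zero variance")
  # fewer than 3 individuals: undefined
  sat3 <- saturation_table(call_haplotypes(vts[1:2]), vts[1:2])
  expect_true(is.na(attr(sat3, "rho")))
})

test_that("saturation correlation matches an independent rank computation", {
  cfg <- scenario_presets(seed = 3)$welsh_like
  ch <- simulate_cohort(cfg)
  res <- resolve_cohort(ch$clones, ch$clone_map)
  sat <- res$saturation
  rank_cor <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  expect_equal(attr(sat, "rho"),
               rank_cor(sat$n_clones, sat$n_haplotypes), tolerance = 1e-12)
})
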