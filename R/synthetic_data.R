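# Synthetic cohorts with the statistical structure the analysis assumes:
# paralogous allele pools with higher between- than within-locus divergence,
# presence/absence genotypes drawn under Hardy-Weinberg proportions, clone
# sampling with Dirichlet-multinomial amplification bias, single-crossover
# PCR chimeras and per-base error -- plus a neutral infinite-sites coalescent
# sampler used to calibrate the diversity statistics.

BASES <- c("A", "C", "G", "T")
NONSTOP_CODONS <- setdiff(
  apply(expand.grid(BASES, BASES, BASES), 1L, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

#' Simulation configuration
#'
#' @param n_individuals number of individuals in the cohort.
#' @param loci list of per-locus settings, each a list with `name`,
#'   `presence_prob` (probability the locus is present in an individual),
#'   `allele_count` (alleles in the pool) and `within_divergence`
#'   (substitutions/site from the locus ancestor).
#' @param between_divergence substitutions/site from the global ancestor to
#'   each locus ancestor.
#' @param length_codons amplicon length in codons.
#' @param clones_min,clones_max range of readable clones per individual
#'   (drawn uniformly).
#' @param amplification_bias Dirichlet concentration per template; smaller
#'   values mean stronger per-template amplification bias (and hence more
#'   frequent dropout of true alleles at low clone counts).
#' @param chimera_rate probability a clone is a single-crossover mosaic of
#'   two distinct templates.
#' @param error_rate per-base substitution error probability.
#' @param supernumerary_prob probability a present locus carries a third
#'   distinct allele (copy-number gain); a scalar default applied to loci
#'   that do not set their own `supernumerary_prob` entry.
#' @param seed integer seed (mandatory; all generator randomness derives
#'   from it).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_individuals, loci, between_divergence,
                       length_codons, clones_min, clones_max,
                       amplification_bias = 40, chimera_rate = 0,
                       error_rate = 0, supernumerary_prob = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_individuals >= 1, length(loci) >= 1,
            between_divergence >= 0, between_divergence <= 0.75,
            length_codons >= 1, clones_min >= 1, clones_min <= clones_max,
            amplification_bias > 0, chimera_rate >= 0, chimera_rate <= 1,
            error_rate >= 0, error_rate <= 1,
            supernumerary_prob >= 0, supernumerary_prob <= 1)
  loci <- lapply(loci, function(l) {
    stopifnot(!is.null(l$name), l$presence_prob >= 0, l$presence_prob <= 1,
              l$allele_count >= 1, l$within_divergence >= 0,
              l$within_divergence <= 0.75)
    if (is.null(l$supernumerary_prob)) l$supernumerary_prob <- supernumerary_prob
    stopifnot(l$supernumerary_prob >= 0, l$supernumerary_prob <= 1)
    l
  })
  structure(list(n_individuals = as.integer(n_individuals), loci = loci,
                 between_divergence = between_divergence,
                 length_codons = as.integer(length_codons),
                 clones_min = as.integer(clones_min),
                 clones_max = as.integer(clones_max),
                 amplification_bias = amplification_bias,
                 chimera_rate = chimera_rate, error_rate = error_rate,
                 supernumerary_prob = supernumerary_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Named scenario presets
#'
#' `welsh_like` mirrors the shape of a small closed amphibian cohort: 18
#' individuals; three paralogous loci with presence probabilities 1.0, 0.67
#' and 0.5 and allele counts 4/3/2; within-locus divergence 0.03 and
#' between-locus divergence 0.15 substitutions/site; 64 codons; 14-21
#' readable clones per individual; 3% chimeric clones; no base error.
#'
#' @param seed seed stored in each preset (default 1).
#' @return named list of [sim_config()] objects.
#' @export
scenario_presets <- function(seed = 1L) {
  list(welsh_like = sim_config(
    n_individuals = 18,
    loci = list(
      list(name = "DAB", presence_prob = 1.0, allele_count = 4,
           within_divergence = 0.03, supernumerary_prob = 0.17),
      list(name = "DBB", presence_prob = 0.67, allele_count = 3,
           within_divergence = 0.03),
      list(name = "DCB", presence_prob = 0.5, allele_count = 2,
           within_divergence = 0.03)),
    between_divergence = 0.15, length_codons = 64,
    clones_min = 14, clones_max = 21,
    amplification_bias = 40, chimera_rate = 0.03, error_rate = 0,
    supernumerary_prob = 0, seed = seed))
}

random_nonstop_seq <- function(n_codons) {
  paste(sample(NONSTOP_CODONS, n_codons, replace = TRUE), collapse = "")
}

# substitute each site with probability `rate`, avoiding in-frame stops
mutate_seq <- function(seq, rate, max_retry = 100L) {
  if (rate == 0) return(seq)
  ch <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (p in hit) ch[[p]] <- sample(setdiff(BASES, ch[[p]]), 1L)
  # repair codons that became stops by redrawing their mutated positions
  n_codon <- length(ch) %/% 3L
  for (ci in seq_len(n_codon)) {
    idx <- (3L * ci - 2L):(3L * ci)
    tries <- 0L
    while (paste(ch[idx], collapse = "") %in% c("TAA", "TAG", "TGA")) {
      tries <- tries + 1L
      if (tries > max_retry)
        stop("could not avoid stop codon at codon ", ci,
             " after ", max_retry, " retries; lower the divergence rate")
      redo <- intersect(hit, idx)
      if (length(redo) == 0L) redo <- idx  # stop was pre-existing: impossible
      for (p in redo) {
        orig <- strsplit(seq, "")[[1L]][[p]]
        ch[[p]] <- sample(setdiff(BASES, orig), 1L)
      }
    }
  }
  paste(ch, collapse = "")
}

#' Generate a multi-locus allele pool
#'
#' One ancestor per locus is derived from a shared global ancestor at
#' `between_divergence` substitutions/site; within-locus alleles derive from
#' the locus ancestor at its `within_divergence`.  Substitutions avoid
#' creating in-frame stop codons.  Deterministic under the config seed.
#'
#' @param cfg a [sim_config()].
#' @return list: `alignment` (named character vector of allele sequences),
#'   `locus_of` (named character vector giving each allele's true locus).
#' @export
generate_allele_pool <- function(cfg) {
  set.seed(cfg$seed)
  root <- random_nonstop_seq(cfg$length_codons)
  seqs <- character(0); locus_of <- character(0)
  for (l in cfg$loci) {
    anc <- mutate_seq(root, cfg$between_divergence)
    for (i in seq_len(l$allele_count)) {
      lab <- sprintf("%s_a%d", l$name, i)
      seqs[[lab]] <- mutate_seq(anc, l$within_divergence)
      locus_of[[lab]] <- l$name
    }
  }
  list(alignment = seqs, locus_of = locus_of)
}

#' Generate true per-individual genotypes
#'
#' Per individual and locus: the locus is present with its `presence_prob`;
#' when present, two alleles are drawn uniformly with replacement
#' (Hardy-Weinberg proportions), collapsing to one distinct haplotype when
#' identical; with `supernumerary_prob` a third distinct allele is added when
#' the pool allows.
#'
#' @param cfg a [sim_config()].
#' @param pool a [generate_allele_pool()] result.
#' @return named list: per individual, a named list of per-locus character
#'   vectors of true allele labels.
#' @export
generate_genotypes <- function(cfg, pool) {
  set.seed(cfg$seed + 1L)
  ids <- sprintf("ind%02d", seq_len(cfg$n_individuals))
  out <- lapply(ids, function(id) {
    g <- lapply(cfg$loci, function(l) {
      if (stats::runif(1) >= l$presence_prob) return(character(0))
      alleles <- names(pool$locus_of)[pool$locus_of == l$name]
      draw <- sample(alleles, 2L, replace = TRUE)
      g <- unique(draw)
      if (l$supernumerary_prob > 0 &&
          stats::runif(1) < l$supernumerary_prob) {
        extra <- setdiff(alleles, g)
        if (length(extra)) g <- c(g, sample(extra, 1L))
      }
      sort(g)
    })
    stats::setNames(g, vapply(cfg$loci, `[[`, character(1), "name"))
  })
  stats::setNames(out, ids)
}

# draw one clone count vector with Dirichlet-multinomial bias
dirichlet_weights <- function(k, concentration) {
  w <- stats::rgamma(k, shape = concentration, rate = 1)
  if (sum(w) == 0) w <- rep(1, k)
  w / sum(w)
}

apply_base_error <- function(seq, error_rate) {
  if (error_rate == 0) return(list(seq = seq, positions = integer(0)))
  ch <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(ch)) < error_rate)
  for (p in hit) ch[[p]] <- sample(setdiff(BASES, ch[[p]]), 1L)
  list(seq = paste(ch, collapse = ""), positions = hit)
}

#' Generate cloned amplicon sequences with full provenance
#'
#' Per individual, a uniform number in `[clones_min, clones_max]` of
#' readable non-recombinant clones is drawn (this is the quantity clone-based
#' genotyping studies report; recombinant clones are excluded before
#' counting, so chimeras here are emitted on top of it).  Each clone copies a
#' template drawn from the individual's haplotypes with
#' Dirichlet-multinomial amplification bias; with probability `chimera_rate`
#' an emission is instead a single-crossover mosaic of two distinct templates
#' at a uniform internal breakpoint (redrawn, boundedly, until the mosaic
#' differs from every true haplotype of the individual, since a mosaic
#' identical to a real haplotype is not an observable chimera).  Each emitted
#' base is then flipped with probability `error_rate`.
#'
#' @param cfg a [sim_config()].
#' @param genotypes a [generate_genotypes()] result.
#' @param pool a [generate_allele_pool()] result.
#' @return list: `clones` (named character vector), `clone_map` (data.frame
#'   `clone_id`, `individual_id`), `provenance` (data.frame per clone:
#'   `clone_id`, `individual_id`, `type`, `source`, `breakpoint_nt`,
#'   `error_positions`).
#' @export
generate_clones <- function(cfg, genotypes, pool) {
  set.seed(cfg$seed + 2L)
  L <- 3L * cfg$length_codons
  clones <- character(0)
  map <- list(); prov <- list()
  for (id in names(genotypes)) {
    labs <- unique(unlist(genotypes[[id]]))
    if (length(labs) == 0L) {
      warning("individual ", id, " has an empty genotype; no clones emitted")
      next
    }
    templates <- pool$alignment[labs]
    n_good <- sample(cfg$clones_min:cfg$clones_max, 1L)
    w <- dirichlet_weights(length(labs), cfg$amplification_bias)
    ci <- 0L; emitted_good <- 0L
    while (emitted_good < n_good) {
      ci <- ci + 1L
      cid <- sprintf("%s|c%02d", id, ci)
      is_chim <- length(labs) >= 2L && stats::runif(1) < cfg$chimera_rate
      if (is_chim) {
        made <- NULL
        for (try in seq_len(50L)) {
          par_idx <- sample(seq_along(labs), 2L, replace = FALSE, prob = w)
          b <- sample(seq_len(L - 1L), 1L)
          mosaic <- splice_at(templates[[par_idx[[1L]]]],
                              templates[[par_idx[[2L]]]], b)
          if (!mosaic %in% templates) { made <- list(par_idx, b, mosaic); break }
        }
        if (is.null(made)) is_chim <- FALSE
      }
      if (is_chim) {
        err <- apply_base_error(made[[3L]], cfg$error_rate)
        clones[[cid]] <- err$seq
        prov[[cid]] <- data.frame(
          clone_id = cid, individual_id = id, type = "chimera",
          source = paste(labs[made[[1L]]], collapse = "+"),
          breakpoint_nt = made[[2L]],
          error_positions = paste(err$positions, collapse = ","),
          stringsAsFactors = FALSE)
      } else {
        ti <- sample(seq_along(labs), 1L, prob = w)
        err <- apply_base_error(templates[[ti]], cfg$error_rate)
        clones[[cid]] <- err$seq
        prov[[cid]] <- data.frame(
          clone_id = cid, individual_id = id, type = "template",
          source = labs[[ti]], breakpoint_nt = NA_integer_,
          error_positions = paste(err$positions, collapse = ","),
          stringsAsFactors = FALSE)
        emitted_good <- emitted_good + 1L
      }
      map[[cid]] <- data.frame(clone_id = cid, individual_id = id,
                               stringsAsFactors = FALSE)
    }
  }
  list(clones = clones,
       clone_map = do.call(rbind, c(map, list(make.row.names = FALSE))),
       provenance = do.call(rbind, c(prov, list(make.row.names = FALSE))))
}

#' Run the full generator for one cohort
#'
#' @param cfg a [sim_config()].
#' @return list: `pool`, `genotypes`, `clones`, `clone_map`, `provenance`.
#' @export
simulate_cohort <- function(cfg) {
  pool <- generate_allele_pool(cfg)
  genotypes <- generate_genotypes(cfg, pool)
  cl <- generate_clones(cfg, genotypes, pool)
  list(pool = pool, genotypes = genotypes, clones = cl$clones,
       clone_map = cl$clone_map, provenance = cl$provenance)
}

#' Validate truth-set cross-references
#'
#' Checks that every emitted clone has exactly one provenance record, that
#' every provenance source exists in the pool, and that all true genotype
#' labels exist in the pool.
#'
#' @param cohort a [simulate_cohort()] result.
#' @return `TRUE` (invisibly); inconsistencies are errors.
#' @export
validate_truth <- function(cohort) {
  if (!setequal(names(cohort$clones), cohort$provenance$clone_id) ||
      anyDuplicated(cohort$provenance$clone_id))
    stop("clone ids and provenance records do not match 1:1")
  src <- unlist(strsplit(cohort$provenance$source, "+", fixed = TRUE))
  if (!all(src %in% names(cohort$pool$alignment)))
    stop("provenance refers to unknown pool allele(s)")
  labs <- unlist(cohort$genotypes)
  if (!all(labs %in% names(cohort$pool$alignment)))
    stop("genotypes refer to unknown pool allele(s)")
  invisible(TRUE)
}

#' Neutral infinite-sites coalescent sample
#'
#' Standard neutral coalescent for `n` lineages: exponential epoch lengths
#' with rate `k(k-1)/2`, uniformly chosen coalescences, mutations placed as a
#' Poisson process at rate `theta_per_site * length / 2` per unit branch
#' length, each assigned a unique site (infinite-sites).  The sample is
#' emitted as a nucleotide alignment: ancestral base A, derived base G.
#'
#' @param n number of sequences (>= 2).
#' @param theta_per_site population-scaled mutation rate per site.
#' @param length number of sites.
#' @param seed integer seed.
#' @return a [codon_alignment()] with labels `t1..tn`.
#' @export
coalescent_sample <- function(n, theta_per_site, length, seed) {
  if (n < 2L) stop("need n >= 2")
  set.seed(seed)
  lineages <- lapply(seq_len(n), identity)  # tip sets
  seg_tips <- list(); seg_len <- numeric(0)
  k <- n
  while (k > 1L) {
    t_k <- stats::rexp(1, rate = k * (k - 1) / 2)
    for (ln in lineages) {
      seg_tips[[length(seg_tips) + 1L]] <- ln
      seg_len <- c(seg_len, t_k)
    }
    pick <- sample.int(k, 2L)
    merged <- c(lineages[[pick[[1L]]]], lineages[[pick[[2L]]]])
    lineages <- c(lineages[-pick], list(merged))
    k <- k - 1L
  }
  total <- sum(seg_len)
  n_mut <- stats::rpois(1, theta_per_site * length * total / 2)
  if (n_mut > length)
    stop("drew ", n_mut, " mutations for ", length,
         " sites under infinite-sites mapping; increase `length`")
  m <- matrix("A", nrow = n, ncol = length)
  if (n_mut > 0L) {
    sites <- sample.int(length, n_mut)
    segs <- sample.int(base::length(seg_len), n_mut, replace = TRUE,
                       prob = seg_len)
    for (i in seq_len(n_mut)) {
      tips <- seg_tips[[segs[[i]]]]
      # mutations on segments ancestral to all tips are invisible but legal
      m[tips, sites[[i]]] <- "G"
    }
  }
  seqs <- apply(m, 1L, paste, collapse = "")
  codon_alignment(stats::setNames(seqs, paste0("t", seq_len(n))))
}
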