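# Assign haplotypes to paralogous class IIb loci (DAB/DBB/DCB) and call
# per-individual copy-number / presence-absence classes.
#
# Locus assignment is nearest-reference with a distance margin rather than
# clade membership: each haplotype takes the locus of its closest reference
# ("type") sequence, and is reported "unresolved" when the gap between the
# best and second-best locus falls below a threshold.  The genealogy
# (neighbor-joining with column bootstrap) is produced for visual grouping.

#' Pairwise p-distance (or Jukes-Cantor) matrix
#'
#' Proportion of differing sites over sites where neither sequence has a gap
#' or N, optionally Jukes-Cantor corrected (`-3/4 log(1 - 4p/3)`).
#'
#' @param alignment a [codon_alignment()] or named character vector of
#'   equal-length sequences.
#' @param correction `"none"` (default) or `"jc"`.
#' @return symmetric numeric matrix with zero diagonal, labelled by sequence.
#' @export
p_distance_matrix <- function(alignment, correction = c("none", "jc")) {
  correction <- match.arg(correction)
  m <- seq_char_matrix(alignment)
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  n <- nrow(m)
  good <- m == "A" | m == "C" | m == "G" | m == "T"
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    use <- good[i, ] & good[j, ]
    if (!any(use))
      stop("no comparable sites between ", rownames(m)[i], " and ",
           rownames(m)[j])
    p <- mean(m[i, use] != m[j, use])
    if (correction == "jc") {
      if (p >= 0.75)
        stop("p-distance ", signif(p, 3), " between ", rownames(m)[i],
             " and ", rownames(m)[j], " is too large for JC correction")
      p <- -0.75 * log(1 - 4 * p / 3)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining (via \pkg{ape}).  Negative branch
#' lengths are reported as-is unless `clamp = TRUE`.
#'
#' @param d symmetric distance matrix (>= 3 taxa).
#' @param clamp clamp negative branch lengths at zero (default `FALSE`).
#' @return an \pkg{ape} `phylo` object (unrooted).
#' @export
nj_tree <- function(d, clamp = FALSE) {
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  if (clamp) tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Column-bootstrap support for the bipartitions of a reference tree
#'
#' Aligned columns are resampled with replacement `B` times; each replicate
#' alignment is rebuilt into a tree with `tree_builder`, and support for each
#' internal bipartition of the reference tree is the percentage of replicates
#' containing it.
#'
#' @param alignment a [codon_alignment()] or named character vector.
#' @param tree_builder function(alignment-subset named character vector) ->
#'   `phylo`; default: NJ on uncorrected p-distance.
#' @param B number of bootstrap pseudoreplicates.
#' @param seed integer seed making the resampling deterministic.
#' @return list with `tree` (the reference `phylo`, `node.label` set to the
#'   support percentages) and `support` (numeric vector, one entry per
#'   internal node).
#' @export
bootstrap_support <- function(alignment, tree_builder = NULL, B = 100L,
                              seed = 1L) {
  if (B < 1L) stop("B must be >= 1")
  if (is.null(tree_builder))
    tree_builder <- function(seqs) nj_tree(p_distance_matrix(seqs))
  seqs <- if (inherits(alignment, "codon_alignment")) alignment$seq else alignment
  m <- seq_char_matrix(seqs)
  ref <- tree_builder(seqs)
  set.seed(seed)
  boots <- vector("list", B)
  for (r in seq_len(B)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    mb <- m[, cols, drop = FALSE]
    sb <- apply(mb, 1L, paste, collapse = "")
    boots[[r]] <- tree_builder(sb)
  }
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  pct <- 100 * counts / B
  ref$node.label <- formatC(pct, format = "f", digits = 0)
  list(tree = ref, support = pct)
}

#' Assign haplotypes to loci by nearest reference sequence
#'
#' Each haplotype is assigned the locus of its nearest reference by
#' uncorrected p-distance.  The margin is the distance to the best reference
#' of the runner-up locus minus the distance to the best reference of the
#' winning locus; assignments with margin below `margin_threshold` (including
#' exact ties, margin 0) are reported `"unresolved"`.
#'
#' @param catalog a [call_haplotypes()] catalog, or a named character vector
#'   of haplotype sequences.
#' @param references named character vector of reference ("type") sequences;
#'   `locus_of` gives the locus of each reference.
#' @param locus_of character vector, same length/order as `references`,
#'   naming each reference's locus.
#' @param margin_threshold minimum distance margin (substitutions/site) for a
#'   confident call; default 0.02.
#' @return data.frame with columns `haplotype`, `locus`, `nearest_reference`,
#'   `margin`.
#' @export
assign_loci <- function(catalog, references, locus_of,
                        margin_threshold = 0.02) {
  haps <- if (inherits(catalog, "haplotype_catalog"))
    stats::setNames(catalog$haplotypes$sequence,
                    as.character(catalog$haplotypes$label))
  else catalog
  if (length(references) != length(locus_of))
    stop("references and locus_of lengths differ")
  loci <- unique(locus_of)
  if (length(loci) < 2L) stop("need references for at least 2 loci")
  if (length(unique(nchar(c(haps, references)))) != 1L)
    stop("haplotype and reference alignment lengths differ")
  out <- data.frame(haplotype = names(haps), locus = NA_character_,
                    nearest_reference = NA_character_, margin = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(haps)) {
    d <- vapply(references, function(r)
      p_distance_matrix(c(h = haps[[i]], r = r))["h", "r"], numeric(1))
    best_per_locus <- vapply(loci, function(l) min(d[locus_of == l]),
                             numeric(1))
    ord <- order(best_per_locus, loci)  # deterministic under ties
    best <- ord[[1L]]; second <- ord[[2L]]
    margin <- best_per_locus[[second]] - best_per_locus[[best]]
    refs_best <- which(locus_of == loci[[best]])
    nearest <- names(references)[refs_best[which.min(d[refs_best])]]
    out$locus[[i]] <- if (margin < margin_threshold) "unresolved"
      else loci[[best]]
    out$nearest_reference[[i]] <- nearest
    out$margin[[i]] <- margin
  }
  out
}

#' Per-individual copy-number / presence-absence calls
#'
#' Classifies each locus of each individual by the number of distinct
#' haplotypes detected: `absent` (0), `homozygous-like` (1; a single detected
#' haplotype cannot distinguish homozygosity from allelic dropout),
#' `heterozygous` (2) or `supernumerary` (>= 3).
#'
#' @param genotypes named list: per individual, a named list of per-locus
#'   haplotype label vectors (see [genotypes_from_catalog()] or
#'   [read_genotype_table()]).
#' @param loci character vector of locus names defining column order.
#' @return list with `calls` (data.frame: `individual_id`, one class column
#'   per locus, `total_haplotypes`) and `summary` (per-locus class counts and
#'   the distribution of total haplotypes per individual).
#' @export
call_cnv <- function(genotypes, loci = NULL) {
  if (is.null(loci))
    loci <- unique(unlist(lapply(genotypes, names)))
  classify <- function(k) {
    if (k == 0L) "absent" else if (k == 1L) "homozygous-like"
    else if (k == 2L) "heterozygous" else "supernumerary"
  }
  rows <- lapply(names(genotypes), function(id) {
    g <- genotypes[[id]]
    sizes <- vapply(loci, function(l)
      length(unique(g[[l]])), integer(1))
    c(list(individual_id = id),
      stats::setNames(as.list(vapply(sizes, classify, character(1))), loci),
      list(total_haplotypes = sum(sizes)))
  })
  calls <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  classes <- c("absent", "homozygous-like", "heterozygous", "supernumerary")
  per_locus <- sapply(loci, function(l)
    vapply(classes, function(cl) sum(calls[[l]] == cl), integer(1)))
  total_dist <- table(calls$total_haplotypes)
  list(calls = calls,
       summary = list(per_locus_class_counts = per_locus,
                      total_haplotype_distribution = total_dist))
}

#' Mean within- and between-locus distances
#'
#' Group-averaged pairwise distances given a locus assignment: the diagonal
#' holds mean within-locus distance (NA for single-haplotype loci), the
#' off-diagonal mean between-locus distance.
#'
#' @param d distance matrix over haplotypes (labels must match
#'   `assignments$haplotype`).
#' @param assignments an [assign_loci()] result (rows with locus
#'   `"unresolved"` are excluded).
#' @return symmetric numeric matrix, loci as rows/columns.
#' @export
within_between_locus_distances <- function(d, assignments) {
  a <- assignments[assignments$locus != "unresolved", , drop = FALSE]
  loci <- unique(a$locus)
  out <- matrix(NA_real_, length(loci), length(loci),
                dimnames = list(loci, loci))
  for (i in seq_along(loci)) for (j in seq_len(i)) {
    hi <- a$haplotype[a$locus == loci[[i]]]
    hj <- a$haplotype[a$locus == loci[[j]]]
    block <- d[hi, hj, drop = FALSE]
    vals <- if (i == j) {
      if (length(hi) < 2L) NA_real_ else block[lower.tri(block)]
    } else as.vector(block)
    out[i, j] <- out[j, i] <- mean(vals)
  }
  out
}

#' Convert a haplotype catalog plus locus assignments into genotypes
#'
#' @param catalog a [call_haplotypes()] catalog.
#' @param assignments an [assign_loci()] result; haplotypes assigned
#'   `"unresolved"` are carried under that pseudo-locus.
#' @return named list: per individual, a named list of per-locus integer
#'   label vectors.
#' @export
genotypes_from_catalog <- function(catalog, assignments) {
  locus_of_label <- stats::setNames(assignments$locus, assignments$haplotype)
  loci <- unique(assignments$locus)
  lapply(catalog$per_individual, function(labs) {
    g <- lapply(loci, function(l)
      labs[locus_of_label[as.character(labs)] == l])
    stats::setNames(g, loci)
  })
}

#' Read a per-individual genotype table
#'
#' Wide TSV: an `individual` column plus one column per locus holding
#' comma-separated haplotype labels (empty cell = locus absent).
#'
#' @param path TSV path.
#' @return named list: per individual, a named list of per-locus integer
#'   label vectors.
#' @export
read_genotype_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!"individual" %in% names(tab))
    stop("genotype table needs an 'individual' column")
  loci <- setdiff(names(tab), "individual")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    g <- lapply(loci, function(l) {
      cell <- trimws(tab[[l]][[i]])
      if (is.na(cell) || cell == "") integer(0)
      else as.integer(strsplit(cell, ",")[[1L]])
    })
    stats::setNames(g, loci)
  })
  stats::setNames(out, tab$individual)
}

#' Write a genotype table to TSV
#'
#' @param genotypes genotype list (see [read_genotype_table()]).
#' @param path output TSV path.
#' @param loci locus column order (default: order of first appearance).
#' @export
write_genotype_table <- function(genotypes, path, loci = NULL) {
  if (is.null(loci)) loci <- unique(unlist(lapply(genotypes, names)))
  rows <- lapply(names(genotypes), function(id) {
    cells <- vapply(loci, function(l)
      paste(sort(genotypes[[id]][[l]]), collapse = ","), character(1))
    c(individual = id, cells)
  })
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
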