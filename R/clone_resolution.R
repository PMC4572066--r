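# Collapse per-individual clone sequences into validated haplotypes.
#
# Two validation rules mirror the clone-based genotyping scheme:
#   * a variant seen in a single clone within an individual is only accepted
#     as a haplotype if an identical sequence occurs in another individual;
#   * putative PCR chimeras -- single-crossover mosaics of two better
#     supported variants from the same individual -- are excluded before the
#     singleton rule, so a chimera arising independently in two individuals
#     cannot rescue itself.

#' Group the clones of one individual into a clone set
#'
#' @param individual_id individual identifier.
#' @param clones named character vector of clone sequences
#'   (names are clone ids).
#' @return object of class `clone_set`.
#' @export
clone_set <- function(individual_id, clones) {
  clones <- clean_dna(clones)
  if (length(clones) < 1L) stop("clone set needs at least one clone")
  if (length(unique(nchar(clones))) != 1L)
    stop("clones of individual ", individual_id, " differ in length")
  structure(list(individual_id = individual_id, clones = clones,
                 n_readable = length(clones)),
            class = "clone_set")
}

#' Split a clone FASTA into per-individual clone sets
#'
#' @param sequences named character vector of clone sequences.
#' @param clone_map data.frame with `clone_id`, `individual_id`
#'   (see [read_clone_map()] / [parse_clone_labels()]).
#' @return named list of [clone_set()] objects, one per individual, in order
#'   of first appearance in the map.
#' @export
split_clone_sets <- function(sequences, clone_map) {
  missing <- setdiff(names(sequences), clone_map$clone_id)
  if (length(missing))
    stop("clone(s) absent from mapping: ", paste(missing, collapse = ", "))
  ids <- clone_map$individual_id[match(names(sequences), clone_map$clone_id)]
  out <- lapply(unique(ids), function(i)
    clone_set(i, sequences[ids == i]))
  names(out) <- unique(ids)
  out
}

#' Collapse a clone set to its distinct sequence variants
#'
#' Exact-sequence grouping; variants are ordered by descending clone support
#' and then lexicographically, so the result is invariant to clone order.
#'
#' @param clones a [clone_set()].
#' @return object of class `variant_table`: data.frame with columns
#'   `sequence` and `support`, plus attributes `individual_id` and
#'   `n_readable`.
#' @export
collapse_clones <- function(clones) {
  stopifnot(inherits(clones, "clone_set"))
  tab <- table(clones$clones)
  df <- data.frame(sequence = names(tab), support = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$support, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, individual_id = clones$individual_id,
            n_readable = clones$n_readable,
            class = c("variant_table", "data.frame"))
}

# mosaic of a up to breakpoint b, then b (positions b+1..L)
splice_at <- function(seq_a, seq_b, b) {
  paste0(substr(seq_a, 1L, b), substr(seq_b, b + 1L, nchar(seq_b)))
}

n_mismatch <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

#' Detect single-crossover PCR chimeras among an individual's variants
#'
#' A variant `v` is called chimeric when some breakpoint `b` and two distinct
#' other variants `A`, `B` -- each supported by at least `min_parent_support`
#' clones, both with more support than `v` -- reproduce `v` as
#' `A[1..b] + B[b+1..L]` with at most `max_mismatch` mismatches.  The call
#' records the minimal-mismatch `(A, B, b)` triple (ties broken by smallest
#' breakpoint, then parent order).  Variants are examined in order of
#' increasing support; once a variant has served as a parent it is never
#' itself called chimeric in the same pass.
#'
#' @param variants a [collapse_clones()] variant table.
#' @param min_parent_support minimum clone support for a parent (default 2).
#' @param max_mismatch mismatch tolerance for the mosaic match (default 0,
#'   appropriate for error-free data; raise for noisy clones).
#' @return data.frame with columns `sequence`, `support`, `parent_a`,
#'   `parent_b` (row indices into `variants` as character labels `v<i>`),
#'   `breakpoint_nt`, `n_mismatches`; attribute `individual_id`.
#' @export
detect_chimeras <- function(variants, min_parent_support = 2L,
                            max_mismatch = 0L) {
  stopifnot(inherits(variants, "variant_table"))
  n <- nrow(variants)
  calls <- data.frame(sequence = character(0), support = integer(0),
                      parent_a = character(0), parent_b = character(0),
                      breakpoint_nt = integer(0), n_mismatches = integer(0),
                      stringsAsFactors = FALSE)
  if (n < 3L) {
    attr(calls, "individual_id") <- attr(variants, "individual_id")
    return(calls)
  }
  L <- nchar(variants$sequence[[1L]])
  # ascending support (then reverse-lexicographic so that processing order is
  # the exact reverse of the canonical variant order)
  ord <- order(variants$support, variants$sequence, decreasing = c(FALSE, TRUE),
               method = "radix")
  protected <- rep(FALSE, n)
  flagged <- rep(FALSE, n)
  for (vi in ord) {
    if (protected[vi]) next
    v <- variants$sequence[[vi]]
    sup_v <- variants$support[[vi]]
    best <- NULL
    for (ai in seq_len(n)) {
      if (ai == vi || flagged[ai]) next
      if (variants$support[[ai]] < min_parent_support) next
      for (bi in seq_len(n)) {
        if (bi == vi || bi == ai || flagged[bi]) next
        if (variants$support[[bi]] < min_parent_support) next
        if (sup_v >= min(variants$support[[ai]], variants$support[[bi]])) next
        A <- variants$sequence[[ai]]; B <- variants$sequence[[bi]]
        for (b in seq_len(L - 1L)) {
          mm <- n_mismatch(v, splice_at(A, B, b))
          if (mm <= max_mismatch &&
              (is.null(best) || mm < best$mm)) {
            best <- list(ai = ai, bi = bi, b = b, mm = mm)
            if (mm == 0L) break
          }
        }
        if (!is.null(best) && best$mm == 0L) break
      }
      if (!is.null(best) && best$mm == 0L) break
    }
    if (!is.null(best)) {
      flagged[vi] <- TRUE
      protected[best$ai] <- TRUE
      protected[best$bi] <- TRUE
      calls <- rbind(calls, data.frame(
        sequence = v, support = sup_v,
        parent_a = paste0("v", best$ai), parent_b = paste0("v", best$bi),
        breakpoint_nt = best$b, n_mismatches = best$mm,
        stringsAsFactors = FALSE))
    }
  }
  attr(calls, "individual_id") <- attr(variants, "individual_id")
  calls
}

#' Build the cohort-wide haplotype catalog
#'
#' Chimera-flagged sequences are removed first (a sequence flagged in any
#' individual is excluded cohort-wide, so it can never rescue a singleton
#' elsewhere).  A remaining variant is retained for an individual when it is
#' supported by at least `min_within_support` clones there, or when it is a
#' singleton whose exact sequence occurs in at least one other individual.
#' Retained sequences are labelled with dense integers, 1 upward, by
#' descending total retained support and then lexicographic order, so the
#' catalog is invariant to individual and clone ordering.
#'
#' @param all_variants list of [collapse_clones()] variant tables, one per
#'   individual.
#' @param chimera_calls list of [detect_chimeras()] results aligned with
#'   `all_variants` (or `NULL` to detect internally with defaults).
#' @param min_within_support clones needed for self-validation (default 2).
#' @return object of class `haplotype_catalog`: list with `haplotypes`
#'   (data.frame `label`, `sequence`), `per_individual` (named list of
#'   integer label vectors) and `dropped_singletons` (per-individual counts).
#' @export
call_haplotypes <- function(all_variants, chimera_calls = NULL,
                            min_within_support = 2L) {
  if (is.null(chimera_calls))
    chimera_calls <- lapply(all_variants, detect_chimeras)
  ids <- vapply(all_variants, function(v) attr(v, "individual_id"),
                character(1))
  chimeric_seqs <- unique(unlist(lapply(chimera_calls,
                                        function(cc) cc$sequence)))
  kept <- lapply(all_variants, function(v) {
    v[!(v$sequence %in% chimeric_seqs), , drop = FALSE]
  })
  # cross-individual occurrence counts of each surviving sequence
  occ <- table(unlist(lapply(kept, function(v) unique(v$sequence))))
  retained <- lapply(kept, function(v) {
    ok <- v$support >= min_within_support |
      (v$support == 1L & occ[v$sequence] >= 2L)
    v[ok, , drop = FALSE]
  })
  dropped <- vapply(seq_along(kept), function(i)
    nrow(kept[[i]]) - nrow(retained[[i]]), integer(1))
  all_seq <- unlist(lapply(retained, function(v) v$sequence))
  all_sup <- unlist(lapply(retained, function(v) v$support))
  if (length(all_seq) == 0L) {
    haps <- data.frame(label = integer(0), sequence = character(0),
                       stringsAsFactors = FALSE)
  } else {
    tot <- tapply(all_sup, all_seq, sum)
    seqs <- names(tot)
    ordr <- order(-as.numeric(tot), seqs)
    haps <- data.frame(label = seq_along(seqs), sequence = seqs[ordr],
                       stringsAsFactors = FALSE)
  }
  per_ind <- lapply(retained, function(v) {
    sort(haps$label[match(v$sequence, haps$sequence)])
  })
  names(per_ind) <- ids
  empty <- ids[lengths(per_ind) == 0L]
  if (length(empty))
    warning("individual(s) with no retained haplotype: ",
            paste(empty, collapse = ", "))
  structure(list(haplotypes = haps, per_individual = per_ind,
                 dropped_singletons = stats::setNames(dropped, ids)),
            class = "haplotype_catalog")
}

#' @export
print.haplotype_catalog <- function(x, ...) {
  cat(sprintf("haplotype_catalog: %d haplotypes across %d individuals\n",
              nrow(x$haplotypes), length(x$per_individual)))
  invisible(x)
}

#' Saturation diagnostic: haplotypes recovered vs clones sequenced
#'
#' One row per individual pairing the number of readable clones with the
#' number of haplotypes resolved, plus the Spearman rank correlation between
#' the two (ties handled by midranks).  A significant positive correlation
#' would suggest clone sampling limited haplotype discovery.
#'
#' @param catalog a [call_haplotypes()] catalog.
#' @param variant_tables the variant tables the catalog was built from.
#' @return data.frame (`individual_id`, `n_clones`, `n_haplotypes`) with
#'   attributes `rho` and `rho_note` (`NA` and an explanation when fewer than
#'   3 individuals or zero variance make the correlation undefined).
#' @export
saturation_table <- function(catalog, variant_tables) {
  ids <- vapply(variant_tables, function(v) attr(v, "individual_id"),
                character(1))
  n_clones <- vapply(variant_tables, function(v) attr(v, "n_readable"),
                     integer(1))
  n_hap <- lengths(catalog$per_individual[ids])
  out <- data.frame(individual_id = ids, n_clones = n_clones,
                    n_haplotypes = as.integer(n_hap),
                    stringsAsFactors = FALSE)
  rho <- NA_real_; note <- NULL
  if (nrow(out) < 3L) {
    note <- "fewer than 3 individuals; correlation undefined"
  } else if (stats::var(out$n_clones) == 0 || stats::var(out$n_haplotypes) == 0) {
    note <- "zero variance in clones or haplotypes; correlation undefined"
  } else {
    rho <- stats::cor(out$n_clones, out$n_haplotypes, method = "spearman")
  }
  attr(out, "rho") <- rho
  attr(out, "rho_note") <- note
  out
}
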