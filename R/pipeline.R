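# Orchestration: simulate (or load) -> resolve -> assign -> stats -> report.
# All stage outputs are pure functions of (inputs, config, seed); a manifest
# records the configuration snapshot so reruns are reproducible.

#' Resolve a cohort of clone sequences into a haplotype catalog
#'
#' Runs collapse -> chimera detection -> catalog construction -> saturation
#' diagnostic for a whole cohort.
#'
#' @param clones named character vector of clone sequences.
#' @param clone_map data.frame `clone_id`, `individual_id`.
#' @param min_parent_support,max_mismatch chimera-detection settings
#'   (see [detect_chimeras()]).
#' @param min_within_support singleton rule threshold
#'   (see [call_haplotypes()]).
#' @return list: `variant_tables`, `chimera_calls`, `catalog`, `saturation`.
#' @export
resolve_cohort <- function(clones, clone_map, min_parent_support = 2L,
                           max_mismatch = 0L, min_within_support = 2L) {
  sets <- split_clone_sets(clones, clone_map)
  vts <- lapply(sets, collapse_clones)
  chim <- lapply(vts, detect_chimeras,
                 min_parent_support = min_parent_support,
                 max_mismatch = max_mismatch)
  catalog <- call_haplotypes(vts, chim,
                             min_within_support = min_within_support)
  sat <- saturation_table(catalog, vts)
  list(variant_tables = vts, chimera_calls = chim, catalog = catalog,
       saturation = sat)
}

#' Validate pipeline inputs before running any stage
#'
#' Checks sequence lengths, reading frame, clone-to-individual
#' cross-references and metadata joins.  Non-fatal issues are returned as
#' warnings; fatal inconsistencies are enumerated so a run can stop before
#' any stage output is written.
#'
#' @param clones named character vector of clone sequences (or `NULL`).
#' @param clone_map clone-to-individual data.frame (or `NULL`).
#' @param references named character vector of reference sequences
#'   (or `NULL`).
#' @param metadata per-individual metadata data.frame with `individual_id`
#'   (or `NULL`).
#' @param frame_offset frame offset that codon-aware statistics will use.
#' @return list with character vectors `fatal` and `warnings`.
#' @export
validate_inputs <- function(clones = NULL, clone_map = NULL,
                            references = NULL, metadata = NULL,
                            frame_offset = 0L) {
  fatal <- character(0); warn <- character(0)
  if (!is.null(clones)) {
    lens <- unique(nchar(clones))
    if (length(lens) > 1L)
      fatal <- c(fatal, paste0("clone sequences have unequal lengths: ",
                               paste(lens, collapse = ", ")))
    else if ((lens - frame_offset) %% 3L != 0L)
      fatal <- c(fatal, sprintf(
        "clone length %d with frame offset %d is off-frame; codon statistics need (length - offset) %%%% 3 == 0",
        lens, frame_offset))
    if (!is.null(clone_map)) {
      missing <- setdiff(names(clones), clone_map$clone_id)
      if (length(missing))
        fatal <- c(fatal, paste0("clone(s) absent from mapping TSV: ",
                                 paste(missing, collapse = ", ")))
      unused <- setdiff(clone_map$clone_id, names(clones))
      if (length(unused))
        warn <- c(warn, paste0("mapping rows without clones: ",
                               paste(unused, collapse = ", ")))
    }
  }
  if (!is.null(references) && !is.null(clones)) {
    if (length(unique(nchar(references))) > 1L ||
        (length(clones) && nchar(references[[1L]]) != nchar(clones[[1L]])))
      fatal <- c(fatal, "reference alignment length does not match clones")
  }
  if (!is.null(metadata)) {
    if (!"individual_id" %in% names(metadata))
      fatal <- c(fatal, "metadata lacks an individual_id column")
    else if (!is.null(clone_map)) {
      extra <- setdiff(unique(clone_map$individual_id),
                       metadata$individual_id)
      if (length(extra))
        warn <- c(warn, paste0("individuals without metadata: ",
                               paste(extra, collapse = ", ")))
    }
  }
  list(fatal = fatal, warnings = warn)
}

#' Run the full pipeline into an output directory
#'
#' Stages: obtain clones (from a [sim_config()] simulation or from files),
#' resolve haplotypes, assign loci against references, call CNV classes, and
#' compute the diversity layer.  Writes one file per report plus a
#' `manifest.json` snapshot; any stage failure halts with a stage-named
#' error.
#'
#' @param config list with either `sim` (a [sim_config()]) or
#'   `clones_fasta` + `clone_map_tsv`; optional `references` (named
#'   character vector) + `reference_locus_of` (locus per reference),
#'   `margin_threshold` (default 0.02), `min_parent_support`,
#'   `max_mismatch`, `min_within_support`, `frame_offset` (default 0).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  defaults <- list(margin_threshold = 0.02, min_parent_support = 2L,
                   max_mismatch = 0L, min_within_support = 2L,
                   frame_offset = 0L)
  config <- utils::modifyList(defaults, config)

  cohort <- NULL
  if (!is.null(config$sim)) {
    cohort <- stage("simulate", {
      ch <- simulate_cohort(config$sim)
      validate_truth(ch)
      ch
    })
    clones <- cohort$clones
    clone_map <- cohort$clone_map
    if (is.null(config$references)) {
      # default references: first pool allele of each locus
      loci <- unique(cohort$pool$locus_of)
      refs <- vapply(loci, function(l)
        cohort$pool$alignment[[which(cohort$pool$locus_of == l)[[1L]]]],
        character(1))
      config$references <- stats::setNames(refs, paste0(loci, "_type"))
      config$reference_locus_of <- loci
    }
  } else {
    clones <- stage("load", read_fasta(config$clones_fasta))
    clone_map <- stage("load", read_clone_map(config$clone_map_tsv))
  }

  diag <- validate_inputs(clones, clone_map, config$references,
                          frame_offset = config$frame_offset)
  if (length(diag$fatal))
    stop("pipeline stage 'validate' failed: ",
         paste(diag$fatal, collapse = "; "), call. = FALSE)
  for (w in diag$warnings) warning(w)

  res <- stage("resolve", resolve_cohort(
    clones, clone_map, config$min_parent_support, config$max_mismatch,
    config$min_within_support))
  catalog <- res$catalog

  hap_seqs <- stats::setNames(catalog$haplotypes$sequence,
                              as.character(catalog$haplotypes$label))
  write_fasta(hap_seqs, file.path(out_dir, "catalog.fasta"))
  chim_all <- do.call(rbind, lapply(names(res$chimera_calls), function(id) {
    cc <- res$chimera_calls[[id]]
    if (nrow(cc) == 0L) return(NULL)
    cbind(individual_id = id, cc)
  }))
  if (is.null(chim_all))
    chim_all <- data.frame(individual_id = character(0))
  utils::write.table(chim_all, file.path(out_dir, "chimeras.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$saturation, file.path(out_dir, "saturation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  assignments <- NULL; genotypes <- NULL; cnv <- NULL
  if (!is.null(config$references)) {
    assignments <- stage("assign", assign_loci(
      catalog, config$references, config$reference_locus_of,
      config$margin_threshold))
    utils::write.table(assignments, file.path(out_dir, "assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    genotypes <- genotypes_from_catalog(catalog, assignments)
    write_genotype_table(genotypes, file.path(out_dir, "genotypes.tsv"))
    cnv <- call_cnv(genotypes)
    utils::write.table(cnv$calls, file.path(out_dir, "cnv.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  stats_rows <- stage("stats", {
    aln <- codon_alignment(hap_seqs, frame_offset = config$frame_offset)
    rows <- list()
    if (length(hap_seqs) >= 2L)
      rows[["all"]] <- diversity(aln)
    if (!is.null(assignments)) {
      for (l in setdiff(unique(assignments$locus), "unresolved")) {
        labs <- assignments$haplotype[assignments$locus == l]
        if (length(labs) >= 2L)
          rows[[l]] <- diversity(codon_alignment(
            hap_seqs[labs], frame_offset = config$frame_offset))
      }
    }
    rows
  })
  stats_tab <- do.call(rbind, lapply(names(stats_rows), function(l) {
    s <- stats_rows[[l]]
    data.frame(locus = l, Ns = s$n_sequences, Nhap = s$Nhap, S = s$S,
               Hd = s$hap_diversity, pi_s = s$pi_s, pi_n = s$pi_n,
               pi = s$pi, theta_w = s$theta_w, tajima_d = s$tajima_d,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(stats_tab, file.path(out_dir, "diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (length(hap_seqs) >= 3L) {
    tr <- nj_tree(p_distance_matrix(hap_seqs))
    ape::write.tree(tr, file.path(out_dir, "tree.nwk"))
  }

  manifest <- list(
    tool = "cloneMHC", version = as.character(utils::packageVersion("cloneMHC")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = config[setdiff(names(config), c("sim", "references"))],
    seed = if (!is.null(config$sim)) config$sim$seed else NULL,
    n_individuals = length(unique(clone_map$individual_id)),
    n_clones = length(clones),
    n_haplotypes = nrow(catalog$haplotypes))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(cohort = cohort, resolution = res,
                 assignments = assignments, genotypes = genotypes,
                 cnv = cnv, stats = stats_tab))
}
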