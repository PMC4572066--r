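# Individual-level comparative layer: within-individual allele distances,
# genotype-sharing / heterozygosity association tests (likelihood-ratio
# contingency), and birth-date trend tests.

#' Mean pairwise distance among an individual's haplotypes
#'
#' An individual-based measure of genetic distance that accounts jointly for
#' heterozygosity and allele divergence: the mean uncorrected p-distance over
#' all unordered pairs of the individual's haplotypes at a locus (undefined
#' for individuals carrying fewer than two), plus a pooled version across all
#' loci.
#'
#' @param genotypes genotype list (see [read_genotype_table()]).
#' @param sequences named character vector mapping haplotype labels to
#'   sequences.
#' @param loci locus names to report (default: all in the genotypes), always
#'   extended with the pooled `"all"` row.
#' @return data.frame: `individual_id`, `locus`, `n_haplotypes`,
#'   `mean_distance` (`NA` when fewer than 2 haplotypes).
#' @export
within_individual_distances <- function(genotypes, sequences, loci = NULL) {
  if (is.null(loci)) loci <- unique(unlist(lapply(genotypes, names)))
  mean_pd <- function(labs) {
    labs <- unique(labs)
    if (length(labs) < 2L) return(NA_real_)
    miss <- setdiff(as.character(labs), names(sequences))
    if (length(miss))
      stop("no sequence for haplotype label(s): ", paste(miss, collapse = ", "))
    d <- p_distance_matrix(sequences[as.character(labs)])
    mean(d[lower.tri(d)])
  }
  rows <- list()
  for (id in names(genotypes)) {
    g <- genotypes[[id]]
    for (l in c(loci, "all")) {
      labs <- if (l == "all") unlist(g) else g[[l]]
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = id, locus = l,
        n_haplotypes = length(unique(labs)),
        mean_distance = mean_pd(labs), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Likelihood-ratio (G) contingency test
#'
#' `G = 2 * sum O * log(O/E)` over cells with positive observed counts,
#' expected counts from the margins; p from chi-square with
#' `(rows-1)(cols-1)` degrees of freedom.  All-zero rows/columns are dropped
#' (with a note); a table that degenerates to fewer than 2 rows or columns
#' leaves the test undefined.
#'
#' @param table matrix of nonnegative integer counts (>= 2 x 2).
#' @return list of class `contingency_result`: `table` (after dropping),
#'   `G`, `df`, `p`, `dropped` (note or `NULL`).
#' @export
lr_contingency <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("need at least a 2x2 table")
  dropped <- NULL
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    dropped <- sprintf("dropped %d all-zero row(s), %d all-zero column(s)",
                       sum(!keep_r), sum(!keep_c))
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    return(structure(list(table = tab, G = NA_real_, df = NA_integer_,
                          p = NA_real_, dropped = dropped,
                          note = "degenerate table; test undefined"),
                     class = "contingency_result"))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  pos <- tab > 0
  G <- 2 * sum(tab[pos] * log(tab[pos] / E[pos]))
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  structure(list(table = tab, G = G, df = df,
                 p = stats::pchisq(G, df, lower.tail = FALSE),
                 dropped = dropped, note = NULL),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("G = %s, df = %s, p = %s\n", format(x$G), format(x$df),
              format(x$p)))
  invisible(x)
}

#' Birth-date trend tests
#'
#' Tests whether date of birth explains variation in a per-individual
#' response.  Continuous mode: ordinary least-squares regression of the
#' response on birth year (slope, r-squared, two-sided p).  Cohort mode
#' (early cohort vs late, split at `cohort_break`): one-way ANOVA F and p.
#' Binary (logical or two-valued) responses are routed through the
#' likelihood-ratio contingency test against the cohort classification.
#'
#' @param metadata data.frame with `individual_id` and `birth_year`.
#' @param response named numeric/logical vector, names = individual ids.
#' @param mode `"continuous"` or `"cohort"`.
#' @param cohort_break first birth year of the late cohort (default 1999;
#'   early cohort is every year before it).
#' @return list: `mode`, `n`, and either `slope`, `r_squared`, `p`
#'   (continuous), or `group_means`, `F`, `p` (cohort), or `G`, `df`, `p`
#'   (binary response, via [lr_contingency()]).  Zero-variance responses give
#'   `p = NA` with a note.
#' @export
birth_date_trends <- function(metadata, response,
                              mode = c("continuous", "cohort"),
                              cohort_break = 1999) {
  mode <- match.arg(mode)
  ids <- intersect(metadata$individual_id, names(response))
  if (length(ids) < 3L) stop("need >= 3 individuals with metadata")
  year <- metadata$birth_year[match(ids, metadata$individual_id)]
  y <- response[ids]
  binary <- is.logical(y) || length(unique(y)) == 2L
  if (stats::var(as.numeric(y)) == 0)
    return(list(mode = mode, n = length(ids), slope = 0, r_squared = 0,
                p = NA_real_, note = "zero-variance response"))
  if (binary && mode == "cohort") {
    cohort <- ifelse(year >= cohort_break, "late", "early")
    tab <- table(cohort, factor(as.character(y)))
    ct <- lr_contingency(tab)
    return(list(mode = "cohort-binary", n = length(ids), G = ct$G,
                df = ct$df, p = ct$p))
  }
  y <- as.numeric(y)
  if (mode == "continuous") {
    fit <- stats::lm(y ~ year)
    sm <- summary(fit)
    list(mode = mode, n = length(ids),
         slope = unname(stats::coef(fit)[["year"]]),
         r_squared = sm$r.squared,
         p = sm$coefficients["year", "Pr(>|t|)"])
  } else {
    cohort <- factor(ifelse(year >= cohort_break, "late", "early"))
    if (nlevels(droplevels(cohort)) < 2L)
      return(list(mode = mode, n = length(ids), p = NA_real_,
                  note = "single cohort; test undefined"))
    fit <- stats::aov(y ~ cohort)
    sm <- summary(fit)[[1L]]
    list(mode = mode, n = length(ids),
         group_means = tapply(y, cohort, mean),
         F = sm$`F value`[[1L]], p = sm$`Pr(>F)`[[1L]])
  }
}
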