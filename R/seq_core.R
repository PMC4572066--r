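# Sequence and codon primitives shared by all pipeline stages.
#
# Sequences are plain uppercase character strings over {A,C,G,T,N,-}; an
# alignment is a named character vector wrapped in a light S3 container that
# carries the reading-frame offset needed by codon-aware statistics.

VALID_DNA_CHARS <- c("A", "C", "G", "T", "N", "-")

#' In-frame codon alignment container
#'
#' Bundles a set of equal-length aligned nucleotide sequences with the
#' reading-frame offset (number of leading nucleotides before the first
#' complete codon).  Codon-aware statistics require that the length minus the
#' offset be a multiple of 3; plain nucleotide statistics do not.
#'
#' @param sequences named character vector of aligned sequences
#'   (names are the sequence labels), or an unnamed vector plus `labels`.
#' @param labels optional character vector of labels (used when `sequences`
#'   is unnamed).
#' @param frame_offset integer in 0:2, nucleotides to skip before the first
#'   complete codon.  The 192-bp class IIb exon-2 amplicon is treated as
#'   starting in frame (0) by default.
#' @return an object of class `codon_alignment` with elements `labels`,
#'   `seq` (named character vector), `length_nt` and `frame_offset`.
#' @export
codon_alignment <- function(sequences, labels = NULL, frame_offset = 0L) {
  if (!is.null(labels)) names(sequences) <- labels
  labels <- names(sequences)
  if (is.null(labels) || anyNA(labels) || any(labels == ""))
    stop("all sequences must be labelled")
  if (anyDuplicated(labels))
    stop("duplicate sequence labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  sequences <- clean_dna(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("sequences are not all the same length")
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  structure(
    list(labels = labels, seq = sequences,
         length_nt = lens[[1L]], frame_offset = as.integer(frame_offset)),
    class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d sequences x %d nt (frame offset %d)\n",
              length(x$seq), x$length_nt, x$frame_offset))
  invisible(x)
}

# uppercase, RNA -> DNA, and reject anything outside {A,C,G,T,N,-}
clean_dna <- function(x) {
  x <- chartr("u", "t", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN-]", x)
  if (any(bad)) {
    ch <- unique(unlist(strsplit(gsub("[ACGTN-]", "", x[bad]), "")))
    stop("invalid characters in sequence(s) ",
         paste(utils::head(which(bad), 3), collapse = ","),
         ": ", paste(ch, collapse = " "),
         " (ambiguity codes other than N are not accepted for clone data)")
  }
  x
}

# alignment (or named vector) -> character matrix, one row per sequence
seq_char_matrix <- function(x) {
  seqs <- if (inherits(x, "codon_alignment")) x$seq else x
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  m
}

check_in_frame <- function(aln) {
  if ((aln$length_nt - aln$frame_offset) %% 3L != 0L)
    stop("alignment length ", aln$length_nt, " minus frame offset ",
         aln$frame_offset, " is not a multiple of 3; ",
         "codon-aware statistics need an in-frame alignment")
  invisible(aln)
}

#' Read aligned or equal-length sequences from a FASTA file
#'
#' Sequences are uppercased and U is mapped to T.  Duplicate labels and empty
#' sequences are errors; ambiguity codes other than N are rejected because
#' cloned amplicon sequences represent single molecules.
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @param id_parser optional function applied to each raw header; it must
#'   return the label to use (see [header_splitter()] for clone headers that
#'   encode `individual|clone`).
#' @return named character vector of sequences, input order preserved.
#' @export
read_fasta <- function(path, id_parser = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = TRUE)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  seqs <- vapply(recs, function(r) as.character(r)[[1L]], character(1))
  labels <- vapply(recs, function(r) attr(r, "name"), character(1))
  if (!is.null(id_parser)) labels <- vapply(labels, id_parser, character(1))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for record(s): ",
         paste(labels[nchar(seqs) == 0L], collapse = ", "))
  if (anyDuplicated(labels))
    stop("duplicate FASTA labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  names(seqs) <- labels
  clean_dna(seqs)
}

#' Write sequences to FASTA
#'
#' Records are written in the order given, so writers are deterministic.
#'
#' @param sequences named character vector of sequences.
#' @param path output file path.
#' @export
write_fasta <- function(sequences, path) {
  seqinr::write.fasta(as.list(sequences), names = names(sequences),
                      file.out = path, nbchar = 70)
  invisible(path)
}

#' Build a header parser that splits on a delimiter
#'
#' Clone FASTA headers often encode `individual<delim>clone`.  The returned
#' function extracts the requested field (default: the whole header unchanged
#' when `field = NULL`).
#'
#' @param delim delimiter character (default `"|"`).
#' @param field which field to return, or `NULL` for all fields pasted back.
#' @return function mapping a header string to a label.
#' @export
header_splitter <- function(delim = "|", field = NULL) {
  function(header) {
    parts <- strsplit(header, delim, fixed = TRUE)[[1L]]
    if (is.null(field)) paste(parts, collapse = delim) else parts[[field]]
  }
}

#' Split clone labels into individual and clone identifiers
#'
#' @param labels character vector of clone labels of the form
#'   `individual<delim>clone`.
#' @param delim delimiter (default `"|"`).
#' @return data.frame with columns `clone_id` (the full label) and
#'   `individual_id`.
#' @export
parse_clone_labels <- function(labels, delim = "|") {
  parts <- strsplit(labels, delim, fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad))
    stop("clone label(s) without '", delim, "' delimiter: ",
         paste(labels[bad], collapse = ", "))
  data.frame(clone_id = labels,
             individual_id = vapply(parts, `[[`, character(1), 1L),
             stringsAsFactors = FALSE)
}

#' Read a clone-to-individual mapping TSV
#'
#' @param path TSV with columns `clone_id` and `individual_id`.
#' @return data.frame with those two columns.
#' @export
read_clone_map <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("clone_id", "individual_id")
  if (!all(need %in% names(m)))
    stop("clone map must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(m$clone_id))
    stop("duplicate clone_id in clone map: ",
         paste(unique(m$clone_id[duplicated(m$clone_id)]), collapse = ", "))
  m[need]
}

#' Translate a nucleotide sequence under the standard code
#'
#' Codons containing N or a gap translate to X; a trailing partial codon is
#' dropped.
#'
#' @param seq nucleotide string.
#' @param frame_offset nucleotides to skip before the first complete codon.
#' @return amino-acid string.
#' @export
translate_dna <- function(seq, frame_offset = 0L) {
  seq <- clean_dna(seq)
  body <- substr(seq, frame_offset + 1L, nchar(seq))
  n_codon <- nchar(body) %/% 3L
  if (n_codon == 0L) return("")
  codons <- substring(body, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  aa <- vapply(codons, translate_codon, character(1), USE.NAMES = FALSE)
  paste(aa, collapse = "")
}

translate_codon <- function(codon) {
  if (grepl("[^ACGT]", codon)) return("X")
  seqinr::translate(strsplit(codon, "")[[1L]])
}

codon_at <- function(seq, codon_index, frame_offset = 0L) {
  start <- frame_offset + 3L * (codon_index - 1L) + 1L
  substr(seq, start, start + 2L)
}

#' Classify the differences between two aligned sequences
#'
#' Each differing aligned position is reported with its codon position and,
#' where both codons are free of N and gaps, whether the change is synonymous
#' or nonsynonymous.  Classification uses single-position codon context: the
#' position is substituted into the first sequence's codon and the two codons
#' compared by translation.  Codons differing at more than one position are
#' flagged `multi_hit`; pathway-averaged counting for those lives in
#' [syn_nonsyn_diffs()].  Positions where either sequence has a gap or N (or
#' that fall outside a complete codon) are skipped and counted separately.
#'
#' @param a,b equal-length aligned nucleotide strings.
#' @param frame_offset reading-frame offset (see [codon_alignment()]).
#' @return data.frame with columns `position_nt`, `kind`
#'   (`"synonymous"`/`"nonsynonymous"`), `codon_position` (1-3) and
#'   `multi_hit`; attribute `skipped` holds the positions excluded because of
#'   gaps/N or incomplete codons.
#' @export
pairwise_differences <- function(a, b, frame_offset = 0L) {
  a <- clean_dna(a); b <- clean_dna(b)
  if (nchar(a) != nchar(b))
    stop("sequence lengths differ: ", nchar(a), " vs ", nchar(b))
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  diff_pos <- which(ca != cb)
  out <- data.frame(position_nt = integer(0), kind = character(0),
                    codon_position = integer(0), multi_hit = logical(0),
                    stringsAsFactors = FALSE)
  skipped <- integer(0)
  n_codon <- (nchar(a) - frame_offset) %/% 3L
  for (p in diff_pos) {
    idx <- p - frame_offset
    ci <- (idx - 1L) %/% 3L + 1L
    if (idx < 1L || ci > n_codon) { skipped <- c(skipped, p); next }
    cod_a <- codon_at(a, ci, frame_offset)
    cod_b <- codon_at(b, ci, frame_offset)
    if (grepl("[^ACGT]", cod_a) || grepl("[^ACGT]", cod_b)) {
      skipped <- c(skipped, p); next
    }
    cp <- (idx - 1L) %% 3L + 1L
    # single-position context: swap only this position into codon a
    cod_sub <- cod_a
    substr(cod_sub, cp, cp) <- cb[p]
    kind <- if (translate_codon(cod_a) == translate_codon(cod_sub))
      "synonymous" else "nonsynonymous"
    out <- rbind(out, data.frame(
      position_nt = p, kind = kind, codon_position = cp,
      multi_hit = cod_a != cod_sub && sum(strsplit(cod_a, "")[[1L]] !=
                                            strsplit(cod_b, "")[[1L]]) > 1L,
      stringsAsFactors = FALSE))
  }
  attr(out, "skipped") <- skipped
  out
}
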