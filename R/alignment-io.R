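#' Labeled haplotype alignments
#'
#' A `labeled_alignment` bundles an equal-length nucleotide alignment with a
#' population label per sample. It is the common input container for all
#' downstream statistics (diversity, per-site tests, distances, trees).
#'
#' @param sequences Character vector of equal-length nucleotide strings over
#'   `A,C,G,T,N,-` (case-insensitive; normalised to uppercase).
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   sequence.
#' @param populations Character vector (or named map keyed by sample id)
#'   assigning each sample to a population.
#' @return An object of class `labeled_alignment` with components
#'   `sample_ids`, `sequences`, `populations` (named by sample id), `length`
#'   (alignment columns) and `mat` (a samples x columns character matrix used
#'   internally).
#' @export
labeled_alignment <- function(sequences, sample_ids, populations) {
  sequences <- toupper(as.character(sequences))
  sample_ids <- as.character(sample_ids)
  if (length(sequences) != length(sample_ids))
    stop("one sample id per sequence required")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1L)
    stop("sequence length mismatch: lengths ", paste(unique(lens), collapse = ", "))
  if (!is.null(names(populations))) {
    missing <- setdiff(sample_ids, names(populations))
    if (length(missing))
      stop("population label missing for: ", paste(missing, collapse = ", "))
    populations <- populations[sample_ids]
  } else {
    if (length(populations) != length(sample_ids))
      stop("one population label per sample required")
  }
  populations <- stats::setNames(as.character(populations), sample_ids)
  if (anyNA(populations) || any(!nzchar(populations)))
    stop("population label missing for some samples")
  mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "N", "-",
                                           "R", "Y", "S", "W", "K", "M",
                                           "B", "D", "H", "V", "?"))
  if (length(bad))
    stop("unknown characters in sequences: ", paste(bad, collapse = ", "))
  rownames(mat) <- sample_ids
  structure(list(sample_ids = sample_ids,
                 sequences = stats::setNames(sequences, sample_ids),
                 populations = populations,
                 length = unname(lens[1]),
                 mat = mat),
            class = "labeled_alignment")
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat("Labeled alignment:", length(x$sample_ids), "samples x",
      x$length, "columns\n")
  tab <- table(x$populations)
  cat("Populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read an alignment and its population labels
#'
#' Reads a multi-record FASTA (wrapped or unwrapped) and a two-column TSV
#' `sample_id<TAB>population` (lines starting with `#` are comments). Record
#' ids must match labels exactly; sequences must be equal length.
#'
#' @param fasta_path Path to an aligned FASTA file.
#' @param labels_path Path to the sample-to-population TSV.
#' @return A [labeled_alignment()].
#' @export
read_alignment <- function(fasta_path, labels_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  lab <- utils::read.table(labels_path, sep = "\t", header = FALSE,
                           comment.char = "#", colClasses = "character",
                           col.names = c("sample_id", "population"))
  if (anyDuplicated(lab$sample_id))
    stop("duplicate sample ids in labels file")
  pops <- stats::setNames(lab$population, lab$sample_id)
  missing <- setdiff(ids, names(pops))
  if (length(missing))
    stop("population label missing for: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(pops), ids)
  if (length(extra))
    stop("labels refer to unknown samples: ", paste(extra, collapse = ", "))
  labeled_alignment(as.character(seqs), ids, pops)
}

#' Write an alignment and its labels back to disk
#'
#' Inverse of [read_alignment()]; unwrapped FASTA plus a TSV label table.
#'
#' @param aln A [labeled_alignment()].
#' @param fasta_path,labels_path Output paths.
#' @return Invisibly, `aln`.
#' @export
write_alignment <- function(aln, fasta_path, labels_path) {
  stopifnot(inherits(aln, "labeled_alignment"))
  writeLines(as.vector(rbind(paste0(">", aln$sample_ids),
                             unname(aln$sequences))), fasta_path)
  writeLines(c("#sample_id\tpopulation",
               paste(aln$sample_ids, aln$populations[aln$sample_ids],
                     sep = "\t")), labels_path)
  invisible(aln)
}

#' Collapse an alignment into distinct haplotypes
#'
#' Haplotype identity is exact string equality (including ambiguity codes).
#' Haplotypes are numbered in order of first occurrence, so the result is
#' deterministic for a given input ordering.
#'
#' @param aln A [labeled_alignment()].
#' @return A list of class `haplotype_set`: `haplotype_seqs` (distinct
#'   sequences, first-occurrence order), `counts` (haplotype x population
#'   count matrix), and `member_map` (list of sample-id vectors per
#'   haplotype).
#' @export
collapse_haplotypes <- function(aln) {
  stopifnot(inherits(aln, "labeled_alignment"))
  idx <- match(aln$sequences, unique(aln$sequences))
  k <- max(idx)
  pops <- sort(unique(aln$populations))
  counts <- table(factor(idx, levels = seq_len(k)),
                  factor(aln$populations, levels = pops))
  counts <- matrix(as.integer(counts), nrow = k,
                   dimnames = list(NULL, pops))
  structure(list(haplotype_seqs = unique(unname(aln$sequences)),
                 counts = counts,
                 member_map = split(aln$sample_ids, idx)),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("Haplotype set:", length(x$haplotype_seqs), "haplotypes,",
      sum(x$counts), "samples\n")
  invisible(x)
}

#' Variable (segregating) columns of an alignment
#'
#' A column is variable when at least two distinct non-missing bases
#' (`A,C,G,T`) occur in it; gaps, `N` and other ambiguity codes do not count
#' as states.
#'
#' @param aln A [labeled_alignment()].
#' @return Integer vector of 1-based column indices, increasing.
#' @export
variable_sites <- function(aln) {
  stopifnot(inherits(aln, "labeled_alignment"))
  m <- aln$mat
  n_states <- vapply(seq_len(ncol(m)), function(j) {
    length(unique(m[m[, j] %in% c("A", "C", "G", "T"), j]))
  }, integer(1))
  which(n_states >= 2L)
}

# Per-population base counts at one column; missing/ambiguous excluded.
site_base_counts <- function(aln, column, pops = sort(unique(aln$populations))) {
  col <- aln$mat[, column]
  keep <- col %in% c("A", "C", "G", "T")
  tab <- table(factor(aln$populations[keep], levels = pops),
               factor(col[keep], levels = c("A", "C", "G", "T")))
  matrix(as.integer(tab), nrow = length(pops),
         dimnames = list(pops, c("A", "C", "G", "T")))
}
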