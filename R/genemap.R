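#' Gene maps over a concatenated alignment
#'
#' A gene map records where each gene sits inside the concatenated alignment
#' (1-based inclusive columns) and the reading-frame offset of its first
#' column, so concatenated coordinates can be translated to gene-relative
#' positions and codon positions. The default map is the two concatenated
#' mitochondrial NADH dehydrogenase genes used throughout the package:
#' ND2 (1046 bp) followed by ND5 (1839 bp), both in frame 0, translated with
#' the vertebrate mitochondrial genetic code.
#'
#' @param gene Character vector of gene names.
#' @param start,end Integer vectors, 1-based inclusive columns on the
#'   concatenated alignment.
#' @param frame Integer vector in `{0,1,2}`: offset of the first column from
#'   a codon start (0 means the gene starts on codon position 1).
#' @param genetic_code Identifier passed to [Biostrings::getGeneticCode()];
#'   default `"2"`, the vertebrate mitochondrial code.
#' @return A data frame of class `gene_map`.
#' @export
gene_map <- function(gene, start, end, frame = 0L, genetic_code = "2") {
  gm <- data.frame(gene = as.character(gene),
                   start = as.integer(start),
                   end = as.integer(end),
                   frame = as.integer(rep_len(frame, length(gene))),
                   stringsAsFactors = FALSE)
  if (any(gm$start < 1L) || any(gm$end < gm$start))
    stop("invalid gene coordinates")
  if (!all(gm$frame %in% 0:2))
    stop("frame must be 0, 1 or 2")
  gm <- gm[order(gm$start), , drop = FALSE]
  if (nrow(gm) > 1L && any(gm$start[-1L] <= gm$end[-nrow(gm)]))
    stop("gene entries overlap")
  attr(gm, "genetic_code") <- genetic_code
  class(gm) <- c("gene_map", "data.frame")
  gm
}

#' @rdname gene_map
#' @export
default_gene_map <- function() {
  gene_map(gene = c("ND2", "ND5"),
           start = c(1L, 1047L),
           end = c(1046L, 2885L),
           frame = c(0L, 0L))
}

#' Read a gene map from a TSV file
#'
#' Expects columns `gene<TAB>start<TAB>end<TAB>frame` (header lines starting
#' with `#` allowed).
#'
#' @param path TSV path.
#' @inheritParams gene_map
#' @return A [gene_map()].
#' @export
read_gene_map <- function(path, genetic_code = "2") {
  x <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                         col.names = c("gene", "start", "end", "frame"),
                         colClasses = c("character", "integer", "integer",
                                        "integer"))
  gene_map(x$gene, x$start, x$end, x$frame, genetic_code = genetic_code)
}

#' Map a concatenated column to a gene-relative position (and back)
#'
#' `gene_coordinates()` converts a 1-based concatenated column to
#' `(gene, gene_position)`; columns falling outside every gene return gene
#' `"unmapped"` rather than an error. `concat_column()` is the inverse.
#'
#' @param column 1-based concatenated column index.
#' @param gmap A [gene_map()].
#' @return For `gene_coordinates()`, a list with `gene`, `gene_position`
#'   (1-based within the gene; `NA` when unmapped) and `codon_position`
#'   (1, 2, 3 or `NA`).
#' @export
gene_coordinates <- function(column, gmap) {
  stopifnot(length(column) == 1L, column >= 1L)
  hit <- which(gmap$start <= column & column <= gmap$end)
  if (!length(hit))
    return(list(gene = "unmapped", gene_position = NA_integer_,
                codon_position = NA_integer_))
  pos <- column - gmap$start[hit] + 1L
  cp <- ((pos - 1L - gmap$frame[hit]) %% 3L) + 1L
  list(gene = gmap$gene[hit], gene_position = as.integer(pos),
       codon_position = as.integer(cp))
}

#' @rdname gene_coordinates
#' @param gene Gene name present in `gmap`.
#' @param gene_position 1-based position within the gene.
#' @export
concat_column <- function(gene, gene_position, gmap) {
  hit <- match(gene, gmap$gene)
  if (is.na(hit)) stop("unknown gene: ", gene)
  col <- gmap$start[hit] + as.integer(gene_position) - 1L
  if (col > gmap$end[hit]) stop("position beyond end of gene ", gene)
  col
}
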