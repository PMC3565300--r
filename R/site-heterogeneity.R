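#' Two-sided Fisher exact test on a 2 x K table
#'
#' Exact test of homogeneity of base composition between two populations.
#' For 2 x 2 tables the two-sided p-value is the sum of hypergeometric
#' probabilities of all tables with the same margins whose point probability
#' does not exceed that of the observed table. For 2 x K (K > 2) the
#' Freeman-Halton extension is computed by exhaustive enumeration of all
#' tables with the fixed margins (feasible for K <= 4 at the sample sizes
#' this package targets: enumeration runs over the K-1 smallest column
#' sums). Degenerate tables (a zero row or column margin) return p = 1 with
#' a warning, since no heterogeneity is testable.
#'
#' @param tab Integer matrix with 2 rows (populations) and K >= 2 columns
#'   (bases).
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2L || ncol(tab) < 2L)
    stop("need a 2 x K table with K >= 2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || sum(cs > 0) < 2L) {
    warning("degenerate table (zero margin); p = 1")
    return(1)
  }
  # drop all-zero columns: they contribute nothing
  tab <- tab[, cs > 0, drop = FALSE]
  cs <- colSums(tab)
  if (ncol(tab) == 2L) {
    # 2x2: condition on margins; x = tab[1,1] ~ hypergeometric
    N <- sum(tab); r1 <- rs[1]
    x <- tab[1, 1]
    support <- max(0, r1 - cs[2]):min(r1, cs[1])
    probs <- stats::dhyper(support, cs[1], cs[2], r1)
    p_obs <- stats::dhyper(x, cs[1], cs[2], r1)
    return(min(1, sum(probs[probs <= p_obs * (1 + 1e-7)])))
  }
  freeman_halton(tab)
}

# Freeman-Halton exact p for a 2xK table by full enumeration.
# Enumerates row-1 counts x_1..x_{K-1} over the K-1 smallest column sums;
# x_K is determined by the row margin. Probability of a table with fixed
# margins: prod_j C(c_j, x_j) / C(N, r1).
freeman_halton <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  ord <- order(cs)               # enumerate smallest columns first
  cs <- cs[ord]
  obs <- tab[1, ord]
  K <- length(cs); r1 <- rs[1]
  lden <- lchoose(N, r1)
  lp_obs <- sum(lchoose(cs, obs)) - lden
  # recursive enumeration over x_1..x_{K-1}
  ptot <- 0
  grid <- vector("list", K - 1L)
  for (j in seq_len(K - 1L)) grid[[j]] <- 0:min(cs[j], r1)
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  partial <- rowSums(combos)
  xK <- r1 - partial
  ok <- xK >= 0 & xK <= cs[K]
  if (!any(ok)) stop("internal error: empty table enumeration")
  combos <- combos[ok, , drop = FALSE]; xK <- xK[ok]
  lp <- lchoose(cs[K], xK) - lden
  for (j in seq_len(K - 1L)) lp <- lp + lchoose(cs[j], combos[[j]])
  min(1, sum(exp(lp[lp <= lp_obs + 1e-7])))
}

#' Base counts per population at one variable column
#'
#' @param aln A [labeled_alignment()] with exactly two populations (or use
#'   `pop_pair` to pick two).
#' @param column 1-based concatenated column index; must be variable.
#' @param pop_pair Optional character vector of two population names.
#' @return 2 x 4 integer matrix (populations x `A,C,G,T`), missing bases
#'   excluded.
#' @export
site_table <- function(aln, column, pop_pair = NULL) {
  stopifnot(inherits(aln, "labeled_alignment"))
  if (is.null(pop_pair)) {
    pop_pair <- sort(unique(aln$populations))
    if (length(pop_pair) != 2L)
      stop("exactly 2 populations required (got ", length(pop_pair), ")")
  }
  keep <- aln$populations %in% pop_pair
  sub <- aln
  sub$mat <- aln$mat[keep, , drop = FALSE]
  sub$populations <- aln$populations[keep]
  tab <- site_base_counts(sub, column, pops = pop_pair)
  if (sum(colSums(tab) > 0) < 2L)
    stop("column ", column, " is not variable")
  tab
}

#' Annotate a column's codon position and synonymy
#'
#' Determines the codon position of a column from the gene map's frame, and
#' whether all observed substitutions at the column are synonymous under the
#' map's genetic code (default: vertebrate mitochondrial, table 2). Synonymy
#' is assessed against the codon contexts actually observed in the
#' alignment: for every complete observed codon spanning the column, each
#' observed base is substituted at the focal position; the column is
#' synonymous when no such swap changes the encoded amino acid.
#'
#' @param aln A [labeled_alignment()].
#' @param column 1-based concatenated column.
#' @param gmap A [gene_map()].
#' @return List with `gene`, `gene_position`, `codon_position` (`NA` when the
#'   column is unmapped), `is_synonymous` (`NA` when unmapped or no complete
#'   codon observed) and `is_transition_only`.
#' @export
annotate_synonymy <- function(aln, column, gmap) {
  gc <- gene_coordinates(column, gmap)
  bases <- unique(aln$mat[aln$mat[, column] %in% c("A", "C", "G", "T"),
                          column])
  ti_only <- length(bases) >= 2L &&
    (all(bases %in% c("A", "G")) || all(bases %in% c("C", "T")))
  if (identical(gc$gene, "unmapped"))
    return(c(gc, list(is_synonymous = NA, is_transition_only = ti_only)))
  hit <- match(gc$gene, gmap$gene)
  codon_start <- column - (gc$codon_position - 1L)
  codon_cols <- codon_start + 0:2
  if (codon_cols[1] < gmap$start[hit] || codon_cols[3] > gmap$end[hit])
    return(c(gc, list(is_synonymous = NA, is_transition_only = ti_only)))
  codons <- apply(aln$mat[, codon_cols, drop = FALSE], 1, paste, collapse = "")
  codons <- unique(codons[grepl("^[ACGT]{3}$", codons)])
  if (!length(codons) || length(bases) < 2L)
    return(c(gc, list(is_synonymous = NA, is_transition_only = ti_only)))
  code <- Biostrings::getGeneticCode(attr(gmap, "genetic_code"))
  syn <- all(vapply(codons, function(cd) {
    variants <- vapply(bases, function(b) {
      v <- strsplit(cd, "")[[1]]
      v[gc$codon_position] <- b
      paste(v, collapse = "")
    }, character(1))
    length(unique(code[variants])) == 1L
  }, logical(1)))
  c(gc, list(is_synonymous = syn, is_transition_only = ti_only))
}

#' Scan all variable sites for base-composition heterogeneity
#'
#' The per-site engine of the analysis: for every variable column, builds
#' the 2 x K base-count table between the two populations, runs the exact
#' test, annotates codon position and synonymy, and flags significance at a
#' raw alpha (default 0.01). Raw p-values are always reported; Benjamini-
#' Hochberg q-values are emitted alongside as a clearly non-default aid --
#' the flagging itself uses the uncorrected alpha.
#'
#' @param aln A [labeled_alignment()] with exactly two populations.
#' @param gmap A [gene_map()] (default [default_gene_map()] when the
#'   alignment is 2885 columns, otherwise a single unnamed frame-0 gene
#'   spanning the alignment).
#' @param alpha Raw significance level for flagging (default 0.01).
#' @return Data frame of class `site_scan`, one row per variable site,
#'   sorted by column: `column`, `gene`, `gene_position`, `codon_position`,
#'   per-population `A/C/G/T` counts, `p_value`, `q_value`,
#'   `is_transition_only`, `is_synonymous`, `significant`.
#' @export
scan_sites <- function(aln, gmap = NULL, alpha = 0.01) {
  stopifnot(inherits(aln, "labeled_alignment"))
  pops <- sort(unique(aln$populations))
  if (length(pops) != 2L)
    stop("exactly 2 populations required (got ", length(pops), ")")
  if (is.null(gmap)) {
    gmap <- if (aln$length == 2885L) default_gene_map() else
      gene_map("gene1", 1L, aln$length, 0L)
  }
  cols <- variable_sites(aln)
  if (!length(cols)) {
    out <- empty_scan(pops)
    attr(out, "alpha") <- alpha
    class(out) <- c("site_scan", "data.frame")
    return(out)
  }
  rows <- lapply(cols, function(cl) {
    tab <- site_base_counts(aln, cl, pops)
    used <- colSums(tab) > 0
    p <- fisher_exact(tab[, used, drop = FALSE])
    ann <- annotate_synonymy(aln, cl, gmap)
    r <- data.frame(column = cl, gene = ann$gene,
                    gene_position = ann$gene_position,
                    codon_position = ann$codon_position,
                    stringsAsFactors = FALSE)
    for (pp in pops) for (b in c("A", "C", "G", "T"))
      r[[paste(pp, b, sep = "_")]] <- tab[pp, b]
    r$p_value <- p
    r$is_transition_only <- ann$is_transition_only
    r$is_synonymous <- ann$is_synonymous
    r
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  out <- out[order(out$column), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("site_scan", "data.frame")
  out
}

empty_scan <- function(pops) {
  out <- data.frame(column = integer(0), gene = character(0),
                    gene_position = integer(0), codon_position = integer(0),
                    stringsAsFactors = FALSE)
  for (pp in pops) for (b in c("A", "C", "G", "T"))
    out[[paste(pp, b, sep = "_")]] <- integer(0)
  out$p_value <- numeric(0)
  out$is_transition_only <- logical(0)
  out$is_synonymous <- logical(0)
  out$q_value <- numeric(0)
  out$significant <- logical(0)
  out
}

#' @export
print.site_scan <- function(x, ...) {
  cat("Site scan:", nrow(x), "variable sites,",
      sum(x$significant), "heterogeneous at alpha =",
      attr(x, "alpha"), "\n")
  if (any(x$significant))
    print.data.frame(x[x$significant, , drop = FALSE], digits = 4)
  invisible(x)
}

#' Write a site-scan table as TSV
#'
#' Mirrors the layout of a published per-site heterogeneity table: gene,
#' gene position, concatenated column, codon position, per-population base
#' counts, p-value (4 decimal places), q-value and synonymy flag.
#'
#' @param scan A `site_scan` from [scan_sites()].
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_site_scan <- function(scan, path) {
  out <- as.data.frame(scan)
  out$p_value <- sprintf("%.4f", out$p_value)
  out$q_value <- sprintf("%.4f", out$q_value)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
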