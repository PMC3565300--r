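#' Haplotype diversity with sampling variance
#'
#' Nei's unbiased haplotype (gene) diversity
#' \eqn{h = n(1 - \sum p_i^2)/(n-1)} with its sampling variance
#' (Nei 1987, eq. 8.12):
#' \deqn{V(h) = \frac{2}{n(n-1)}\left\{2(n-2)\left[\sum p_i^3 -
#'   \left(\sum p_i^2\right)^2\right] + \sum p_i^2 -
#'   \left(\sum p_i^2\right)^2\right\}}
#' The square root is reported as a standard error; published tables often
#' print such values after a plus-minus sign without naming the formula.
#'
#' @param counts Integer vector of haplotype counts in one population
#'   (order irrelevant).
#' @return List with `h` and `h_se`.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("insufficient sample: need n >= 2")
  p <- counts / n
  s2 <- sum(p^2)
  h <- n * (1 - s2) / (n - 1)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - s2^2) + s2 - s2^2)
  list(h = h, h_se = sqrt(max(v, 0)))
}

#' Nucleotide diversity with sampling variance
#'
#' Average proportion of nucleotide differences per site between two
#' sequences, \eqn{\pi = \binom{n}{2}^{-1} \sum_{i<j} d_{ij}}, where
#' \eqn{d_{ij}} is the p-distance computed over sites non-missing in both
#' members of the pair (pairwise deletion). The total variance follows
#' Nei 1987, eq. 10.7:
#' \deqn{V(\pi) = \frac{n+1}{3(n-1)}\frac{\pi}{L} +
#'   \frac{2(n^2+n+3)}{9n(n-1)}\pi^2}
#' with \eqn{L} the alignment length. p-distance (not a model-corrected
#' distance) is used deliberately: diversity statistics follow Nei's
#' estimators, while model corrections are reserved for tree building.
#'
#' @param aln A [labeled_alignment()], typically subset to one population
#'   (see [subset_population()]).
#' @return List with `pi`, `pi_se`, and `n_pairs`.
#' @export
nucleotide_diversity <- function(aln) {
  stopifnot(inherits(aln, "labeled_alignment"))
  n <- length(aln$sample_ids)
  if (n < 2) stop("insufficient sample: need n >= 2")
  m <- aln$mat
  good <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      shared <- good[i, ] & good[j, ]
      L <- sum(shared)
      if (L == 0L) stop("no shared non-missing sites for a pair")
      total <- total + sum(m[i, shared] != m[j, shared]) / L
    }
  }
  pi <- total / (n * (n - 1) / 2)
  L <- aln$length
  v <- (n + 1) / (3 * (n - 1)) * pi / L +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(pi = pi, pi_se = sqrt(max(v, 0)), n_pairs = n * (n - 1) / 2)
}

#' Subset an alignment to one population
#'
#' @param aln A [labeled_alignment()].
#' @param population Population name.
#' @return A [labeled_alignment()] containing only that population's samples.
#' @export
subset_population <- function(aln, population) {
  keep <- aln$populations == population
  if (!any(keep)) stop("unknown population: ", population)
  labeled_alignment(unname(aln$sequences[keep]), aln$sample_ids[keep],
                    aln$populations[keep])
}

#' Per-population diversity table
#'
#' Computes sample size, haplotype count, haplotype diversity and nucleotide
#' diversity (each with standard errors) for every population in the
#' alignment.
#'
#' @param aln A [labeled_alignment()].
#' @return Data frame with one row per population: `population`, `n`,
#'   `n_haplotypes`, `h`, `h_se`, `pi`, `pi_se`.
#' @export
diversity_table <- function(aln) {
  stopifnot(inherits(aln, "labeled_alignment"))
  pops <- sort(unique(aln$populations))
  rows <- lapply(pops, function(p) {
    sub <- subset_population(aln, p)
    hs <- collapse_haplotypes(sub)
    counts <- rowSums(hs$counts)
    hd <- haplotype_diversity(counts)
    nd <- nucleotide_diversity(sub)
    data.frame(population = p, n = length(sub$sample_ids),
               n_haplotypes = length(hs$haplotype_seqs),
               h = hd$h, h_se = hd$h_se, pi = nd$pi, pi_se = nd$pi_se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
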