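#' Deterministic benchmark alignment with a known footprint clade
#'
#' Builds a fully deterministic 151-sequence alignment (91 northern, 60
#' southern samples, 2885 columns = ND2 1046 bp + ND5 1839 bp) that
#' reproduces, by construction, the canonical footprint situation the
#' pipeline is designed to detect:
#' \itemize{
#'   \item three heterogeneous third-codon-position columns whose
#'     per-population base counts are north C:91 / south C:54,T:6 at
#'     ND2-501, north A:91 / south A:54,G:6 at ND5-1239, and north C:91 /
#'     south C:55,T:5 at ND5-1812 -- the only columns significant at
#'     alpha = 0.01, all synonymous transitions (the engineered codons are
#'     4-fold degenerate);
#'   \item a 5-tip southern clade (S-26, S-36, S-37, S-42, S-45) carrying
#'     the derived state at all three sites, with a 3-tip northern sister
#'     clade (N-24, N-75, N-82); the ND5-1812 substitution is carried by
#'     the southern clade alone (apomorphic), while the other two recur
#'     once each on unrelated southern tips (S-50, S-55);
#'   \item two deep background lineages, mixed in both populations, so
#'     midpoint rooting falls on the deep split as in a real
#'     two-lineage mitochondrial gene tree.
#' }
#' All other columns are monomorphic. The function has no randomness; its
#' output is bit-identical across runs.
#'
#' @return A [labeled_alignment()] with populations `north` and `south`.
#' @export
make_table1_fixture <- function() {
  L <- 2885L
  # 4-codon background unit, all 4-fold degenerate families (Leu, Ala,
  # Thr, Val), so any third-position change is synonymous
  unit <- strsplit("CTAGCCACAGTG", "")[[1]]
  bg <- rep(unit, length.out = L)
  # fix the codon context of the three heterogeneous sites (Leu family)
  bg[499:501] <- c("C", "T", "C")
  bg[2283:2285] <- c("C", "T", "A")
  bg[2856:2858] <- c("C", "T", "C")

  ids <- c(paste0("N-", 1:91), paste0("S-", 1:60))
  pops <- stats::setNames(rep(c("north", "south"), c(91, 60)), ids)
  mat <- matrix(rep(bg, each = length(ids)), nrow = length(ids),
                dimnames = list(ids, NULL))
  transition <- function(b) c(A = "G", G = "A", C = "T", T = "C")[[b]]

  five_s <- c("S-26", "S-36", "S-37", "S-42", "S-45")
  three_n <- c("N-24", "N-75", "N-82")
  eight <- c(five_s, three_n)
  # S-50 and S-55 (the recurrent carriers) live in the deep second
  # lineage, so their convergent states sit on clades unrelated to the
  # footprint clade
  b_lineage <- c(paste0("N-", setdiff(1:32, 24)),
                 paste0("S-", c(1:20, 50, 55)))

  # clade-defining private columns (third positions, synonymous)
  for (cl in c(12L, 24L, 48L)) mat[eight, cl] <- transition(bg[cl])
  mat[three_n, 36L] <- transition(bg[36L])
  # the three heterogeneous sites
  mat[c(five_s, "S-50"), 501L] <- "T"
  mat[c(five_s, "S-55"), 2285L] <- "G"
  mat[five_s, 2858L] <- "T"
  # deep second lineage, present in both populations
  for (cl in seq(1049L, by = 30L, length.out = 20L))
    mat[b_lineage, cl] <- transition(bg[cl])

  labeled_alignment(apply(mat, 1, paste, collapse = ""), ids, pops)
}
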