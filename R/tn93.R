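#' Tamura-Nei (1993) distance with invariant-sites and gamma corrections
#'
#' Closed-form TN93 distance between two aligned sequences, from the
#' observed proportions of A<->G transitions (P1), C<->T transitions (P2)
#' and transversions (Q), with base frequencies averaged over the pair
#' (pairwise deletion for missing data). With purine/pyrimidine sums
#' \eqn{g_R = g_A + g_G}, \eqn{g_Y = g_C + g_T} and
#' \deqn{k_1 = 2 g_A g_G / g_R,\quad k_2 = 2 g_T g_C / g_Y,\quad
#'       k_3 = 2\,(g_R g_Y - g_A g_G g_Y/g_R - g_T g_C g_R/g_Y)}
#' the distance is \eqn{d = -k_1 \log w_1 - k_2 \log w_2 - k_3 \log w_3}
#' with
#' \deqn{w_1 = 1 - P_1/k_1 - Q/(2 g_R),\quad
#'       w_2 = 1 - P_2/k_2 - Q/(2 g_Y),\quad
#'       w_3 = 1 - Q/(2 g_R g_Y).}
#' The `+I` correction divides the observed proportions by
#' \eqn{1 - p_{inv}} before the formula; the `+G` correction (gamma rate
#' heterogeneity with shape \eqn{\alpha}) replaces every \eqn{-\log w} by
#' \eqn{\alpha\,(w^{-1/\alpha} - 1)}.
#'
#' @param seq1,seq2 Equal-length nucleotide strings.
#' @param alpha Gamma shape parameter; `NULL` or `Inf` disables the gamma
#'   correction. Smaller alpha means stronger rate heterogeneity and larger
#'   corrected distances.
#' @param p_inv Proportion of invariant sites in `[0, 1)`; 0 disables the
#'   correction.
#' @return Distance in substitutions per site.
#' @export
tn93_distance <- function(seq1, seq2, alpha = NULL, p_inv = 0) {
  a <- strsplit(toupper(seq1), "")[[1]]
  b <- strsplit(toupper(seq2), "")[[1]]
  if (length(a) != length(b)) stop("sequence length mismatch")
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(keep)) stop("no shared non-missing sites")
  tn93_from_chars(a[keep], b[keep], alpha, p_inv)
}

tn93_from_chars <- function(a, b, alpha, p_inv, label = "pair") {
  L <- length(a)
  freq <- (table(factor(a, levels = c("A", "C", "G", "T"))) +
           table(factor(b, levels = c("A", "C", "G", "T")))) / (2 * L)
  gA <- freq[["A"]]; gC <- freq[["C"]]; gG <- freq[["G"]]; gT <- freq[["T"]]
  gR <- gA + gG; gY <- gC + gT
  diff <- a != b
  pur <- c("A", "G")
  is_ts1 <- diff & a %in% pur & b %in% pur                 # A<->G
  is_ts2 <- diff & !(a %in% pur) & !(b %in% pur)           # C<->T
  P1 <- sum(is_ts1) / L
  P2 <- sum(is_ts2) / L
  Q <- sum(diff & !is_ts1 & !is_ts2) / L
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must lie in [0, 1)")
  if (p_inv > 0) {
    P1 <- P1 / (1 - p_inv); P2 <- P2 / (1 - p_inv); Q <- Q / (1 - p_inv)
  }
  if (P1 + P2 + Q == 0) return(0)
  k1 <- if (gR > 0) 2 * gA * gG / gR else 0
  k2 <- if (gY > 0) 2 * gT * gC / gY else 0
  k3 <- 2 * (gR * gY - (if (gR > 0) gA * gG * gY / gR else 0) -
               (if (gY > 0) gT * gC * gR / gY else 0))
  w1 <- if (k1 > 0) 1 - P1 / k1 - Q / (2 * gR) else if (P1 > 0) -1 else 1
  w2 <- if (k2 > 0) 1 - P2 / k2 - Q / (2 * gY) else if (P2 > 0) -1 else 1
  w3 <- if (gR * gY > 0) 1 - Q / (2 * gR * gY) else if (Q > 0) -1 else 1
  if (w1 <= 0 || w2 <= 0 || w3 <= 0)
    stop("saturated pair: ", label,
         " (log argument <= 0 under TN93)")
  corr <- if (is.null(alpha) || !is.finite(alpha)) {
    function(w) -log(w)
  } else {
    if (alpha <= 0) stop("alpha must be > 0")
    function(w) alpha * (w^(-1 / alpha) - 1)
  }
  d <- (if (k1 > 0) k1 * corr(w1) else 0) +
       (if (k2 > 0) k2 * corr(w2) else 0) +
       k3 * corr(w3)
  max(d, 0)
}

#' Pairwise TN93(+I+G) distance matrix
#'
#' Computes all pairwise distances for the samples of an alignment (or the
#' distinct haplotypes of a [collapse_haplotypes()] result via
#' `level = "haplotype"`). Base frequencies are pair-averaged by default,
#' the convention of the original model; `freqs = "alignment"` uses
#' alignment-wide frequencies for every pair. Any saturated pair aborts with
#' the offending pair named.
#'
#' @param aln A [labeled_alignment()].
#' @inheritParams tn93_distance
#' @param freqs `"pair"` (default) or `"alignment"`.
#' @param level `"sample"` (default, one row per individual) or
#'   `"haplotype"`.
#' @return Object of class `tn93_dist`: list with `ids`, symmetric matrix
#'   `d`, and `model` descriptor (`name`, `alpha`, `p_inv`).
#' @export
distance_matrix <- function(aln, alpha = NULL, p_inv = 0,
                            freqs = c("pair", "alignment"),
                            level = c("sample", "haplotype")) {
  stopifnot(inherits(aln, "labeled_alignment"))
  freqs <- match.arg(freqs)
  level <- match.arg(level)
  if (level == "haplotype") {
    hs <- collapse_haplotypes(aln)
    seqs <- hs$haplotype_seqs
    ids <- paste0("hap", seq_along(seqs))
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  } else {
    ids <- aln$sample_ids
    mat <- aln$mat
  }
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  good <- matrix(mat %in% c("A", "C", "G", "T"), nrow = n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      keep <- good[i, ] & good[j, ]
      if (!any(keep))
        stop("no shared non-missing sites for pair ", ids[i], "/", ids[j])
      a <- mat[i, keep]; b <- mat[j, keep]
      if (freqs == "alignment") {
        dij <- tn93_fixed_freqs(a, b, base_freqs(mat), alpha, p_inv,
                                paste(ids[i], ids[j], sep = "/"))
      } else {
        dij <- tryCatch(
          tn93_from_chars(a, b, alpha, p_inv,
                          label = paste(ids[i], ids[j], sep = "/")),
          error = function(e) stop(conditionMessage(e), call. = FALSE))
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  structure(list(ids = ids, d = d,
                 model = list(name = "TN93+I+G", alpha = alpha,
                              p_inv = p_inv, freqs = freqs)),
            class = "tn93_dist")
}

base_freqs <- function(mat) {
  v <- as.vector(mat)
  v <- v[v %in% c("A", "C", "G", "T")]
  tab <- table(factor(v, levels = c("A", "C", "G", "T")))
  as.numeric(tab) / sum(tab)
}

# TN93 with externally supplied base frequencies (alignment-wide mode).
tn93_fixed_freqs <- function(a, b, freq, alpha, p_inv, label) {
  L <- length(a)
  gA <- freq[1]; gC <- freq[2]; gG <- freq[3]; gT <- freq[4]
  gR <- gA + gG; gY <- gC + gT
  diff <- a != b
  pur <- c("A", "G")
  is_ts1 <- diff & a %in% pur & b %in% pur
  is_ts2 <- diff & !(a %in% pur) & !(b %in% pur)
  P1 <- sum(is_ts1) / L; P2 <- sum(is_ts2) / L
  Q <- sum(diff & !is_ts1 & !is_ts2) / L
  if (p_inv > 0) {
    P1 <- P1 / (1 - p_inv); P2 <- P2 / (1 - p_inv); Q <- Q / (1 - p_inv)
  }
  if (P1 + P2 + Q == 0) return(0)
  k1 <- if (gR > 0) 2 * gA * gG / gR else 0
  k2 <- if (gY > 0) 2 * gT * gC / gY else 0
  k3 <- 2 * (gR * gY - (if (gR > 0) gA * gG * gY / gR else 0) -
               (if (gY > 0) gT * gC * gR / gY else 0))
  w1 <- if (k1 > 0) 1 - P1 / k1 - Q / (2 * gR) else if (P1 > 0) -1 else 1
  w2 <- if (k2 > 0) 1 - P2 / k2 - Q / (2 * gY) else if (P2 > 0) -1 else 1
  w3 <- if (gR * gY > 0) 1 - Q / (2 * gR * gY) else if (Q > 0) -1 else 1
  if (w1 <= 0 || w2 <= 0 || w3 <= 0)
    stop("saturated pair: ", label)
  corr <- if (is.null(alpha) || !is.finite(alpha)) function(w) -log(w)
          else function(w) alpha * (w^(-1 / alpha) - 1)
  max((if (k1 > 0) k1 * corr(w1) else 0) +
      (if (k2 > 0) k2 * corr(w2) else 0) + k3 * corr(w3), 0)
}

#' @export
print.tn93_dist <- function(x, ...) {
  cat("TN93 distance matrix:", length(x$ids), "taxa; alpha =",
      if (is.null(x$model$alpha)) "none" else x$model$alpha,
      "; p_inv =", x$model$p_inv, "\n")
  invisible(x)
}

#' Write a distance matrix (PHYLIP square format or TSV)
#'
#' @param dm A `tn93_dist` from [distance_matrix()].
#' @param path Output path.
#' @param format `"phylip"` (square, default) or `"tsv"`.
#' @return Invisibly, the path.
#' @export
write_distance_matrix <- function(dm, path, format = c("phylip", "tsv")) {
  format <- match.arg(format)
  if (format == "phylip") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", length(dm$ids)), con)
    for (i in seq_along(dm$ids)) {
      writeLines(paste(c(formatC(dm$ids[i], width = -10),
                         sprintf("%.8f", dm$d[i, ])), collapse = "  "), con)
    }
  } else {
    utils::write.table(data.frame(id = dm$ids, dm$d, check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
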