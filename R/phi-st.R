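#' AMOVA fixation index phi-ST between two populations
#'
#' Analysis of molecular variance for one grouping level, following the
#' classic molecular-variance framework (Excoffier, Smouse & Quattro 1992),
#' on squared pairwise distances:
#' \deqn{SS_{total} = \frac{1}{N}\sum_{i<j} d_{ij}^2,\qquad
#'   SS_{within} = \sum_p \frac{1}{n_p}\sum_{i<j \in p} d_{ij}^2}
#' with \eqn{SS_{among} = SS_{total} - SS_{within}}; mean squares use
#' \eqn{df_{among} = P-1} and \eqn{df_{within} = N-P}; the among-population
#' variance component is \eqn{\sigma_a^2 = (MS_{among} - MS_{within})/n'}
#' with \eqn{n' = (N - \sum_p n_p^2/N)/(P-1)}, \eqn{\sigma_w^2 =
#' MS_{within}}, and \eqn{\phi_{ST} = \sigma_a^2/(\sigma_a^2+\sigma_w^2)}.
#' Negative estimates are legitimate (sampling noise around zero
#' differentiation) and are never clamped. Significance comes from
#' permuting individuals across populations with sizes fixed; the p-value
#' uses the +1/+1 correction so it is never exactly zero.
#'
#' By default the supplied model distances are squared (the convention when
#' an arbitrary distance matrix feeds an AMOVA); `square = FALSE` uses them
#' as-is, for matrices that already represent squared Euclidean
#' differences.
#'
#' @param dm A `tn93_dist` from [distance_matrix()] or a symmetric numeric
#'   matrix with sample ids as dimnames.
#' @param populations Named character vector: population per sample id;
#'   exactly two populations, each with at least two members.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer random seed (mandatory: permutation p-values must be
#'   reproducible).
#' @param square Square the distances before the sums of squares
#'   (default TRUE).
#' @return Object of class `phi_st_result`: `phi_st`, `p_value`, `n_perm`,
#'   `sigma_among`, `sigma_within`, `df`, and the population sizes.
#' @export
amova_phi_st <- function(dm, populations, n_perm = 10000L, seed,
                         square = TRUE) {
  if (missing(seed)) stop("seed is required for the permutation test")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  D <- if (inherits(dm, "tn93_dist")) dm$d else as.matrix(dm)
  ids <- rownames(D)
  if (is.null(names(populations))) {
    if (length(populations) != nrow(D))
      stop("populations must be named by sample id or match dm order")
    names(populations) <- ids
  }
  missing_ids <- setdiff(ids, names(populations))
  if (length(missing_ids))
    stop("no population for: ", paste(missing_ids, collapse = ", "))
  grp <- populations[ids]
  pops <- sort(unique(grp))
  if (length(pops) != 2L)
    stop("exactly 2 populations required (got ", length(pops), ")")
  sizes <- table(grp)
  if (any(sizes < 2L)) stop("each population needs >= 2 members")
  D2 <- if (square) D^2 else D
  obs <- phi_from_d2(D2, grp == pops[1])
  n <- nrow(D2)
  n1 <- sum(grp == pops[1])
  if (is.na(obs$phi)) {
    warning("no molecular variance; phi_ST undefined")
    p_value <- NA_real_
  } else {
    set.seed(as.integer(seed))
    hits <- 0L
    for (b in seq_len(n_perm)) {
      perm <- logical(n)
      perm[sample.int(n, n1)] <- TRUE
      phi_b <- phi_from_d2(D2, perm)$phi
      if (!is.na(phi_b) && phi_b >= obs$phi - 1e-12) hits <- hits + 1L
    }
    p_value <- (hits + 1) / (n_perm + 1)
  }
  structure(list(phi_st = obs$phi,
                 p_value = p_value,
                 n_perm = as.integer(n_perm),
                 sigma_among = obs$sigma_a, sigma_within = obs$sigma_w,
                 df = c(among = 1L, within = n - 2L),
                 populations = stats::setNames(as.integer(sizes), pops),
                 squared_distances = square),
            class = "phi_st_result")
}

# Variance components from a squared-distance matrix and a 2-group split.
phi_from_d2 <- function(D2, in_first) {
  n <- nrow(D2)
  n1 <- sum(in_first); n2 <- n - n1
  tot <- sum(D2[upper.tri(D2)])
  w1 <- sum(D2[in_first, in_first][upper.tri(diag(n1))])
  w2 <- sum(D2[!in_first, !in_first][upper.tri(diag(n2))])
  ss_total <- tot / n
  ss_within <- w1 / n1 + w2 / n2
  ss_among <- ss_total - ss_within
  ms_among <- ss_among / 1
  ms_within <- ss_within / (n - 2)
  n_prime <- (n - (n1^2 + n2^2) / n) / 1
  sigma_a <- (ms_among - ms_within) / n_prime
  sigma_w <- ms_within
  denom <- sigma_a + sigma_w
  phi <- if (denom > 0) sigma_a / denom else NA_real_
  list(phi = phi, sigma_a = sigma_a, sigma_w = sigma_w)
}

#' @export
print.phi_st_result <- function(x, ...) {
  cat(sprintf("phi_ST = %.5f (p = %.4g, %d permutations)\n",
              x$phi_st, x$p_value, x$n_perm))
  cat(sprintf("  sigma^2 among = %.6g, within = %.6g; n = %s\n",
              x$sigma_among, x$sigma_within,
              paste(sprintf("%s:%d", names(x$populations), x$populations),
                    collapse = ", ")))
  invisible(x)
}

#' Write a phi-ST result as JSON
#'
#' @param x A `phi_st_result`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_phi_st <- function(x, path) {
  jsonlite::write_json(
    list(phi_st = x$phi_st, p_value = x$p_value, n_perm = x$n_perm,
         sigma_among = x$sigma_among, sigma_within = x$sigma_within,
         populations = as.list(x$populations),
         squared_distances = x$squared_distances),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
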