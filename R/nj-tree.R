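#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration in the Studier-Keppler form: at each
#' step the pair minimizing
#' \eqn{Q(i,j) = (r-2) d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)} is joined,
#' with branch lengths from the usual split formulas. Ties in Q are broken
#' by the smallest (i, j) index pair under the stable cluster ordering
#' (input order, merged clusters appended), so output is deterministic.
#' Negative branch lengths, which NJ can produce on non-additive input, are
#' clamped to 0 with the deficit transferred to the sibling branch of the
#' join; the raw (unclamped) lengths are retained in the
#' `raw_edge_length` attribute. On additive input the method recovers the
#' generating topology and branch lengths exactly.
#'
#' @param dm A `tn93_dist` from [distance_matrix()], or a symmetric numeric
#'   matrix with dimnames.
#' @return An unrooted `ape::phylo` tree (stored with a basal
#'   trifurcation), tips labelled by the matrix ids.
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "tn93_dist")) {
    D <- dm$d
  } else {
    D <- as.matrix(dm)
  }
  ids <- rownames(D)
  n <- nrow(D)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  if (n < 3L) stop("need at least 3 taxa for neighbor joining")
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric")

  # cluster refs: positive = tip index, negative = internal node (-k)
  refs <- seq_len(n)
  merges <- list()        # per internal node: kids (refs), lens, raw lens
  Dm <- D
  while (length(refs) > 3L) {
    r <- length(refs)
    R <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- Dm[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- Dm[i, j] - li
    raw <- c(li, lj)
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(li + lj, 0); lj <- 0 }
    k <- length(merges) + 1L
    merges[[k]] <- list(kids = refs[c(i, j)], lens = c(li, lj), raw = raw)
    dnew <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    dnew <- dnew[-c(i, j)]
    Dm <- Dm[-c(i, j), -c(i, j), drop = FALSE]
    Dm <- rbind(cbind(Dm, dnew), c(dnew, 0))
    refs <- c(refs[-c(i, j)], -k)
  }
  # final trifurcation from the three-point formulas
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  lens <- c((d12 + d13 - d23) / 2,
            (d12 + d23 - d13) / 2,
            (d13 + d23 - d12) / 2)
  raw <- lens
  lens <- pmax(lens, 0)
  k <- length(merges) + 1L
  merges[[k]] <- list(kids = refs, lens = lens, raw = raw)

  build_phylo(ids, merges)
}

# Assemble an ape phylo from the merge list; preorder (cladewise) numbering.
build_phylo <- function(ids, merges) {
  n <- length(ids)
  M <- length(merges)
  edge <- matrix(0L, 0, 2)
  elen <- numeric(0)
  eraw <- numeric(0)
  next_num <- n + 1L
  recurse <- function(ref) {
    # returns ape node number for ref, emitting edges below it
    if (ref > 0) return(ref)
    cur <- next_num
    next_num <<- next_num + 1L
    m <- merges[[-ref]]
    for (q in seq_along(m$kids)) {
      kid_ref <- m$kids[q]
      if (kid_ref > 0) {
        edge <<- rbind(edge, c(cur, kid_ref))
        elen <<- c(elen, m$lens[q]); eraw <<- c(eraw, m$raw[q])
      } else {
        kid_num_at <- nrow(edge) + 1L
        edge <<- rbind(edge, c(cur, 0L))
        elen <<- c(elen, m$lens[q]); eraw <<- c(eraw, m$raw[q])
        edge[kid_num_at, 2] <<- recurse(kid_ref)
      }
    }
    cur
  }
  recurse(-M)
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = ids, Nnode = M),
                  class = "phylo")
  attr(tr, "order") <- "cladewise"
  attr(tr, "raw_edge_length") <- eraw
  tr
}

#' Root a tree for character mapping
#'
#' ACCTRAN optimization needs an orientation, but the source analyses rarely
#' state the rooting used. Two modes are exposed: midpoint rooting (default;
#' root at the midpoint of the longest tip-to-tip path, natural when two
#' deep lineages are present) and outgroup rooting on a named tip. A tree
#' whose branch lengths are all zero cannot be midpoint-rooted; it is
#' returned rooted at its basal node with a warning.
#'
#' @param tree An `ape::phylo`, typically from [neighbor_joining()].
#' @param root_tip Optional tip label; when given, the tree is rooted on
#'   that tip's branch instead of at the midpoint.
#' @return A rooted `ape::phylo`.
#' @export
midpoint_root <- function(tree, root_tip = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(root_tip)) {
    if (!root_tip %in% tree$tip.label)
      stop("unknown tip: ", root_tip)
    return(ape::root(tree, outgroup = root_tip, resolve.root = TRUE))
  }
  if (is.null(tree$edge.length) || sum(tree$edge.length) <= 0) {
    warning("all branch lengths zero; midpoint undefined, ",
            "rooting on the first tip")
    return(ape::root(tree, outgroup = tree$tip.label[1],
                     resolve.root = TRUE))
  }
  phangorn::midpoint(tree)
}

#' Newick serialization
#'
#' Thin wrappers over the standard Newick reader/writer, fixed at 10
#' significant digits for branch lengths so that write-then-read round-trips
#' are exact at that precision.
#'
#' @param tree An `ape::phylo`.
#' @param path File path.
#' @return `read_newick()` returns an `ape::phylo`; `write_newick()` returns
#'   the path invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!grepl(";", txt, fixed = TRUE))
    stop("malformed Newick: missing terminating ';' near position ",
         nchar(txt))
  open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (open != close)
    stop("malformed Newick: unbalanced parentheses (", open, " '(' vs ",
         close, " ')')")
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("malformed Newick: parse failed")
  tr
}
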