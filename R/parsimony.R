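# State sets are bitmasks: A=1, C=2, G=4, T=8; missing (N/-/?) = 15.
.base_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)

base_to_mask <- function(b) {
  m <- .base_bits[b]
  m[is.na(m)] <- 15L
  unname(m)
}

mask_to_base <- function(m) {
  # lowest-order state under the fixed A < C < G < T order (tie-break)
  names(.base_bits)[match(TRUE, bitwAnd(m, .base_bits) > 0L)]
}

#' Fitch small parsimony on a rooted tree
#'
#' Computes the minimum number of unordered state changes for one
#' nucleotide character on a fixed rooted tree. The downpass is Hartigan's
#' counting generalisation of the Fitch pass, which is exact for
#' polytomies too: at each internal node, each base is scored by the
#' number of children whose state set contains it; the node's set is the
#' arg-max, and the change count grows by (number of children) minus the
#' maximum count. On binary nodes this reduces exactly to the familiar
#' intersect-else-union rule. Missing tip states (`N`, `-`, `?`) are
#' treated as full ambiguity and never force a change.
#'
#' @param tree A rooted `ape::phylo` (binary, basal trifurcation or other
#'   polytomies allowed).
#' @param tip_states Named character vector, one base per tip label.
#' @return List with `score` (minimum changes) and `down` (integer vector of
#'   per-node state-set bitmasks, indexed by ape node number).
#' @export
fitch_parsimony <- function(tree, tip_states) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  missing_tips <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing_tips))
    stop("no state for tip(s): ", paste(missing_tips, collapse = ", "))
  states <- toupper(tip_states[tree$tip.label])
  nnode <- n + tree$Nnode
  down <- integer(nnode)
  down[seq_len(n)] <- base_to_mask(states)
  score <- 0L
  po <- ape::reorder.phylo(tree, "postorder")
  kids <- split(po$edge[, 2], po$edge[, 1])
  # postorder edge list guarantees children are finished before parents
  for (p in unique(po$edge[, 1])) {
    counts <- integer(4)
    for (ch in kids[[as.character(p)]])
      counts <- counts + as.integer(bitwAnd(down[ch], .base_bits) > 0L)
    K <- max(counts)
    down[p] <- sum(.base_bits[counts == K])
    score <- score + length(kids[[as.character(p)]]) - K
  }
  list(score = score, down = down)
}

#' ACCTRAN resolution of a Fitch reconstruction
#'
#' Resolves the ambiguity left by the Fitch downpass under accelerated
#' transformation: states are assigned root-to-tip, a node keeps its
#' parent's state whenever that state lies in the node's downpass set, and
#' otherwise switches immediately -- placing every change on the most
#' rootward branch where it is forced, so reversals are preferred over
#' parallel terminal changes. Remaining ties (the root's set, or the choice
#' of entering state on a forced change) are broken by the fixed
#' A < C < G < T order. The number of placed changes always equals the
#' Fitch minimum.
#'
#' @param tree A rooted `ape::phylo`.
#' @param fitch Result of [fitch_parsimony()] on the same tree.
#' @param column Optional site column carried through for reporting.
#' @return A `character_mapping` list: `column`, `states` (base per node,
#'   indexed by ape node number), `changes` (data frame: `edge`,
#'   `parent_node`, `child_node`, `from`, `to`), `score`.
#' @export
acctran_assign <- function(tree, fitch, column = NA_integer_) {
  n <- length(tree$tip.label)
  down <- fitch$down
  nnode <- n + tree$Nnode
  assigned <- character(nnode)
  root <- n + 1L
  assigned[root] <- mask_to_base(down[root])
  co <- ape::reorder.phylo(tree, "cladewise")
  changes <- list()
  for (e in seq_len(nrow(co$edge))) {
    p <- co$edge[e, 1]; ch <- co$edge[e, 2]
    pa <- assigned[p]
    pbit <- .base_bits[[pa]]
    if (bitwAnd(down[ch], pbit) > 0L) {
      assigned[ch] <- pa
    } else {
      assigned[ch] <- mask_to_base(down[ch])
      changes[[length(changes) + 1L]] <-
        data.frame(edge = e, parent_node = p, child_node = ch,
                   from = pa, to = assigned[ch], stringsAsFactors = FALSE)
    }
  }
  changes <- if (length(changes)) do.call(rbind, changes) else
    data.frame(edge = integer(0), parent_node = integer(0),
               child_node = integer(0), from = character(0),
               to = character(0), stringsAsFactors = FALSE)
  structure(list(column = column, states = assigned, changes = changes,
                 score = fitch$score, edge_order = "cladewise"),
            class = "character_mapping")
}

#' @export
print.character_mapping <- function(x, ...) {
  cat("Character mapping (column ", x$column, "): ", x$score,
      " change(s)\n", sep = "")
  if (nrow(x$changes)) print.data.frame(x$changes)
  invisible(x)
}

#' Map one alignment column on a tree under ACCTRAN
#'
#' Convenience wrapper: extracts tip states at `column`, runs
#' [fitch_parsimony()] then [acctran_assign()].
#'
#' @param tree A rooted `ape::phylo` whose tips are sample ids of `aln`.
#' @param aln A [labeled_alignment()].
#' @param column 1-based alignment column.
#' @return A `character_mapping`.
#' @export
map_site <- function(tree, aln, column) {
  tips <- stats::setNames(aln$mat[, column], aln$sample_ids)
  acctran_assign(tree, fitch_parsimony(tree, tips), column = column)
}
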