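#' Detect footprint clades from mapped characters
#'
#' A "footprint" of limited migration is a clade on whose subtending branch
#' the derived substitutions of several population-heterogeneous sites
#' converge, with population-biased membership. For every branch of the
#' rooted tree, this collects the sites whose ACCTRAN change list includes
#' that branch; branches carrying changes at `min_sites` or more sites
#' define footprint clades. Each clade is reported with its tip membership
#' and per-population composition, its sister clade's membership and
#' composition, and a per-site apomorphy flag -- a site is "solely mapped"
#' (a clean synapomorphy) when its change appears on exactly one branch
#' tree-wide.
#'
#' @param tree A rooted `ape::phylo`.
#' @param mappings List of `character_mapping` objects from [map_site()] or
#'   [acctran_assign()], typically for the sites flagged by [scan_sites()].
#' @param populations Named character vector: population per tip label.
#' @param min_sites Minimum number of co-occurring site changes on a branch
#'   to call a footprint clade (default 2; convergence requires
#'   co-occurrence).
#' @return Object of class `footprint_report`: list with `clades` (list of
#'   entries: `tips`, `composition`, `sister_tips`, `sister_composition`,
#'   `sites`, `apomorphic`, `defining_branch`) and `site_branch_counts`
#'   (changes per site tree-wide).
#' @export
detect_footprint_clades <- function(tree, mappings, populations,
                                    min_sites = 2L) {
  stopifnot(inherits(tree, "phylo"), min_sites >= 1L)
  n <- length(tree$tip.label)
  pops <- sort(unique(populations))
  co <- ape::reorder.phylo(tree, "cladewise")
  n_edge <- nrow(co$edge)
  # edge -> sites with a change there; site -> number of branches changed
  edge_sites <- vector("list", n_edge)
  site_nbranch <- integer(length(mappings))
  site_cols <- vapply(mappings, function(m) as.integer(m$column), integer(1))
  for (s in seq_along(mappings)) {
    ch <- mappings[[s]]$changes
    site_nbranch[s] <- nrow(ch)
    for (e in ch$edge)
      edge_sites[[e]] <- c(edge_sites[[e]], s)
  }
  names(site_nbranch) <- site_cols
  hits <- which(vapply(edge_sites, length, integer(1)) >= min_sites)
  clades <- lapply(hits, function(e) {
    child <- co$edge[e, 2]
    tips <- clade_tips(co, child)
    parent <- co$edge[e, 1]
    sibs <- co$edge[co$edge[, 1] == parent, 2]
    sibs <- setdiff(sibs, child)
    sister <- unlist(lapply(sibs, function(s) clade_tips(co, s)))
    sidx <- edge_sites[[e]]
    list(defining_branch = e,
         tips = tips,
         composition = pop_composition(tips, populations, pops),
         sister_tips = sister,
         sister_composition = pop_composition(sister, populations, pops),
         sites = site_cols[sidx],
         changes = do.call(rbind, lapply(sidx, function(s) {
           ch <- mappings[[s]]$changes
           row <- ch[ch$edge == e, c("from", "to"), drop = FALSE]
           data.frame(column = site_cols[s], from = row$from[1],
                      to = row$to[1], stringsAsFactors = FALSE)
         })),
         apomorphic = stats::setNames(site_nbranch[sidx] == 1L,
                                      site_cols[sidx]))
  })
  structure(list(clades = clades,
                 site_branch_counts = site_nbranch,
                 min_sites = as.integer(min_sites),
                 populations = pops),
            class = "footprint_report")
}

clade_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  tree$tip.label[intersect(unlist(phangorn::Descendants(tree, node, "tips")),
                           seq_len(n))]
}

pop_composition <- function(tips, populations, pops) {
  tab <- table(factor(populations[tips], levels = pops))
  stats::setNames(as.integer(tab), pops)
}

#' @export
print.footprint_report <- function(x, ...) {
  cat("Footprint report:", length(x$clades), "clade(s) with changes at >=",
      x$min_sites, "heterogeneous site(s)\n")
  for (cl in x$clades) {
    comp <- paste(sprintf("%s:%d", names(cl$composition), cl$composition),
                  collapse = ", ")
    scomp <- paste(sprintf("%s:%d", names(cl$sister_composition),
                           cl$sister_composition), collapse = ", ")
    cat(sprintf(" - clade of %d tips (%s); sister %d tips (%s); sites %s%s\n",
                length(cl$tips), comp, length(cl$sister_tips), scomp,
                paste(cl$sites, collapse = ","),
                if (any(cl$apomorphic)) paste0(" [apomorphic: ",
                  paste(names(cl$apomorphic)[cl$apomorphic],
                        collapse = ","), "]") else ""))
  }
  invisible(x)
}

#' Write a footprint report as JSON
#'
#' @param report A `footprint_report`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_footprint_report <- function(report, path) {
  out <- list(min_sites = report$min_sites,
              site_branch_counts = as.list(report$site_branch_counts),
              clades = lapply(report$clades, function(cl) {
                list(defining_branch = cl$defining_branch,
                     tips = cl$tips,
                     composition = as.list(cl$composition),
                     sister_tips = cl$sister_tips,
                     sister_composition = as.list(cl$sister_composition),
                     sites = cl$sites,
                     apomorphic = as.list(cl$apomorphic))
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write per-site change lists as TSV
#'
#' One row per (site, branch) change: column, branch (cladewise edge
#' index), parent and child node numbers, ancestral and derived state.
#'
#' @param mappings List of `character_mapping` objects.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_change_table <- function(mappings, path) {
  rows <- lapply(mappings, function(m) {
    if (!nrow(m$changes)) return(NULL)
    cbind(data.frame(column = m$column), m$changes)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(column = integer(0), edge = integer(0),
               parent_node = integer(0), child_node = integer(0),
               from = character(0), to = character(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
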