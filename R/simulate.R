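#' Configuration for the two-deme mitochondrial simulator
#'
#' The simulator emulates the statistical structure the analysis pipeline
#' assumes: two populations ("north", "south") sampled from two demes
#' exchanging limited migration, two deep ancestral mitochondrial lineages
#' present in both demes, concatenated protein-coding genes with elevated
#' mutability at third codon positions, and very high haplotype diversity.
#' Defaults are calibrated so that realized haplotype diversity is ~0.99-1.0
#' and nucleotide diversity falls in [0.005, 0.010] at the default sample
#' sizes (91 + 60 over 2885 bp); the calibration reasoning is laid out in
#' the package vignette.
#'
#' Time is measured backward in coalescent units of 2N generations of the
#' ancestral (pre-expansion) deme size; within a deme k lineages coalesce
#' at rate k(k-1)/2, damped by 1/`expansion_factor` more recently than
#' `expansion_time` (recent population expansion: large present size,
#' hence long terminal branches and near-unique haplotypes, the regime
#' high-diversity marine mtDNA data sit in). Every lineage migrates at
#' rate `migration_rate`/2. At `split_time` the two demes merge into one
#' ancestral deme. Each sampled lineage is assigned to ancestral lineage A
#' with probability `lineage_mix` (per deme); coalescence across the A/B
#' boundary happens only at the basal split, placed so that the expected
#' sequence divergence between the two lineage ancestors equals
#' `admixture_depth` substitutions/site.
#'
#' @param n_north,n_south Sample sizes per deme.
#' @param gmap A [gene_map()]; alignment length and third-position columns
#'   come from it.
#' @param theta Population mutation parameter per site (2N mu, N the
#'   ancestral size); mutations fall on branches at rate `theta`/2 per site
#'   per unit time.
#' @param migration_rate Scaled migration rate (per-lineage rate =
#'   `migration_rate`/2); 0 means isolation since `split_time`.
#' @param split_time Deme merge time, coalescent units, looking backward.
#' @param expansion_time Time of the recent population expansion;
#'   coalescence is damped between the present and this time.
#' @param expansion_factor Ratio of present to ancestral effective size
#'   (>= 1; 1 disables the expansion epoch).
#' @param admixture_depth Expected divergence between the two ancestral
#'   lineages, substitutions/site.
#' @param lineage_mix Probability a sampled lineage belongs to ancestral
#'   lineage A; length 1 or 2 (north, south).
#' @param ti_tv Transition:transversion ratio of the mutation process.
#' @param third_pos_weight Rate multiplier for third codon positions
#'   (weights are renormalised to mean 1 over the alignment).
#' @param base_freqs Root base composition (A, C, G, T).
#' @param seed Integer seed; mandatory.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_north = 91L, n_south = 60L,
                       gmap = default_gene_map(),
                       theta = 0.0022, migration_rate = 1,
                       split_time = 0.25, expansion_time = 1,
                       expansion_factor = 20,
                       admixture_depth = 0.005,
                       lineage_mix = 0.5, ti_tv = 10,
                       third_pos_weight = 5,
                       base_freqs = c(A = 0.27, C = 0.30, G = 0.15,
                                      T = 0.28),
                       seed) {
  if (missing(seed)) stop("seed is mandatory in sim_config")
  stopifnot(n_north >= 1, n_south >= 1, theta >= 0, migration_rate >= 0,
            split_time >= 0, admixture_depth >= 0, ti_tv > 0,
            third_pos_weight > 0, all(lineage_mix >= 0),
            all(lineage_mix <= 1), expansion_time >= 0,
            expansion_factor >= 1)
  lineage_mix <- rep_len(lineage_mix, 2L)
  structure(list(n_north = as.integer(n_north),
                 n_south = as.integer(n_south),
                 gmap = gmap, theta = theta,
                 migration_rate = migration_rate, split_time = split_time,
                 expansion_time = expansion_time,
                 expansion_factor = expansion_factor,
                 admixture_depth = admixture_depth,
                 lineage_mix = stats::setNames(lineage_mix,
                                               c("north", "south")),
                 ti_tv = ti_tv, third_pos_weight = third_pos_weight,
                 base_freqs = base_freqs / sum(base_freqs),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a two-deme mitochondrial dataset
#'
#' Runs the structured coalescent described in [sim_config()], drops
#' finite-sites mutations on the genealogy, and returns the alignment
#' together with the true genealogy and a truth record for power studies.
#'
#' @param cfg A [sim_config()].
#' @return List of class `mtfp_sim`: `aln` (a [labeled_alignment()] with
#'   populations `north`/`south`, ids `N-1..`/`S-1..`), `genealogy`
#'   (`ape::phylo`, branch lengths in coalescent units), and `truth` (list:
#'   `lineage` per tip, `n_migrations`, `mutations` data frame with
#'   `edge`, `column`, `from`, `to`, `mutated_columns`, `config` echo).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_north + cfg$n_south
  ids <- c(paste0("N-", seq_len(cfg$n_north)),
           paste0("S-", seq_len(cfg$n_south)))
  deme <- rep(c("north", "south"), c(cfg$n_north, cfg$n_south))
  lineage <- ifelse(stats::runif(n) < cfg$lineage_mix[deme], "A", "B")
  names(lineage) <- ids

  groups <- split(seq_len(n), lineage)
  sub <- lapply(groups, function(tips)
    coalesce_group(tips, deme[tips], cfg$migration_rate, cfg$split_time,
                   cfg$expansion_time, cfg$expansion_factor))
  n_mig <- sum(vapply(sub, `[[`, numeric(1), "n_migrations"))

  merges <- list()
  roots <- list()   # (ref, height) per lineage group
  for (g in sub) {
    off <- length(merges)
    for (m in g$merges) {
      m$kids <- ifelse(m$kids > 0, m$kids, m$kids - off)
      merges[[length(merges) + 1L]] <- m
    }
    ref <- if (g$root_ref > 0) g$root_ref else g$root_ref - off
    roots[[length(roots) + 1L]] <- list(ref = ref, height = g$root_height)
  }
  if (length(roots) == 2L) {
    h <- c(roots[[1]]$height, roots[[2]]$height)
    stem <- if (cfg$theta > 0) cfg$admixture_depth / cfg$theta else 1
    H <- max(max(h) + 1e-9, mean(h) + stem)
    merges[[length(merges) + 1L]] <-
      list(kids = c(roots[[1]]$ref, roots[[2]]$ref), lens = H - h,
           raw = H - h)
  } else if (length(merges) == 0L) {
    stop("degenerate genealogy: need >= 2 tips")
  }
  tree <- build_phylo(ids, merges)

  L <- max(cfg$gmap$end)
  w <- rep(1, L)
  for (r in seq_len(nrow(cfg$gmap))) {
    pos <- cfg$gmap$start[r]:cfg$gmap$end[r]
    cp <- ((pos - cfg$gmap$start[r] - cfg$gmap$frame[r]) %% 3L) + 1L
    w[pos[cp == 3L]] <- cfg$third_pos_weight
  }
  w <- w / mean(w)

  bases <- c("A", "C", "G", "T")
  root_seq <- sample(bases, L, replace = TRUE, prob = cfg$base_freqs)
  co <- ape::reorder.phylo(tree, "cladewise")
  nnode <- n + tree$Nnode
  seqs <- vector("list", nnode)
  seqs[[n + 1L]] <- root_seq
  muts <- list()
  rate <- cfg$theta / 2 * L
  for (e in seq_len(nrow(co$edge))) {
    p <- co$edge[e, 1]; ch <- co$edge[e, 2]
    s <- seqs[[p]]
    n_mut <- stats::rpois(1, co$edge.length[e] * rate)
    if (n_mut > 0) {
      cols <- sample.int(L, n_mut, replace = TRUE, prob = w)
      for (cl in cols) {
        from <- s[cl]
        to <- mutate_base(from, cfg$ti_tv)
        s[cl] <- to
        muts[[length(muts) + 1L]] <-
          data.frame(edge = e, column = cl, from = from, to = to,
                     stringsAsFactors = FALSE)
      }
    }
    seqs[[ch]] <- s
  }
  tip_seqs <- vapply(seq_len(n), function(i)
    paste(seqs[[i]], collapse = ""), character(1))
  aln <- labeled_alignment(tip_seqs, ids, stats::setNames(deme, ids))
  mut_df <- if (length(muts)) do.call(rbind, muts) else
    data.frame(edge = integer(0), column = integer(0),
               from = character(0), to = character(0))
  structure(list(aln = aln, genealogy = co,
                 truth = list(lineage = lineage,
                              n_migrations = n_mig,
                              mutations = mut_df,
                              mutated_columns = sort(unique(mut_df$column)),
                              config = cfg)),
            class = "mtfp_sim")
}

# Structured coalescent for one ancestral-lineage group of tips, with a
# two-epoch size history (recent expansion damps coalescence before
# expansion_time by 1/expansion_factor). Returns merges in the (kids,
# lens, raw) format of build_phylo, with internal refs local to this
# group (-1, -2, ...), plus root ref/height.
coalesce_group <- function(tips, deme, migration_rate, split_time,
                           expansion_time = 0, expansion_factor = 1) {
  active_ref <- as.integer(tips)
  active_h <- rep(0, length(tips))
  active_deme <- deme
  t <- 0
  merges <- list()
  n_mig <- 0
  merged <- FALSE
  while (length(active_ref) > 1L) {
    if (!merged && t >= split_time) {
      merged <- TRUE
      active_deme[] <- "ancestral"
    }
    k_by <- table(factor(active_deme, levels = c("north", "south")))
    coal_mult <- if (t < expansion_time) 1 / expansion_factor else 1
    if (merged) {
      rate_coal <- coal_mult *
        length(active_ref) * (length(active_ref) - 1) / 2
      rate_mig <- 0
    } else {
      rate_coal <- coal_mult * sum(k_by * (k_by - 1) / 2)
      rate_mig <- length(active_ref) * migration_rate / 2
    }
    total <- rate_coal + rate_mig
    boundaries <- c(if (!merged) split_time,
                    if (t < expansion_time) expansion_time)
    boundaries <- boundaries[boundaries > t]
    next_b <- if (length(boundaries)) min(boundaries) else Inf
    if (total <= 0) {          # nothing can happen until the next boundary
      if (!is.finite(next_b))
        stop("internal error: stalled coalescent")
      t <- next_b
      if (!merged && t >= split_time) {
        merged <- TRUE
        active_deme[] <- "ancestral"
      }
      next
    }
    dt <- stats::rexp(1, total)
    if (t + dt >= next_b) {
      t <- next_b
      if (!merged && t >= split_time) {
        merged <- TRUE
        active_deme[] <- "ancestral"
      }
      next
    }
    t <- t + dt
    if (stats::runif(1) < rate_coal / total) {
      # coalescence: pick a deme weighted by its pair count, then a pair
      if (merged) {
        pair <- sample(seq_along(active_ref), 2L)
      } else {
        dsel <- sample(names(k_by), 1L,
                       prob = as.numeric(k_by * (k_by - 1) / 2))
        cand <- which(active_deme == dsel)
        pair <- cand[sample(seq_along(cand), 2L)]
      }
      i <- pair[1]; j <- pair[2]
      k <- length(merges) + 1L
      merges[[k]] <- list(kids = active_ref[c(i, j)],
                          lens = t - active_h[c(i, j)],
                          raw = t - active_h[c(i, j)])
      new_deme <- active_deme[i]
      active_ref <- c(active_ref[-c(i, j)], -k)
      active_h <- c(active_h[-c(i, j)], t)
      active_deme <- c(active_deme[-c(i, j)], new_deme)
    } else {
      i <- sample.int(length(active_ref), 1L)
      active_deme[i] <- if (active_deme[i] == "north") "south" else "north"
      n_mig <- n_mig + 1
    }
  }
  list(merges = merges, root_ref = active_ref[1], root_height = active_h[1],
       n_migrations = n_mig)
}

mutate_base <- function(from, ti_tv) {
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  if (stats::runif(1) < ti_tv / (ti_tv + 1)) return(ts[[from]])
  tv <- setdiff(c("A", "C", "G", "T"), c(from, ts[[from]]))
  sample(tv, 1L)
}

#' @export
print.mtfp_sim <- function(x, ...) {
  cat("Simulated two-deme dataset:\n")
  print(x$aln)
  cat("Mutations:", nrow(x$truth$mutations), "on",
      length(x$truth$mutated_columns), "columns;",
      x$truth$n_migrations, "migration events\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the same FASTA/TSV formats the pipeline reads, plus the truth
#' record as JSON and the true genealogy as Newick.
#'
#' @param sim An `mtfp_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_alignment(sim$aln, file.path(dir, "alignment.fasta"),
                  file.path(dir, "populations.tsv"))
  write_newick(sim$genealogy, file.path(dir, "genealogy.nwk"))
  cfg <- sim$truth$config
  jsonlite::write_json(
    list(lineage = as.list(sim$truth$lineage),
         n_migrations = sim$truth$n_migrations,
         mutations = sim$truth$mutations,
         mutated_columns = sim$truth$mutated_columns,
         config = cfg[setdiff(names(cfg), "gmap")]),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(dir)
}
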