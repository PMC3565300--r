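#' Run the full footprint-detection pipeline
#'
#' Orchestrates the whole analysis in dependency order: per-population
#' diversity, the per-site heterogeneity scan, TN93+I+G distances,
#' neighbor joining, rooting, ACCTRAN character mapping of the heterogeneous
#' sites, footprint-clade detection, and the AMOVA phi-ST permutation test.
#' When `out_dir` is given every stage's artifact is written
#' (`diversity.tsv`, `site_tests.tsv`, `distances.phy`, `tree.nwk`,
#' `rooted_tree.nwk`, `changes.tsv`, `footprint.json`, `phi_st.json`) plus
#' a `manifest.json` recording the package version, configuration, seed and
#' input checksums; a stage failure leaves the completed artifacts in place
#' and an `error_manifest.json` naming the failed stage.
#'
#' @param aln A [labeled_alignment()] with exactly two populations, or
#'   `NULL` to read from `fasta`/`labels`.
#' @param fasta,labels Input paths, used when `aln` is `NULL`.
#' @param gmap A [gene_map()]; default as in [scan_sites()].
#' @param alpha Raw per-site significance level (default 0.01).
#' @param gamma_shape Gamma shape for the distance model (default 0.5; a
#'   configuration placeholder, not an estimate -- supply the value selected
#'   for your data).
#' @param p_inv Invariant-sites proportion for the distance model (default
#'   0.5; same caveat).
#' @param root `"midpoint"` (default) or a tip id to use as outgroup.
#' @param min_sites Convergence threshold for footprint clades (default 2).
#' @param map_all_sites Map every variable site instead of only the
#'   significant ones (default FALSE, the analysis' own behavior).
#' @param n_perm Permutations for phi-ST (default 10000).
#' @param seed Integer seed (mandatory; drives the permutation test).
#' @param out_dir Optional output directory for artifacts.
#' @param quiet Suppress per-stage progress messages.
#' @return Object of class `mtfp_run` with components `diversity`,
#'   `site_scan`, `distances`, `tree`, `rooted_tree`, `mappings`,
#'   `footprint`, `phi_st`, `config`.
#' @export
run_pipeline <- function(aln = NULL, fasta = NULL, labels = NULL,
                         gmap = NULL, alpha = 0.01,
                         gamma_shape = 0.5, p_inv = 0.5,
                         root = "midpoint", min_sites = 2L,
                         map_all_sites = FALSE,
                         n_perm = 10000L, seed,
                         out_dir = NULL, quiet = FALSE) {
  if (missing(seed)) stop("seed is mandatory")
  say <- function(...) if (!quiet) message(...)
  emit <- function(fun) if (!is.null(out_dir)) fun()
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(alpha = alpha, gamma_shape = gamma_shape, p_inv = p_inv,
              root = root, min_sites = min_sites,
              map_all_sites = map_all_sites, n_perm = n_perm, seed = seed)
  checksums <- NULL
  stage <- "input"
  res <- list(config = cfg)
  fail <- function(e) {
    if (!is.null(out_dir))
      jsonlite::write_json(list(failed_stage = stage,
                                error = conditionMessage(e), config = cfg),
                           file.path(out_dir, "error_manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    if (is.null(aln)) {
      aln <- read_alignment(fasta, labels)
      checksums <- as.list(tools::md5sum(c(fasta, labels)))
    }
    if (is.null(gmap))
      gmap <- if (aln$length == 2885L) default_gene_map() else
        gene_map("gene1", 1L, aln$length, 0L)
    say(sprintf("input: %d samples x %d columns", length(aln$sample_ids),
                aln$length))

    stage <- "diversity"
    res$diversity <- diversity_table(aln)
    emit(function() utils::write.table(res$diversity,
      file.path(out_dir, "diversity.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE))

    stage <- "site_scan"
    res$site_scan <- scan_sites(aln, gmap, alpha = alpha)
    say(sprintf("site scan: %d variable sites, %d heterogeneous at alpha=%g",
                nrow(res$site_scan), sum(res$site_scan$significant), alpha))
    emit(function() write_site_scan(res$site_scan,
                                    file.path(out_dir, "site_tests.tsv")))

    stage <- "distances"
    res$distances <- distance_matrix(aln, alpha = gamma_shape,
                                     p_inv = p_inv)
    emit(function() write_distance_matrix(res$distances,
                                          file.path(out_dir, "distances.phy")))

    stage <- "nj_tree"
    res$tree <- neighbor_joining(res$distances)
    emit(function() write_newick(res$tree, file.path(out_dir, "tree.nwk")))
    stage <- "rooting"
    res$rooted_tree <- if (identical(root, "midpoint"))
      midpoint_root(res$tree) else midpoint_root(res$tree, root_tip = root)
    emit(function() write_newick(res$rooted_tree,
                                 file.path(out_dir, "rooted_tree.nwk")))

    stage <- "character_mapping"
    map_cols <- if (map_all_sites) res$site_scan$column else
      res$site_scan$column[res$site_scan$significant]
    res$mappings <- lapply(map_cols, function(cl)
      map_site(res$rooted_tree, aln, cl))
    say(sprintf("mapping: %d site(s), parsimony scores %s",
                length(res$mappings),
                paste(vapply(res$mappings, `[[`, integer(1), "score"),
                      collapse = ",")))
    emit(function() write_change_table(res$mappings,
                                       file.path(out_dir, "changes.tsv")))

    stage <- "footprint"
    res$footprint <- detect_footprint_clades(res$rooted_tree, res$mappings,
                                             aln$populations,
                                             min_sites = min_sites)
    say(sprintf("footprint: %d clade(s)", length(res$footprint$clades)))
    emit(function() write_footprint_report(res$footprint,
                                           file.path(out_dir, "footprint.json")))

    stage <- "phi_st"
    res$phi_st <- amova_phi_st(res$distances, aln$populations,
                               n_perm = n_perm, seed = seed)
    say(sprintf("phi_ST = %.5f (p = %.4g)", res$phi_st$phi_st,
                res$phi_st$p_value))
    emit(function() write_phi_st(res$phi_st,
                                 file.path(out_dir, "phi_st.json")))

    stage <- "manifest"
    emit(function() jsonlite::write_json(
      list(package = "mtfootprint",
           version = as.character(utils::packageVersion("mtfootprint")),
           config = cfg, input_checksums = checksums,
           n_samples = length(aln$sample_ids),
           n_variable_sites = nrow(res$site_scan),
           n_significant = sum(res$site_scan$significant),
           n_footprint_clades = length(res$footprint$clades)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE,
      pretty = TRUE, digits = NA))
  }, error = fail)
  res$aln <- aln
  class(res) <- "mtfp_run"
  res
}

#' @export
print.mtfp_run <- function(x, ...) {
  cat("== mtfootprint pipeline run ==\n")
  print(x$aln)
  cat("\nDiversity:\n")
  print(x$diversity, digits = 4)
  cat("\n")
  print(x$site_scan)
  cat("\n")
  print(x$footprint)
  cat("\n")
  print(x$phi_st)
  invisible(x)
}

#' @export
summary.mtfp_run <- function(object, ...) {
  sig <- as.data.frame(object$site_scan)[object$site_scan$significant, ,
                                         drop = FALSE]
  out <- list(
    n_samples = length(object$aln$sample_ids),
    populations = table(object$aln$populations),
    n_variable_sites = nrow(object$site_scan),
    significant_sites = sig[, c("column", "gene", "gene_position",
                                "codon_position", "p_value",
                                "is_synonymous")],
    n_footprint_clades = length(object$footprint$clades),
    phi_st = object$phi_st$phi_st,
    phi_st_p = object$phi_st$p_value)
  class(out) <- "summary.mtfp_run"
  out
}

#' @export
print.summary.mtfp_run <- function(x, ...) {
  cat(sprintf("%d samples (%s); %d variable sites, %d heterogeneous\n",
              x$n_samples,
              paste(sprintf("%s:%d", names(x$populations),
                            as.integer(x$populations)), collapse = ", "),
              x$n_variable_sites, nrow(x$significant_sites)))
  if (nrow(x$significant_sites))
    print(x$significant_sites, digits = 4, row.names = FALSE)
  cat(sprintf("%d footprint clade(s); phi_ST = %.5f (p = %.4g)\n",
              x$n_footprint_clades, x$phi_st, x$phi_st_p))
  invisible(x)
}
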