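test_that("two-sided exact test reproduces known 2x2 values", {
  # frozen benchmark tables: a 91-vs-60 survey where the minor base is
  # private to one population
  expect_equal(round(fisher_exact(rbind(c(91, 0), c(54, 6))), 4), 0.0034)
  expect_equal(round(fisher_exact(rbind(c(91, 0), c(55, 5))), 4), 0.0089)
  expect_equal(suppressWarnings(fisher_exact(rbind(c(10, 0), c(10, 0)))), 1)
  # all 6 outcomes for margins (5,5)/(5,5) enumerated by hand: 2/252
  expect_equal(fisher_exact(rbind(c(5, 0), c(0, 5))), 2 / 252,
               tolerance = 1e-12)
  expect_warning(p <- fisher_exact(rbind(c(0, 0), c(3, 4))), "degenerate")
  expect_equal(p, 1)
})

test_that("exact test is invariant to row swap and column permutation", {
  tab <- rbind(c(12, 3, 1), c(7, 9, 2))
  p <- fisher_exact(tab)
  expect_equal(fisher_exact(tab[2:1, ]), p)
  expect_equal(fisher_exact(tab[, c(3, 1, 2)]), p)
})

test_that("2x2 p-values agree with an independent implementation", {
  set.seed(5)
  for (rep in 1:40) {
    N <- sample(6:30, 1)
    x <- as.vector(stats::rmultinom(1, N, prob = stats::runif(4, 0.2, 1)))
    tab <- matrix(x, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("Freeman-Halton enumeration matches the reference for 2xK", {
  set.seed(9)
  for (K in c(3, 4)) {
    for (rep in 1:12) {
      N <- sample(8:25, 1)
      tab <- matrix(as.vector(stats::rmultinom(1, N,
                                               stats::runif(2 * K, 0.2, 1))),
                    nrow = 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_exact(tab),
                   stats::fisher.test(tab)$p.value, tolerance = 1e-7)
    }
  }
  # large-margin case typical of a real variable site (skewed minor counts)
  tab <- rbind(c(88, 2, 1), c(57, 0, 3))
  expect_equal(fisher_exact(tab), stats::fisher.test(tab)$p.value,
               tolerance = 1e-7)
})

test_that("uniquely extremal tables give the one-tail mass", {
  # minor base private to population 2: observed table is the unique
  # extreme; two-sided p equals the cumulative tail
  tab <- rbind(c(91, 0), c(54, 6))
  tail_mass <- stats::dhyper(91, 145, 6, 91)  # X = row1/col1 count; 91 is maximal
  expect_equal(fisher_exact(tab), tail_mass, tolerance = 1e-12)
})

test_that("site tables count bases per population with missing excluded", {
  aln <- make_table1_fixture()
  t501 <- site_table(aln, 501)
  expect_equal(t501["north", ], c(A = 0L, C = 91L, G = 0L, T = 0L))
  expect_equal(t501["south", ], c(A = 0L, C = 54L, G = 0L, T = 6L))
  t1812 <- site_table(aln, concat_column("ND5", 1812, default_gene_map()))
  expect_equal(t1812["south", c("C", "T")], c(C = 55L, T = 5L))
  expect_error(site_table(aln, 2), "not variable")

  # row sums = population size minus missing at that column
  g <- labeled_alignment(c("ANT", "AAT", "ACT", "A-T"), paste0("s", 1:4),
                         c("N", "N", "S", "S"))
  tg <- site_table(g, 2)
  expect_equal(rowSums(tg), c(N = 1, S = 1))
})

test_that("synonymy is judged against observed codon contexts", {
  gm <- gene_map("g", 1, 6, 0)
  # third position of a CTN leucine codon: 4-fold degenerate
  a <- labeled_alignment(c("CTCAAA", "CTTAAA"), c("x", "y"), c("N", "S"))
  ann <- annotate_synonymy(a, 3, gm)
  expect_equal(ann$codon_position, 3L)
  expect_true(ann$is_synonymous)
  expect_true(ann$is_transition_only)

  # first position of ATG: Met -> Val under the vertebrate mito code
  b <- labeled_alignment(c("ATGAAA", "GTGAAA"), c("x", "y"), c("N", "S"))
  annb <- annotate_synonymy(b, 1, gm)
  expect_equal(annb$codon_position, 1L)
  expect_false(annb$is_synonymous)

  # ATA is Met in the vertebrate mito code (Ile in the standard code), so
  # ATA/ATG variation is synonymous only under the mito code
  cc <- labeled_alignment(c("ATAAAA", "ATGAAA"), c("x", "y"), c("N", "S"))
  expect_true(annotate_synonymy(cc, 3, gm)$is_synonymous)
  gm_std <- gene_map("g", 1, 6, 0, genetic_code = "1")
  expect_false(annotate_synonymy(cc, 3, gm_std)$is_synonymous)

  # unmapped column
  gm2 <- gene_map("g", 1, 3, 0)
  d <- labeled_alignment(c("CTCA", "CTCG"), c("x", "y"), c("N", "S"))
  expect_equal(annotate_synonymy(d, 4, gm2)$gene, "unmapped")
})

test_that("site scan flags heterogeneous sites at raw alpha", {
  aln <- make_table1_fixture()
  sc <- scan_sites(aln)
  expect_equal(nrow(sc), 27L)
  sig <- sc[sc$significant, ]
  expect_equal(sig$column, c(501L, 2285L, 2858L))
  expect_equal(sprintf("%.4f", sig$p_value), c("0.0034", "0.0034", "0.0089"))
  expect_equal(sig$codon_position, rep(3L, 3))
  expect_true(all(sig$is_synonymous))
  expect_true(all(sig$is_transition_only))
  expect_true(all(sc$q_value >= sc$p_value))

  # no variable sites -> empty scan
  flat <- labeled_alignment(rep("ACGTAC", 5), paste0("s", 1:5),
                            c("N", "N", "N", "S", "S"))
  expect_equal(nrow(scan_sites(flat)), 0L)

  expect_error(scan_sites(rand_aln(6, 10, pops = rep("P", 6))),
               "exactly 2 populations")
})

test_that("a single engineered heterogeneous column is the only flag", {
  # monomorphic backdrop plus one column with the 91/54-6 composition
  base <- strsplit(paste(rep("CTA", 20), collapse = ""), "")[[1]]
  ids <- c(paste0("n", 1:91), paste0("s", 1:60))
  mat <- matrix(rep(base, each = 151), nrow = 151)
  mat[142:147, 6] <- "G"   # six southern carriers at a third position
  aln <- labeled_alignment(apply(mat, 1, paste, collapse = ""), ids,
                           stats::setNames(rep(c("north", "south"),
                                               c(91, 60)), ids))
  sc <- scan_sites(aln, gene_map("g", 1, 60, 0))
  expect_equal(nrow(sc), 1L)
  expect_true(sc$significant)
  expect_equal(round(sc$p_value, 4), 0.0034)
})
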