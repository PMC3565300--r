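test_that("the 4-taxon additive benchmark is solved exactly", {
  D <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4,
              dimnames = list(c("A", "B", "C", "D"),
                              c("A", "B", "C", "D")))
  tr <- neighbor_joining(D)
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  expect_equal(nrow(tr$edge), 2 * 4 - 3)
  # topology (AB)|(CD) with external branches 1 and internal branch 2
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp[rownames(D), colnames(D)], D, tolerance = 1e-12)
  expect_true(ape::is.monophyletic(ape::root(tr, outgroup = "A"),
                                   c("C", "D")))
})

test_that("three taxa resolve by the closed three-point formulas", {
  D <- matrix(c(0, 3, 5,
                3, 0, 6,
                5, 6, 0), 3, dimnames = list(c("x", "y", "z"),
                                             c("x", "y", "z")))
  tr <- neighbor_joining(D)
  lens <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("x", "y", "z")],
               c(x = (3 + 5 - 6) / 2, y = (3 + 6 - 5) / 2,
                 z = (5 + 6 - 3) / 2))
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers random additive trees exactly", {
  set.seed(77)
  for (rep in 1:30) {
    gen <- random_additive(8)
    tr <- neighbor_joining(gen$D)
    expect_phylo_equal_topology(tr, gen$tree)
    # path-length matrix equals the generating additive matrix
    cp <- ape::cophenetic.phylo(tr)
    expect_equal(cp[rownames(gen$D), colnames(gen$D)], gen$D,
                 tolerance = 1e-8)
  }
})

test_that("NJ output is deterministic and preserves the tip set", {
  aln <- related_aln(n = 9, L = 150, n_mut = 8, seed = 13)
  dm <- distance_matrix(aln)
  t1 <- neighbor_joining(dm)
  t2 <- neighbor_joining(dm)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_setequal(t1$tip.label, aln$sample_ids)
  expect_equal(nrow(t1$edge), 2 * 9 - 3)
  expect_true(all(t1$edge.length >= 0))
  expect_length(attr(t1, "raw_edge_length"), nrow(t1$edge))
})

test_that("agglomeration agrees with an independent NJ on clean data", {
  # additive input: both implementations must find the same topology
  set.seed(99)
  for (rep in 1:5) {
    gen <- random_additive(10)
    expect_phylo_equal_topology(neighbor_joining(gen$D),
                                ape::nj(stats::as.dist(gen$D)))
  }
})

test_that("midpoint rooting splits the longest tip-to-tip path", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  r <- midpoint_root(ape::unroot(tr))
  expect_true(ape::is.rooted(r))
  depths <- ape::node.depth.edgelength(r)
  expect_equal(depths[match("A", r$tip.label)],
               depths[match("C", r$tip.label)])

  # caterpillar with one long terminal branch: root lands on that branch
  cat_tr <- ape::read.tree(
    text = "(((A:0.1,B:0.1):0.1,C:0.1):0.1,(D:0.1,E:5):0.1);")
  rc <- midpoint_root(ape::unroot(cat_tr))
  # all-pairs oracle: the two farthest tips are E and A (or B); the root
  # must be equidistant from the two path endpoints
  cp <- ape::cophenetic.phylo(cat_tr)
  far <- which(cp == max(cp), arr.ind = TRUE)[1, ]
  dep <- ape::node.depth.edgelength(rc)
  d1 <- dep[match(rownames(cp)[far[1]], rc$tip.label)]
  d2 <- dep[match(rownames(cp)[far[2]], rc$tip.label)]
  expect_equal(d1, d2, tolerance = 1e-9)
  expect_equal(d1 + d2, max(cp), tolerance = 1e-9)

  # outgroup mode
  ro <- midpoint_root(ape::unroot(cat_tr), root_tip = "C")
  expect_true(ape::is.monophyletic(ro, setdiff(ro$tip.label, "C")))
  expect_error(midpoint_root(cat_tr, root_tip = "nope"), "unknown tip")

  # zero-length tree falls back with a warning
  z <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  expect_warning(midpoint_root(z), "zero")
})

test_that("Newick writer/reader round-trips NJ output", {
  gen <- random_additive(6)
  tr <- neighbor_joining(gen$D)
  p <- tempfile(fileext = ".nwk")
  write_newick(tr, p)
  back <- read_newick(p)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(phangorn::RF.dist(back, tr), 0)
  # labels and lengths survive at the documented precision
  cp <- ape::cophenetic.phylo(back)
  expect_equal(cp[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr), tolerance = 1e-8)

  p2 <- tempfile()
  writeLines("(A:1,B:2", p2)
  expect_error(read_newick(p2), "malformed")
  writeLines("((A:1,B:2);", p2)
  expect_error(read_newick(p2), "unbalanced")
})
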