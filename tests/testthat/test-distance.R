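test_that("identical sequences are at distance zero under any model", {
  s <- "ACGTACGTACGTACGTTGCA"
  expect_equal(tn93_distance(s, s), 0)
  expect_equal(tn93_distance(s, s, alpha = 0.3, p_inv = 0.4), 0)
})

test_that("plain TN93 matches the reference implementation", {
  set.seed(21)
  for (rep in 1:10) {
    L <- 500
    a <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                prob = c(0.3, 0.25, 0.2, 0.25))
    b <- a
    mut <- sample(L, 40)
    b[mut] <- vapply(b[mut], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    bin <- ape::as.DNAbin(rbind(x = tolower(a), y = tolower(b)))
    ref <- as.numeric(ape::dist.dna(bin, model = "TN93"))
    mine <- tn93_distance(paste(a, collapse = ""), paste(b, collapse = ""))
    expect_equal(mine, ref, tolerance = 1e-9)
    # gamma variant against the same reference
    refg <- as.numeric(ape::dist.dna(bin, model = "TN93", gamma = 0.4))
    mineg <- tn93_distance(paste(a, collapse = ""), paste(b, collapse = ""),
                           alpha = 0.4)
    expect_equal(mineg, refg, tolerance = 1e-9)
  }
})

test_that("gamma and invariant-site corrections behave monotonically", {
  set.seed(8)
  a <- sample(c("A", "C", "G", "T"), 600, replace = TRUE)
  b <- a
  mut <- sample(600, 60)
  b[mut] <- vapply(b[mut], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  s1 <- paste(a, collapse = ""); s2 <- paste(b, collapse = "")
  alphas <- c(0.2, 0.5, 1, 2, 5, 50)
  d_alpha <- vapply(alphas, function(al) tn93_distance(s1, s2, alpha = al),
                    numeric(1))
  expect_true(all(diff(d_alpha) < 0))     # smaller alpha -> larger distance
  pinvs <- c(0, 0.1, 0.3, 0.5, 0.7)
  d_pinv <- vapply(pinvs, function(pi_) tn93_distance(s1, s2, p_inv = pi_),
                   numeric(1))
  expect_true(all(diff(d_pinv) > 0))      # larger p_inv -> larger distance

  # alpha -> Inf and p_inv -> 0 recover plain TN93
  expect_equal(tn93_distance(s1, s2, alpha = Inf, p_inv = 0),
               tn93_distance(s1, s2), tolerance = 1e-12)
  expect_equal(tn93_distance(s1, s2, alpha = 1e7),
               tn93_distance(s1, s2), tolerance = 1e-7)
})

test_that("saturation raises a named error instead of silent infinity", {
  # maximally divergent pair: log arguments go non-positive
  s1 <- paste(rep("ACGT", 25), collapse = "")
  s2 <- paste(rep("CAGT", 25), collapse = "")
  expect_error(tn93_distance(paste(rep("A", 60), collapse = ""),
                             paste(rep("G", 60), collapse = "")),
               "saturated")
  a <- labeled_alignment(c(paste(rep("AC", 30), collapse = ""),
                           paste(rep("CA", 30), collapse = ""),
                           paste(rep("AC", 30), collapse = "")),
                         c("x", "y", "z"), c("N", "S", "N"))
  expect_error(distance_matrix(a), "x/y")
})

test_that("distance matrices are symmetric, zero-diagonal and stable", {
  aln <- related_aln(n = 8, L = 300, seed = 31)
  dm <- distance_matrix(aln)
  expect_equal(diag(dm$d), stats::setNames(rep(0, 8), aln$sample_ids))
  expect_equal(dm$d, t(dm$d))
  expect_true(all(is.finite(dm$d)))

  # permuting input order permutes rows/columns consistently
  ord <- c(3, 1, 2, 8, 5, 4, 7, 6)
  aln2 <- labeled_alignment(unname(aln$sequences[ord]),
                            aln$sample_ids[ord],
                            aln$populations[aln$sample_ids[ord]])
  dm2 <- distance_matrix(aln2)
  expect_equal(dm2$d, dm$d[aln$sample_ids[ord], aln$sample_ids[ord]])
})

test_that("haplotype-level and alignment-frequency modes work", {
  aln <- labeled_alignment(c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAT"),
                           c("x", "y", "z"), c("N", "N", "S"))
  dm <- distance_matrix(aln, level = "haplotype")
  expect_equal(length(dm$ids), 2L)
  dmf <- distance_matrix(related_aln(4, 200, seed = 2), freqs = "alignment")
  expect_equal(dmf$d, t(dmf$d))
})

test_that("PHYLIP and TSV writers emit parseable output", {
  aln <- related_aln(n = 4, L = 100, n_mut = 6, seed = 7)
  dm <- distance_matrix(aln)
  p <- tempfile(fileext = ".phy")
  write_distance_matrix(dm, p)
  lines <- readLines(p)
  expect_equal(as.integer(trimws(lines[1])), 4L)
  expect_equal(length(lines), 5L)
  tsv <- tempfile(fileext = ".tsv")
  write_distance_matrix(dm, tsv, format = "tsv")
  back <- utils::read.table(tsv, sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE)
  expect_equal(as.matrix(back), dm$d, tolerance = 1e-10,
               ignore_attr = TRUE)
})
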