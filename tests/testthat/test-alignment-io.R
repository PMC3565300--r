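test_that("alignment construction validates its input", {
  a <- labeled_alignment(c("ACGTACGTAC", "ACGAACGTAC"), c("x", "y"),
                         c(x = "N", y = "S"))
  expect_s3_class(a, "labeled_alignment")
  expect_equal(a$length, 10L)
  expect_equal(sort(unique(a$populations)), c("N", "S"))

  expect_error(labeled_alignment(c("ACGTACGTAC", "ACGAACGTA"),
                                 c("x", "y"), c("N", "S")),
               "length mismatch")
  expect_error(labeled_alignment(c("ACGT", "ACGT"), c("x", "x"),
                                 c("N", "S")), "duplicate")
  expect_error(labeled_alignment(c("ACGT", "ACGT"), c("x", "y"),
                                 c(x = "N")), "missing")
  expect_error(labeled_alignment(c("ACXT", "ACGT"), c("x", "y"),
                                 c("N", "S")), "unknown characters")
})

test_that("FASTA + labels round-trip reproduces the alignment exactly", {
  aln <- rand_aln(n = 7, L = 33, seed = 42)
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  write_alignment(aln, fa, tsv)
  back <- read_alignment(fa, tsv)
  expect_identical(back$sequences, aln$sequences)
  expect_identical(back$populations, aln$populations)
  expect_identical(back$sample_ids, aln$sample_ids)

  # wrapped FASTA is accepted too
  fa2 <- tempfile(fileext = ".fasta")
  lines <- unlist(lapply(aln$sample_ids, function(id)
    c(paste0(">", id), substring(aln$sequences[id], c(1, 21), c(20, 33)))))
  writeLines(lines, fa2)
  expect_identical(read_alignment(fa2, tsv)$sequences, aln$sequences)

  # labels referencing unknown samples are rejected
  writeLines(c(paste(aln$sample_ids, "P1", sep = "\t"), "ghost\tP2"), tsv)
  expect_error(read_alignment(fa, tsv), "unknown samples")
})

test_that("study-scale input shape is handled", {
  aln <- make_table1_fixture()
  expect_equal(length(aln$sample_ids), 151L)
  expect_equal(aln$length, 2885L)
  expect_equal(as.integer(table(aln$populations)[c("north", "south")]),
               c(91L, 60L))
})

test_that("haplotype collapsing counts by exact identity", {
  a <- labeled_alignment(rep("AAAA", 4), paste0("s", 1:4),
                         rep(c("P1", "P2"), 2))
  h <- collapse_haplotypes(a)
  expect_equal(length(h$haplotype_seqs), 1L)
  expect_equal(sum(h$counts), 4L)

  b <- labeled_alignment(c("AAA", "AAA", "AAT"), c("x", "y", "z"),
                         c("P1", "P2", "P1"))
  hb <- collapse_haplotypes(b)
  expect_equal(hb$haplotype_seqs, c("AAA", "AAT"))
  expect_equal(hb$counts, matrix(c(1L, 1L, 1L, 0L), 2,
                                 dimnames = list(NULL, c("P1", "P2"))))
  expect_equal(hb$member_map[[1]], c("x", "y"))
})

test_that("haplotype counts always conserve sample totals", {
  for (seed in 1:5) {
    aln <- rand_aln(n = 10, L = 8, seed = seed)
    h <- collapse_haplotypes(aln)
    expect_equal(sum(h$counts), 10L)
    # oracle: distinct strings
    expect_equal(length(h$haplotype_seqs),
                 length(unique(unname(aln$sequences))))
  }
})

test_that("variable sites match a brute-force column scan", {
  same <- labeled_alignment(rep("ACGT", 3), paste0("s", 1:3),
                            c("P1", "P1", "P2"))
  expect_equal(variable_sites(same), integer(0))
  two <- labeled_alignment(c("ACGT", "ACGA"), c("x", "y"), c("P1", "P2"))
  expect_equal(variable_sites(two), 4L)

  aln <- rand_aln(n = 6, L = 100, seed = 3)
  oracle <- which(vapply(seq_len(100), function(j)
    length(unique(aln$mat[, j])) > 1, logical(1)))
  expect_equal(variable_sites(aln), oracle)

  # gaps and N never count as states
  g <- labeled_alignment(c("A-GT", "ANGT", "AAGT"), c("x", "y", "z"),
                         c("P1", "P2", "P1"))
  expect_equal(variable_sites(g), integer(0))
})

test_that("gene coordinates map concatenated columns both ways", {
  gm <- default_gene_map()
  expect_equal(gene_coordinates(501, gm)[c("gene", "gene_position")],
               list(gene = "ND2", gene_position = 501L))
  expect_equal(gene_coordinates(1046 + 1239, gm)[c("gene", "gene_position")],
               list(gene = "ND5", gene_position = 1239L))
  expect_equal(gene_coordinates(1, gm)$gene_position, 1L)
  expect_equal(gene_coordinates(501, gm)$codon_position, 3L)

  # inverse identity over a grid of mapped columns
  for (col in c(1L, 500L, 1046L, 1047L, 2000L, 2885L)) {
    gc <- gene_coordinates(col, gm)
    expect_equal(concat_column(gc$gene, gc$gene_position, gm), col)
  }

  # unmapped columns are reported, not errors
  gm2 <- gene_map(c("g1", "g2"), c(1, 20), c(9, 30), 0)
  expect_equal(gene_coordinates(15, gm2)$gene, "unmapped")
  expect_error(gene_map("g", 5, 4, 0), "invalid")
  expect_error(gene_map(c("a", "b"), c(1, 5), c(6, 9), 0), "overlap")
})

test_that("gene maps read from TSV", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("#gene\tstart\tend\tframe", "ND2\t1\t1046\t0",
               "ND5\t1047\t2885\t0"), p)
  gm <- read_gene_map(p)
  expect_equal(gm$gene, c("ND2", "ND5"))
  expect_equal(gm$end, c(1046L, 2885L))
})
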