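test_that("construct assembly yields the expected codon counts", {
  kdm5b <- ladder_construct("KDM5B")
  p300 <- ladder_construct("P300")
  expect_equal(kdm5b$L_mRNA_nt + kdm5b$L_tag_nt, 5658)
  expect_equal(kdm5b$total_codons, 1886)
  expect_equal(p300$L_mRNA_nt + p300$L_tag_nt, 8268)
  expect_equal(p300$total_codons, 2756)
  expect_equal(length(kdm5b$codons), kdm5b$total_codons)
})

test_that("epitope profile is a staircase in UMP units", {
  con <- ladder_construct("RRAGC")
  f <- con$epitope_profile
  expect_true(all(diff(f) >= 0))             # non-decreasing (N-terminal)
  expect_equal(max(f), 1)
  expect_equal(f[1], 0)                      # zero before first epitope
  steps <- diff(f)[diff(f) > 0]
  expect_equal(steps, rep(1 / 10, 10))       # unit steps of 1/n_epitopes
  # a ribosome halfway through the tag (5 epitopes done) plus two past it
  half <- max(which(con$epitope_counts == 5))
  expect_equal(2 * f[con$total_codons] + f[half], 2.5)
})

test_that("tagless construct has an identically zero profile", {
  con <- bare_construct(200)
  expect_true(all(con$epitope_profile == 0))
  expect_equal(con$total_codons, 200)
})

test_that("tag variants reshape the epitope profile as designed", {
  base <- tag_design()
  expect_equal(base$length_nt, 1011L)
  gene <- generate_synthetic_gene(1200, seed = 3)

  dim5 <- make_tag_variant(base, "remove_5")
  con <- build_construct(gene, dim5)
  expect_equal(max(con$epitope_profile), 0.5)      # 5 of 10 epitopes dead
  expect_equal(dim5$length_nt, base$length_nt)     # sequence length kept

  add5 <- make_tag_variant(base, "add_5")
  expect_equal(add5$n_epitopes, 15L)
  expect_equal(add5$length_nt, 1011L + 3L * 5L * 10L)
  con_a <- build_construct(gene, add5)
  expect_equal(max(con_a$epitope_counts), 15)

  split <- make_tag_variant(base, "split_3_to_C")
  con_s <- build_construct(gene, split)
  f <- con_s$epitope_profile
  # after the N-terminal block (before the gene ends) profile sits at 0.7
  expect_equal(f[split$front_len_aa + 1], 0.7)
  expect_equal(f[con_s$total_codons], 1)
  expect_lt(f[con_s$total_codons - split$back_len_aa], 1)

  relC <- make_tag_variant(base, "relocate_C")
  con_c <- build_construct(gene, relC)
  expect_equal(con_c$epitope_profile[400], 0)      # nothing before 3' tag
  expect_equal(max(con_c$epitope_profile), 1)
})

test_that("synthetic genes are reproducible, stop-free and usage-faithful", {
  g1 <- generate_synthetic_gene(1200, seed = 7)
  g2 <- generate_synthetic_gene(1200, seed = 7)
  expect_identical(g1$nucleotides, g2$nucleotides)
  expect_error(generate_synthetic_gene(1000), "multiple of 3")

  lens <- table_gene_lengths()
  expect_equal(unname(lens[c("RRAGC", "P300")]), c(1200L, 7257L))
  for (nm in names(lens)) {
    g <- generate_synthetic_gene(lens[[nm]], seed = 1)
    expect_equal(g$length_nt, unname(lens[[nm]]))
  }

  # uniform usage: multinomial goodness-of-fit holds and no codon strays
  # beyond 4 sd (family-wise-safe bound over 61 codons)
  g <- generate_synthetic_gene(30000, human_codon_usage(uniform = TRUE),
                               seed = 11)
  counts <- table(factor(g$codons, levels = names(human_codon_usage())))
  n <- 10000; p <- 1 / 61
  expect_gt(stats::chisq.test(counts)$p.value, 1e-3)
  expect_true(all(abs(counts - n * p) <= 4 * sqrt(n * p * (1 - p))))
  expect_false(any(g$codons %in% c("TAA", "TAG", "TGA")))
})

test_that("coding sequence validation rejects malformed input", {
  expect_error(coding_sequence("ATGAA"), "multiple of 3")
  expect_error(coding_sequence("ATGTAAGGG"), "internal stop")
  expect_silent(coding_sequence("ATGGGGTAA"))   # terminal stop allowed
  expect_silent(coding_sequence("AUGGCU"))      # RNA alphabet accepted
})

test_that("FASTA round-trip preserves sequences", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">geneA", "ATGGCTGCA", ">geneB", "ATGAAA", "GCTTAA"), path)
  seqs <- read_coding_fasta(path)
  expect_equal(length(seqs), 2)
  expect_equal(seqs[[1]]$nucleotides, "ATGGCTGCA")
  expect_equal(seqs[[2]]$nucleotides, "ATGAAAGCTTAA")
})

test_that("JSON serialization records the construct layout", {
  con <- ladder_construct("ORC2")
  js <- jsonlite::fromJSON(construct_json(con))
  expect_equal(js$total_codons, (1734 + 1011) / 3)
  expect_equal(length(js$epitope_completion_codons), 10)
  js_tag <- jsonlite::fromJSON(construct_json(tag_design()))
  expect_equal(js_tag$length_nt, 1011)
})
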