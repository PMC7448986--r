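ch <- asNamespace("chemrec")

test_that("an intronless perfect match is recovered exactly", {
  set.seed(31)
  prot <- rand_protein(150)
  cds <- ch$with_local_seed(31, ch$protein_to_cds(prot))
  dna <- paste0(rand_dna(400), cds, rand_dna(400))
  m <- spliced_align(prot, dna)
  expect_true(m$aligned)
  expect_equal(nrow(m$exons), 1L)
  expect_equal(unname(m$exons[1, ]), c(400L, 400L + nchar(cds)))
  expect_identical(m$protein, prot)
  expect_equal(m$frameshift_events, 0L)
  expect_equal(m$internal_stop_count, 0L)
  # score dominance: equals straight protein self-alignment score
  sub <- scoring_scheme()$matrix
  aa <- strsplit(prot, "")[[1]]
  expect_equal(m$score, sum(diag(sub[aa, aa])))
})

test_that("an inserted GT..AG intron is recovered at the exact junction", {
  set.seed(32)
  prot <- rand_protein(180)
  cds <- ch$with_local_seed(32, ch$protein_to_cds(prot))
  intron <- paste0("GT", rand_dna(196), "AG")
  genic <- paste0(substr(cds, 1, 300), intron, substr(cds, 301, nchar(cds)))
  dna <- paste0(rand_dna(350), genic, rand_dna(350))
  m <- spliced_align(prot, dna)
  expect_equal(nrow(m$exons), 2L)
  expect_equal(unname(m$exons[1, ]), c(350L, 650L))
  expect_equal(unname(m$exons[2, ]), c(850L, 850L + nchar(cds) - 300L))
  expect_identical(m$protein, prot)
  expect_identical(m$cds, cds)
})

test_that("a 1-bp deletion is modeled as one frameshift event", {
  set.seed(33)
  prot <- rand_protein(160)
  cds <- ch$with_local_seed(33, ch$protein_to_cds(prot))
  mut <- paste0(substr(cds, 1, 119), substr(cds, 121, nchar(cds)))
  dna <- paste0(rand_dna(300), mut, rand_dna(300))
  m <- spliced_align(prot, dna)
  expect_equal(m$frameshift_events, 1L)
  expect_gte(nchar(m$protein), nchar(prot) - 3)
})

test_that("premature stops are counted and shown as X", {
  set.seed(34)
  prot <- rand_protein(160)
  cds <- ch$with_local_seed(34, ch$protein_to_cds(prot))
  mut <- paste0(substr(cds, 1, 240), "TAA", substr(cds, 244, nchar(cds)))
  dna <- paste0(rand_dna(200), mut, rand_dna(200))
  m <- spliced_align(prot, dna)
  expect_equal(m$internal_stop_count, 1L)
  expect_identical(substr(m$protein, 81, 81), "X")
})

test_that("reported introns are always GT..AG", {
  set.seed(35)
  for (rep in 1:5) {
    prot <- rand_protein(200)
    cds <- ch$protein_to_cds(prot)
    g <- forge_gene(cds, sample(1:4, 1))
    dna <- paste0(rand_dna(600), g$seq, rand_dna(600))
    m <- spliced_align(ch$mutate_protein(prot, 0.1), dna)
    if (nrow(m$exons) < 2) next
    for (k in seq_len(nrow(m$exons) - 1)) {
      expect_identical(substr(dna, m$exons[k, 2] + 1, m$exons[k, 2] + 2),
                       "GT")
      expect_identical(substr(dna, m$exons[k + 1, 1] - 1,
                              m$exons[k + 1, 1]), "AG")
    }
  }
})

test_that("no alignment above zero gives a rejected empty model", {
  m <- spliced_align(paste(rep("W", 60), collapse = ""),
                     paste(rep("A", 500), collapse = ""))
  expect_false(m$aligned)
  expect_equal(nrow(m$exons), 0L)
})

test_that("best-model selection prefers the true source and breaks ties lexicographically", {
  set.seed(36)
  prot <- rand_protein(200)
  cds <- ch$with_local_seed(36, ch$protein_to_cds(prot))
  g <- ch$with_local_seed(37, forge_gene(cds, 2))
  genome <- c(s1 = paste0(rand_dna(2500), g$seq, rand_dna(2500)))
  true_ref <- ch$with_local_seed(38, ch$mutate_protein(prot, 0.08))
  far_ref <- ch$with_local_seed(39, ch$mutate_protein(prot, 0.35))
  refs <- c(REF_far = far_ref, REF_true = true_ref)
  hs <- search_all(refs, genome, evalue_cutoff = 1e-3)
  loci <- chain_hits(hs)
  expect_length(loci, 1L)
  l <- add_flanks(loci[[1]], nchar(genome[[1]]))
  m <- select_best_model(l, refs, genome, top_n = 5)
  expect_equal(m$reference_id, "REF_true")
  # tie contract: identical references -> lexicographically smaller id wins
  refs2 <- c(REF_b = true_ref, REF_a = true_ref)
  hs2 <- search_all(refs2, genome, evalue_cutoff = 1e-3)
  l2 <- add_flanks(chain_hits(hs2)[[1]], nchar(genome[[1]]))
  m2 <- select_best_model(l2, refs2, genome)
  expect_equal(m2$reference_id, "REF_a")
})

test_that("minus-strand models come back in forward coordinates", {
  set.seed(40)
  prot <- rand_protein(150)
  cds <- ch$with_local_seed(40, ch$protein_to_cds(prot))
  g <- ch$with_local_seed(41, forge_gene(cds, 1))
  fwd <- paste0(rand_dna(1000), g$seq, rand_dna(1000))
  genome <- c(s1 = ch$cr_revcomp(fwd))
  ref <- c(R1 = prot)
  hs <- search_all(ref, genome, evalue_cutoff = 1e-3)
  expect_true(all(hs$strand == "-"))
  l <- add_flanks(chain_hits(hs)[[1]], nchar(genome[[1]]))
  m <- select_best_model(l, ref, genome)
  expect_identical(m$protein, prot)
  expect_equal(m$strand, "-")
  L <- nchar(fwd)
  # forward-strand coordinates mirror the construction positions
  expect_equal(sort(as.vector(L - m$exons)),
               sort(as.vector(1000L + g$exons)))
})
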