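test_that("single intronless gene is planted verbatim and recorded", {
  spec <- family_spec(n_genes = 1, intron_count_range = c(0L, 0L),
                      n_pseudo_stop = 0, n_pseudo_frameshift = 0,
                      n_partial = 0, tandem_cluster_sizes = integer(0),
                      scaffold_count = 1, scaffold_length = 20000,
                      protein_length_range = c(100L, 120L), rng_seed = 3)
  fg <- forge_genome(spec)
  expect_equal(nrow(fg$truth$genes), 1L)
  expect_equal(nrow(fg$truth$exons), 1L)
  g <- fg$truth$genes[1, ]
  cds <- fg$truth$cds[[g$gene_id]]
  seg <- substr(fg$genome[[g$scaffold]], g$start0 + 1, g$end0)
  if (g$strand == "-") seg <- chartr("ACGT", "TGCA",
                                     paste(rev(strsplit(seg, "")[[1]]),
                                           collapse = ""))
  expect_identical(seg, cds)
})

test_that("planted exons translate back to the recorded protein", {
  fg <- forge_genome(family_spec(n_genes = 10, n_pseudo_stop = 1,
                                 n_pseudo_frameshift = 1, n_partial = 1,
                                 tandem_cluster_sizes = c(3L),
                                 scaffold_count = 2,
                                 scaffold_length = 150000, rng_seed = 5))
  tg <- fg$truth$genes
  for (i in seq_len(nrow(tg))) {
    g <- tg[i, ]
    ex <- fg$truth$exons[fg$truth$exons$gene_id == g$gene_id, ]
    # exon rows are stored 5'->3' on the coding strand; on the minus strand
    # each forward-strand slice is reverse-complemented individually
    pieces <- substring(fg$genome[[g$scaffold]], ex$start0 + 1, ex$end0)
    if (g$strand == "-")
      pieces <- vapply(pieces, function(p)
        chartr("ACGT", "TGCA", paste(rev(strsplit(p, "")[[1]]),
                                     collapse = "")), character(1))
    cds <- paste(pieces, collapse = "")
    expect_identical(cds, fg$truth$cds[[g$gene_id]], label = g$gene_id)
    tr <- oracle_translate(cds)[["+1"]]
    if (g$status == "intact")
      expect_identical(tr, fg$truth$proteins[[g$gene_id]])
    if (g$status == "pseudo_stop")
      expect_true(grepl("*", substr(tr, 1, nchar(tr) - 1), fixed = TRUE))
    if (g$status == "pseudo_frameshift")
      expect_equal(nchar(fg$truth$cds[[g$gene_id]]) %% 3L, 2L)
  }
  # intron boundaries are GT..AG on the coding strand
  for (gid in unique(fg$truth$exons$gene_id)) {
    g <- tg[tg$gene_id == gid, ]
    ex <- fg$truth$exons[fg$truth$exons$gene_id == gid, ]
    if (nrow(ex) < 2) next
    scaf <- fg$genome[[g$scaffold]]
    for (k in seq_len(nrow(ex) - 1)) {
      if (g$strand == "+") {
        don <- substr(scaf, ex$end0[k] + 1, ex$end0[k] + 2)
        acc <- substr(scaf, ex$start0[k + 1] - 1, ex$start0[k + 1])
        expect_identical(c(don, acc), c("GT", "AG"))
      } else {
        # coding-strand GT..AG reads AC..CT on the forward strand
        don <- substr(scaf, ex$start0[k] - 1, ex$start0[k])
        acc <- substr(scaf, ex$end0[k + 1] + 1, ex$end0[k + 1] + 2)
        expect_identical(c(don, acc), c("AC", "CT"))
      }
    }
  }
})

test_that("forging is byte-identical under a fixed seed", {
  spec <- family_spec(n_genes = 6, scaffold_count = 1,
                      scaffold_length = 100000, n_pseudo_stop = 1,
                      n_pseudo_frameshift = 0, n_partial = 0,
                      tandem_cluster_sizes = integer(0), rng_seed = 7)
  a <- forge_genome(spec)
  b <- forge_genome(spec)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth$genes, b$truth$genes)
  expect_identical(a$refs, b$refs)
  c <- forge_genome(family_spec(n_genes = 6, scaffold_count = 1,
                                scaffold_length = 100000,
                                n_pseudo_stop = 1, n_pseudo_frameshift = 0,
                                n_partial = 0,
                                tandem_cluster_sizes = integer(0),
                                rng_seed = 8))
  expect_false(identical(a$genome, c$genome))
})

test_that("status counts follow the spec and clusters sit within 50 kb", {
  fg <- forge_genome(family_spec(rng_seed = 2))
  expect_equal(sum(fg$truth$genes$status == "pseudo_stop"), 6L)
  expect_equal(sum(fg$truth$genes$status == "pseudo_frameshift"), 4L)
  expect_equal(sum(fg$truth$genes$status == "partial"), 5L)
  expect_equal(nrow(fg$truth$genes), 60L)
  # the two 4-gene clusters are the first 8 gene ids, placed contiguously
  for (ids in list(sprintf("OR_g%03d", 1:4), sprintf("OR_g%03d", 5:8))) {
    rows <- fg$truth$genes[fg$truth$genes$gene_id %in% ids, ]
    expect_equal(length(unique(rows$scaffold)), 1L)
    expect_lt(max(rows$end0) - min(rows$start0), 50000)
    expect_equal(length(unique(rows$strand)), 1L)
  }
})

test_that("overfull spec raises a sizing error", {
  spec <- family_spec(n_genes = 30, scaffold_count = 1,
                      scaffold_length = 60000, n_pseudo_stop = 0,
                      n_pseudo_frameshift = 0, n_partial = 0,
                      tandem_cluster_sizes = integer(0), rng_seed = 1)
  expect_error(forge_genome(spec), "capacity")
})

test_that("transcripts reproduce the CDS and extra genes are genome-absent", {
  fg <- forge_genome(family_spec(n_genes = 6, n_pseudo_stop = 1,
                                 n_pseudo_frameshift = 0, n_partial = 1,
                                 tandem_cluster_sizes = integer(0),
                                 scaffold_count = 1,
                                 scaffold_length = 120000, rng_seed = 4))
  tx0 <- forge_transcripts(fg$truth, seed = 1, truncation = c(0L, 0L))
  intact <- fg$truth$genes$gene_id[fg$truth$genes$status == "intact"]
  expect_setequal(names(tx0), paste0("TX_", intact))
  for (g in intact)
    expect_identical(tx0[[paste0("TX_", g)]], fg$truth$cds[[g]])
  extra <- c(ORx1 = rand_protein(300), ORx2 = rand_protein(300))
  tx1 <- forge_transcripts(fg$truth, extra, seed = 1)
  expect_true(all(c("TX_ORx1", "TX_ORx2") %in% names(tx1)))
  expect_equal(length(tx1), length(intact) + 2L)
  expect_identical(forge_transcripts(fg$truth, extra, seed = 1), tx1)
})
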