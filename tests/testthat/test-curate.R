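ch <- asNamespace("chemrec")

mk_model <- function(protein, stops = 0L, fs = 0L) {
  structure(list(gene_id = "g", locus_id = "l", scaffold_id = "s",
                 strand = "+", exons = matrix(c(0L, 3L * nchar(protein)), 1),
                 cds = "", protein = protein, model_score = 100,
                 frameshift_events = fs, internal_stop_count = stops,
                 reference_id = "r", family = "OR",
                 status = "unclassified"), class = "gene_model")
}

test_that("retention rules follow the published thresholds", {
  cfg <- pipeline_config()
  # 195 aa clean model vs 400 aa reference: below half-length -> rejected
  expect_equal(classify_status(mk_model(rand_protein(195)), 400, cfg)$status,
               "rejected")
  # 189 aa clean vs 300 aa reference: not larger than 190 aa -> rejected
  expect_equal(classify_status(mk_model(rand_protein(189)), 300, cfg)$status,
               "rejected")
  # 191 aa vs 300 aa reference: > 190 and >= half -> partial
  expect_equal(classify_status(mk_model(rand_protein(191)), 300, cfg)$status,
               "partial")
  # 190 aa boundary is excluded (strictly larger than 190)
  expect_equal(classify_status(mk_model(rand_protein(190)), 300, cfg)$status,
               "rejected")
  # full-length at 0.9 x reference
  expect_equal(classify_status(mk_model(rand_protein(360)), 400, cfg)$status,
               "full")
  # pseudogenes bypass all length filters
  expect_equal(classify_status(mk_model(rand_protein(120), stops = 1L), 400,
                               cfg)$status, "pseudogene")
  expect_equal(classify_status(mk_model(rand_protein(250), fs = 1L), 300,
                               cfg)$status, "pseudogene")
})

test_that("family assignment uses best hit with a decoy and margin rule", {
  set.seed(51)
  or1 <- rand_protein(300); gr1 <- rand_protein(300)
  dec <- rand_protein(300)
  db <- list(OR = c(OR1 = or1), GR = c(GR1 = gr1), decoy = c(D1 = dec))
  expect_equal(assign_family(or1, db), "OR")
  expect_equal(assign_family(gr1, db), "GR")
  expect_equal(assign_family(dec, db), "inconsistent")
  # identical best hits in two families -> zero margin -> inconsistent
  db2 <- list(OR = c(OR1 = or1), GR = c(GR1 = or1))
  expect_equal(assign_family(or1, db2), "inconsistent")
  expect_error(assign_family(or1, list()), "empty")
})

test_that("completeness thresholds behave exactly at the boundaries", {
  set.seed(52)
  ref <- rand_protein(400)
  refs <- c(R1 = ref)
  ann <- annotation_set(list(), species = "t", family = "OR")
  tx <- c(t119 = ch$protein_to_cds(substr(ref, 1, 119)),
          t120 = ch$protein_to_cds(substr(ref, 1, 120)))
  rep_or <- completeness_check(tx, refs, ann)
  expect_equal(rep_or$min_homology_aa, 120L)
  tab <- rep_or$table
  expect_false(tab$candidate[tab$transcript == "t119"])
  expect_true(tab$candidate[tab$transcript == "t120"])
  expect_equal(rep_or$transcripts_total, 1L)
  expect_equal(rep_or$transcripts_missing, 1L) # nothing annotated
  # IR threshold 190
  ann_ir <- annotation_set(list(), species = "t", family = "IR")
  tx_ir <- c(t150 = ch$protein_to_cds(substr(ref, 1, 150)),
             t189 = ch$protein_to_cds(substr(ref, 1, 189)),
             t190 = ch$protein_to_cds(substr(ref, 1, 190)))
  rep_ir <- completeness_check(tx_ir, refs, ann_ir)
  expect_equal(rep_ir$min_homology_aa, 190L)
  expect_equal(rep_ir$transcripts_total, 1L)
  expect_true(rep_ir$table$candidate[3])
  expect_false(any(rep_ir$table$candidate[1:2]))
})

test_that("found/missing accounting separates genome-absent transcripts", {
  fg <- forge_genome(family_spec(n_genes = 5, n_pseudo_stop = 0,
                                 n_pseudo_frameshift = 0, n_partial = 0,
                                 tandem_cluster_sizes = integer(0),
                                 scaffold_count = 1,
                                 scaffold_length = 120000, rng_seed = 53))
  ann <- truth_to_annotation(fg$truth)
  # three family members absent from the genome (20% diverged relatives)
  extra <- setNames(lapply(fg$truth$proteins[1:3], ch$mutate_protein,
                           div = 0.20), c("abs1", "abs2", "abs3"))
  extra <- unlist(extra)
  tx <- forge_transcripts(fg$truth, extra, seed = 2)
  rep <- completeness_check(tx, fg$refs, ann)
  expect_equal(rep$transcripts_total, 8L)
  expect_equal(rep$transcripts_found_in_annotation, 5L)
  expect_equal(rep$transcripts_missing, 3L)
  expect_equal(rep$transcripts_found_in_annotation +
                 rep$transcripts_missing, rep$transcripts_total)
})

test_that("two-round identification is a fixed point when refs are exact", {
  fg <- forge_genome(family_spec(n_genes = 4, n_pseudo_stop = 0,
                                 n_pseudo_frameshift = 0, n_partial = 0,
                                 tandem_cluster_sizes = integer(0),
                                 scaffold_count = 1,
                                 scaffold_length = 100000, rng_seed = 54))
  exact_refs <- fg$truth$proteins
  names(exact_refs) <- paste0("REF_", names(exact_refs))
  ann <- run_two_round(fg$genome, exact_refs, pipeline_config(),
                       family = "OR", species = "t")
  expect_equal(unname(ann$counts["total"]), 4)
  expect_equal(length(ann$round1_models), length(ann$models))
  expect_equal(unname(ann$counts["total"]),
               unname(sum(ann$counts[c("full_length", "partial",
                                       "pseudogene")])))
})

test_that("an empty genome yields an empty annotation set", {
  genome <- c(s1 = rand_dna(50000))
  refs <- c(R1 = rand_protein(300))
  ann <- run_two_round(genome, refs, pipeline_config(), family = "OR",
                       species = "t")
  expect_equal(unname(ann$counts["total"]), 0)
})

test_that("round 2 rescues a gene only reachable through a round-1 paralog", {
  set.seed(55)
  # gene A: 2 introns (long exons), found by the 40%-diverged reference;
  # gene B: paralog of A (10% divergence) split into many short exons, so
  # every exon hit against the distant reference stays above the e-value
  # cutoff's score floor only for the much closer round-1 protein of A
  protA <- rand_protein(430)
  protB <- ch$mutate_protein(protA, 0.10)
  gA <- forge_gene(ch$protein_to_cds(protA), 2)
  cdsB <- ch$protein_to_cds(protB)
  # ~20-codon exons and a reference with uniform per-window divergence, so
  # no single exon of B clears the e-value score floor against the distant
  # reference, while every exon is findable by the round-1 protein of A
  bnd <- seq(20L, nchar(cdsB) %/% 3L - 2L, by = 20L) * 3L
  gB <- forge_gene(cdsB, length(bnd), boundaries = bnd)
  genome <- c(s1 = paste0(rand_dna(8000), gA$seq, rand_dna(30000), gB$seq,
                          rand_dna(8000)))
  refs <- c(REF_A = mutate_protein_stratified(protA, 0.40, 20L))
  cfg <- pipeline_config()
  ann <- run_two_round(genome, refs, cfg, family = "OR", species = "t")
  r1_span <- vapply(ann$round1_models, function(m) min(m$exons),
                    numeric(1))
  b_start <- 8000 + nchar(gA$seq) + 30000
  found_r1 <- any(r1_span > b_start - 2000)
  found_r2 <- any(vapply(ann$models, function(m) min(m$exons),
                         numeric(1)) > b_start - 2000)
  expect_false(found_r1)
  expect_true(found_r2)
  # monotonicity: round 2 never loses genes
  expect_gte(length(ann$models), length(ann$round1_models))
})
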