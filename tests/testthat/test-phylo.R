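test_that("tree length filters follow the family thresholds", {
  p <- setNames(c(rand_protein(229), rand_protein(230), rand_protein(250),
                  rand_protein(249), rand_protein(200)),
                c("or229", "or230", "x250", "x249", "x200"))
  expect_setequal(names(filter_for_tree(p, "OR")),
                  c("or230", "x250", "x249"))
  expect_setequal(names(filter_for_tree(p, "GR")), "x250")
  expect_setequal(names(filter_for_tree(p, "IR")), names(p))
})

test_that("alignment places gaps correctly and round-trips", {
  a <- build_msa(c(s1 = "ACDEFG", s2 = "ACDEFG"))
  expect_false(any(grepl("-", unclass(a), fixed = TRUE)))
  b <- build_msa(c(s1 = "ACDEFG", s2 = "ACEFG"))
  expect_equal(unique(nchar(unclass(b))), 6L)
  gap_col <- which(strsplit(b[["s2"]], "")[[1]] == "-")
  expect_length(gap_col, 1L)
  expect_equal(strsplit(b[["s1"]], "")[[1]][gap_col], "D")
  set.seed(61)
  p <- setNames(vapply(1:4, function(i) rand_protein(80), character(1)),
                paste0("s", 1:4))
  m <- build_msa(p)
  expect_identical(gsub("-", "", unclass(m)), unclass(p))
  expect_error(build_msa(c(a = "ACDEF")), "at least 2")
})

test_that("JTT distances are zero on identity, symmetric, and recover t", {
  set.seed(62)
  r <- rand_protein(200)
  expect_equal(as.numeric(jtt_distance(r, r)), 0, tolerance = 1e-6)
  a <- rand_protein(200); b <- rand_protein(200)
  expect_equal(as.numeric(jtt_distance(a, b)),
               as.numeric(jtt_distance(b, a)))
  # simulation recovery at t = 0.5 under JTT
  tree <- ape::read.tree(text = "(a:0.25,b:0.25);")
  sim <- phangorn::simSeq(tree, l = 10000, type = "AA", model = "JTT")
  mat <- toupper(as.character(sim))
  d <- jtt_distance(paste(mat["a", ], collapse = ""),
                    paste(mat["b", ], collapse = ""))
  expect_gt(d, 0.45); expect_lt(d, 0.55)
  expect_warning(jtt_distance(substr(a, 1, 20), substr(b, 1, 20)),
                 "unreliable")
  # gamma rate heterogeneity: zero at identity, inflates diverged distances
  expect_equal(as.numeric(jtt_distance(r, r, gamma_shape = 1)), 0,
               tolerance = 1e-6)
  ra <- paste(mat["a", ], collapse = ""); rb <- paste(mat["b", ],
                                                     collapse = "")
  expect_gt(as.numeric(jtt_distance(ra, rb, gamma_shape = 1)),
            as.numeric(jtt_distance(ra, rb)))
})

test_that("neighbor joining is exact on additive matrices", {
  set.seed(63)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    true <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    d <- stats::cophenetic(true)
    est <- nj_from_distances(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true),
                                           ape::unroot(est))), 0,
                 label = paste("rep", rep))
  }
})

sim_family_msa <- function(n_pairs = 4, seed = 64, l = 400,
                           pair_bl = 0.05, anc_bl = 0.6) {
  # one (A_i, B_i) cherry per orthologue pair plus an outgroup leaf
  set.seed(seed)
  nwk <- paste0("(", paste(vapply(seq_len(n_pairs), function(i)
    sprintf("(A%d:%f,B%d:%f):%f", i, pair_bl, i, pair_bl, anc_bl),
    character(1)), collapse = ","), ",OUT:1.2);")
  tree <- ape::read.tree(text = nwk)
  sim <- phangorn::simSeq(tree, l = l, type = "AA", model = "JTT")
  mat <- toupper(as.character(sim))
  seqs <- setNames(apply(mat, 1, paste, collapse = ""), rownames(mat))
  structure(seqs, class = "msa")
}

test_that("bootstrapped trees recover planted cherries with stable seeds", {
  msa <- sim_family_msa(n_pairs = 4)
  t1 <- build_tree(msa, family = "IR", n_bootstrap = 50, seed = 9,
                   outgroup = "OUT")
  t2 <- build_tree(msa, family = "IR", n_bootstrap = 50, seed = 9,
                   outgroup = "OUT")
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(ape::is.rooted(t1))
  sp <- setNames(sub("[0-9]+$", "", t1$tip.label), t1$tip.label)
  pairs <- find_ortholog_pairs(t1, sp, focal_species = c("A", "B"))
  expect_equal(nrow(pairs), 4L)
  expect_setequal(sub("A", "", pairs$gene_a), sub("B", "", pairs$gene_b))
  # strong cherries get strong support
  expect_true(all(pairs$support >= 75))
})

test_that("rooting preserves bipartition supports", {
  msa <- sim_family_msa(n_pairs = 3, seed = 65)
  unrooted <- build_tree(msa, family = "IR", n_bootstrap = 30, seed = 4)
  rooted <- build_tree(msa, family = "IR", n_bootstrap = 30, seed = 4,
                       outgroup = "OUT")
  sup_of <- function(tr) {
    ntip <- length(tr$tip.label)
    labs <- as.character(tr$node.label)
    desc <- phangorn::Descendants(tr, (ntip + 1):(ntip + tr$Nnode), "tips")
    key <- vapply(desc, function(ix) {
      s <- sort(tr$tip.label[ix])
      if ("OUT" %in% s) s <- sort(setdiff(tr$tip.label, s))
      paste(s, collapse = "|")
    }, character(1))
    ok <- !is.na(labs) & labs != "" & labs != "Root" & !duplicated(key)
    setNames(labs[ok], key[ok])
  }
  su <- sup_of(unrooted); sr <- sup_of(rooted)
  common <- intersect(names(su), names(sr))
  expect_gt(length(common), 0)
  expect_identical(su[common], sr[common])
})

test_that("ortholog pairing follows the exclusive two-leaf clade rule", {
  t1 <- ape::read.tree(text = "((A1:1,B1:1):1,(A2:1,B2:1):1);")
  sp <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  p1 <- find_ortholog_pairs(t1, sp, c("A", "B"))
  expect_equal(nrow(p1), 2L)
  expect_setequal(paste(p1$gene_a, p1$gene_b), c("A1 B1", "A2 B2"))
  # a paralog cherry blocks pairing
  t2 <- ape::root(ape::read.tree(text = "((A1:1,A2:1):1,B1:2);"), "B1",
                  resolve.root = TRUE)
  p2 <- find_ortholog_pairs(t2, sp, c("A", "B"))
  expect_equal(nrow(p2), 0L)
  expect_error(find_ortholog_pairs(ape::unroot(t1), sp), "rooted")
  # every gene appears in at most one pair
  expect_lte(max(table(c(p1$gene_a, p1$gene_b))), 1L)
})
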