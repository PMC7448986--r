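ch <- asNamespace("chemrec")

mk_aln <- function(codons_a, codons_b) {
  structure(list(ids = c("a", "b"), codons_a = codons_a,
                 codons_b = codons_b, n_codons = length(codons_a)),
            class = "codon_alignment")
}

test_that("codon alignment back-translates a guided protein alignment", {
  cds_a <- "ATGAAAGTT"          # M K V
  cds_b <- "ATGGTT"             # M V
  msa <- c(a = "MKV", b = "M-V")
  aln <- suppressWarnings(codon_align(msa, cds_a, cds_b))
  expect_equal(aln$codons_a, c("ATG", "AAA", "GTT"))
  expect_equal(aln$codons_b, c("ATG", "---", "GTT"))
  # identical gapless pair reproduces the CDS verbatim
  aln2 <- suppressWarnings(codon_align(c(a = "MKV", b = "MKV"), cds_a,
                                       cds_a))
  expect_equal(paste(aln2$codons_a, collapse = ""), cds_a)
  expect_equal(paste(aln2$codons_b, collapse = ""), cds_a)
  # mismatched CDS errors with the discordant codon index
  expect_error(codon_align(c(a = "MKV", b = "MWV"), cds_a, "ATGAAAGTT"),
               "codon 2")
  # stop-containing columns are removed with a warning
  w <- capture_warnings(
    aln3 <- codon_align(c(a = "MXV", b = "MKV"), "ATGTAAGTT", cds_a))
  expect_true(any(grepl("stop", w)))
  expect_equal(aln3$n_codons, 2L)
})

test_that("pairwise lnL matches the brute-force category-sum oracle", {
  aln <- mk_aln(c("ATG", "AAA"), c("ATG", "AGA"))
  pat <- ch$codon_patterns(aln)
  for (par in list(list(m = "M7", p = c(0.4, 2, 0.5, 1.5)),
                   list(m = "M8", p = c(0.4, 2, 0.5, 1.5, 0.7, 2.5)))) {
    mine <- ch$pair_loglik(par$p, par$m, pat, K = 10)
    ora <- oracle_pair_lnL(aln$codons_a, aln$codons_b, par$m,
                           t = par$p[1], kappa = par$p[2], p = par$p[3],
                           q = par$p[4],
                           p0 = if (par$m == "M8") par$p[5] else 1,
                           omega_s = if (par$m == "M8") par$p[6] else 2)
    expect_equal(mine, ora, tolerance = 1e-8, label = par$m)
  }
})

test_that("identical sequences drive t to the floor with stationary lnL", {
  set.seed(81)
  tab <- ch$cr_codon_tables()
  cods <- sample(tab$codons, 120, replace = TRUE)
  aln <- mk_aln(cods, cods)
  fit <- fit_site_model(aln, "M7")
  expect_lte(fit$t, 1e-3)
  expect_equal(fit$lnL, 120 * log(1 / 61), tolerance = 1e-3)
})

test_that("M8 never falls below M7 (nesting) and the LRT behaves", {
  for (seed in 82:84) {
    sim <- simulate_codon_pair(codon_sim_spec("M7", n_codons = 150, t = 0.4,
                                              rng_seed = seed))
    aln <- mk_aln(sim$codons_a, sim$codons_b)
    f7 <- fit_site_model(aln, "M7")
    f8 <- fit_site_model(aln, "M8", init = f7)
    expect_gte(f8$lnL, f7$lnL - 1e-4)
    lr <- lrt(f7, f8)
    expect_gte(lr$delta, 0)
    expect_gte(lr$p_value, 0); expect_lte(lr$p_value, 1)
  }
})

test_that("the LRT matches an independent chi-square oracle", {
  f7 <- structure(list(model = "M7", lnL = -1000, n_codons = 100,
                       patterns = list(n = c(50, 50))),
                  class = "site_model_fit")
  mk8 <- function(lnL) structure(
    list(model = "M8", lnL = lnL, n_codons = 100,
         patterns = list(n = c(50, 50))), class = "site_model_fit")
  expect_equal(lrt(f7, mk8(-1000))$p_value, 1)
  # optimizer noise below M7 floors at zero
  expect_equal(lrt(f7, mk8(-1000.01))$delta, 0)
  # delta at the 1% point of chi-square df 1
  crit <- qchisq(0.99, df = 1)
  expect_equal(lrt(f7, mk8(-1000 + crit / 2))$p_value, 0.01,
               tolerance = 1e-10)
  expect_equal(lrt(f7, mk8(-1000 + crit / 2), df = 2)$p_value,
               pchisq(crit, 2, lower.tail = FALSE), tolerance = 1e-10)
  f7b <- f7; f7b$patterns$n <- c(99, 1)
  expect_error(lrt(f7b, mk8(-999)), "different alignments")
})

test_that("NEB on a single site equals hand-computed Bayes", {
  aln <- mk_aln("AAA", "AGA")
  fit <- structure(list(model = "M8", lnL = 0, t = 0.6, kappa = 2, p = 0.5,
                        q = 1.5, p0 = 0.7, omega_s = 3, K = 10,
                        converged = TRUE, n_codons = 1),
                   class = "site_model_fit")
  mine <- neb_sites(fit, aln)
  # brute force over the 11 categories with an independent expm
  om <- c(oracle_beta_means(0.5, 1.5, 10), 3)
  w <- c(rep(0.7 / 10, 10), 0.3)
  Qs <- lapply(om, oracle_gy94, kappa = 2)
  mu <- sum(vapply(seq_along(om), function(k) w[k] * mean(-diag(Qs[[k]])),
                   numeric(1)))
  liks <- vapply(seq_along(om), function(k) {
    P <- as.matrix(Matrix::expm(Qs[[k]] * 0.6 / mu))
    (1 / 61) * P["AAA", "AGA"]
  }, numeric(1))
  post <- w * liks / sum(w * liks)
  expect_equal(mine[1], sum(post[om > 1]), tolerance = 1e-6)
})

test_that("NEB with all omega classes below 1 is identically zero", {
  aln <- mk_aln(c("AAA", "GGG"), c("AGA", "GGG"))
  fit <- structure(list(model = "M8", lnL = 0, t = 0.4, kappa = 2, p = 0.5,
                        q = 5, p0 = 1, omega_s = 1.5, K = 10,
                        converged = TRUE, n_codons = 2),
                   class = "site_model_fit")
  expect_true(all(ch$beta_class_means(0.5, 5, 10) < 1))
  expect_equal(neb_sites(fit, aln), c(0, 0))
})

test_that("BEB collapses to NEB on a single-point grid and stays in [0,1]", {
  sim <- simulate_codon_pair(codon_sim_spec("M8", n_codons = 80, t = 0.5,
                                            p0 = 0.6, omega_s = 3,
                                            rng_seed = 85))
  aln <- mk_aln(sim$codons_a, sim$codons_b)
  f8 <- fit_site_model(aln, "M8")
  neb <- neb_sites(f8, aln)
  beb1 <- beb_sites(f8, aln, grid_points = 1)
  expect_equal(beb1, neb, tolerance = 1e-10)
  beb <- beb_sites(f8, aln)
  expect_true(all(beb >= 0 & beb <= 1, na.rm = TRUE))
})

test_that("selected-class sites rank above beta sites in NEB", {
  sim <- simulate_codon_pair(codon_sim_spec("M8", n_codons = 500, t = 0.8,
                                            p0 = 0.5, omega_s = 3,
                                            rng_seed = 86))
  aln <- mk_aln(sim$codons_a, sim$codons_b)
  f8 <- fit_site_model(aln, "M8")
  neb <- neb_sites(f8, aln)
  expect_gt(mean(neb[sim$category == "selected"]),
            mean(neb[sim$category == "beta"]))
})

test_that("the selection call applies both cutoffs exactly", {
  mk <- function(p) list(delta = qchisq(1 - p, 1), p_value = p, df = 1L)
  neb <- c(0.99, 0.50); beb <- c(0.99, 0.40)
  # LRT not significant at 0.01 despite perfect sites
  r1 <- call_selection("p1", mk(0.02), neb, beb)
  expect_false(r1$positively_selected)
  # significant LRT but BEB below 0.95
  r2 <- call_selection("p2", mk(0.005), c(0.97, 0.5), c(0.93, 0.4))
  expect_false(r2$positively_selected)
  expect_length(r2$selected_sites, 0)
  # both cutoffs met
  r3 <- call_selection("p3", mk(0.005), c(0.97, 0.5), c(0.96, 0.4))
  expect_true(r3$positively_selected)
  expect_equal(r3$selected_sites, 1L)
})

test_that("BEB shrinks extreme posteriors relative to NEB on short alignments", {
  shrink <- vapply(87:90, function(seed) {
    sim <- simulate_codon_pair(codon_sim_spec("M8", n_codons = 60, t = 0.5,
                                              p0 = 0.6, omega_s = 2.5,
                                              rng_seed = seed))
    aln <- mk_aln(sim$codons_a, sim$codons_b)
    f8 <- fit_site_model(aln, "M8")
    neb <- neb_sites(f8, aln); beb <- beb_sites(f8, aln)
    mean(abs(beb - 0.5)) - mean(abs(neb - 0.5))
  }, numeric(1))
  expect_lte(mean(shrink), 0)
})
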