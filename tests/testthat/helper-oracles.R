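# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: translation via a hand-written codon table walk,
# local alignment via Biostrings::pairwiseAlignment, matrix exponentials via
# Matrix::expm, and codon rate matrices rebuilt from first principles.

# brute-force six-frame translator (hand lookup, no package code)
oracle_translate <- function(dna) {
  gc <- Biostrings::GENETIC_CODE
  tr1 <- function(s) {
    n <- nchar(s) %/% 3
    if (n == 0) return("")
    out <- character(n)
    for (i in seq_len(n)) {
      cod <- substr(s, 3 * i - 2, 3 * i)
      out[i] <- if (grepl("[^ACGT]", cod)) "X" else gc[[cod]]
    }
    paste(out, collapse = "")
  }
  rc <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", dna), "")[[1]]),
              collapse = "")
  list(`+1` = tr1(dna), `+2` = tr1(substr(dna, 2, nchar(dna))),
       `+3` = tr1(substr(dna, 3, nchar(dna))),
       `-1` = tr1(rc), `-2` = tr1(substr(rc, 2, nchar(rc))),
       `-3` = tr1(substr(rc, 3, nchar(rc))))
}

# Smith-Waterman oracle: best local score of a protein query against any of
# the six translated frames (stops as 'X'-like floor handled by the same
# -4-floored matrix the package declares)
oracle_submat <- function() {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  b <- e$BLOSUM62
  b["*", ] <- -4; b[, "*"] <- -4
  b
}

oracle_sw_score <- function(query, subject_aa, gap_open = 11,
                            gap_extend = 1) {
  if (nchar(subject_aa) < 1) return(0)
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject_aa),
    type = "local", substitutionMatrix = oracle_submat(),
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
}

oracle_best_frame_score <- function(query, dna) {
  max(vapply(oracle_translate(dna), function(p)
    if (nchar(p) >= 1) oracle_sw_score(query, p) else 0, numeric(1)))
}

# independent GY94 rate matrix (structure rebuilt from the genetic code)
oracle_gy94 <- function(kappa, omega) {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  n <- length(codons)
  Q <- matrix(0, n, n, dimnames = list(codons, codons))
  purines <- c("A", "G")
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- strsplit(codons[i], "")[[1]]; b <- strsplit(codons[j], "")[[1]]
    d <- which(a != b)
    if (length(d) != 1) next
    r <- 1 / n
    if ((a[d] %in% purines) == (b[d] %in% purines)) r <- r * kappa
    if (gc[[codons[i]]] != gc[[codons[j]]]) r <- r * omega
    Q[i, j] <- r
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# beta class means by numerical integration (independent of the package's
# closed form)
oracle_beta_means <- function(p, q, K) {
  cuts <- qbeta(seq(0, 1, length.out = K + 1), p, q)
  vapply(seq_len(K), function(k) {
    stats::integrate(function(x) x * dbeta(x, p, q), cuts[k],
                     cuts[k + 1], rel.tol = 1e-12)$value * K
  }, numeric(1))
}

# brute-force pairwise site-model log-likelihood: explicit category sum with
# an independent scaling-and-squaring expm, uniform codon frequencies
oracle_pair_lnL <- function(codons_a, codons_b, model, t, kappa, p, q,
                            p0 = 1, omega_s = 2, K = 10) {
  om <- oracle_beta_means(p, q, K)
  w <- rep(1 / K, K)
  if (model == "M8") {
    om <- c(om, omega_s)
    w <- c(w * p0, 1 - p0)
  }
  Qs <- lapply(om, oracle_gy94, kappa = kappa)
  mu <- sum(vapply(seq_along(om), function(k)
    w[k] * mean(-diag(Qs[[k]])), numeric(1)))
  codlist <- rownames(Qs[[1]])
  Ps <- lapply(Qs, function(Q) as.matrix(Matrix::expm(Q * t / mu)))
  lnL <- 0
  for (s in seq_along(codons_a)) {
    xi <- match(codons_a[s], codlist); yi <- match(codons_b[s], codlist)
    lik <- sum(vapply(seq_along(om), function(k)
      w[k] * (1 / length(codlist)) * Ps[[k]][xi, yi], numeric(1)))
    lnL <- lnL + log(lik)
  }
  lnL
}

# random sequence helpers for tests
rand_protein <- function(n) paste(sample(c("A", "R", "N", "D", "C", "Q",
  "E", "G", "H", "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
  n, replace = TRUE), collapse = "")
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# build an annotation_set directly from a truth_set (identity mapping)
truth_to_annotation <- function(truth) {
  models <- lapply(seq_len(nrow(truth$genes)), function(i) {
    g <- truth$genes[i, ]
    ex <- as.matrix(truth$exons[truth$exons$gene_id == g$gene_id,
                                c("start0", "end0")])
    status <- switch(g$status, intact = "full", partial = "partial",
                     "pseudogene")
    structure(list(gene_id = g$gene_id, locus_id = g$gene_id,
                   scaffold_id = g$scaffold, strand = g$strand,
                   exons = ex, cds = truth$cds[[g$gene_id]],
                   protein = truth$proteins[[g$gene_id]],
                   model_score = 0,
                   frameshift_events = as.integer(g$status == "pseudo_frameshift"),
                   internal_stop_count = as.integer(g$status == "pseudo_stop"),
                   reference_id = g$gene_id, family = truth$family,
                   status = status), class = "gene_model")
  })
  annotation_set(models, species = "truth", family = truth$family)
}

# substitute a fixed fraction of residues inside every `block`-residue
# window, so divergence is uniform along the sequence: no chance-conserved
# window can let a distant reference seed a local hit on its own
mutate_protein_stratified <- function(protein, div, block = 20L) {
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V")
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  starts <- seq(1L, length(ch), by = block)
  for (s0 in starts) {
    idx <- s0:min(s0 + block - 1L, length(ch))
    k <- ceiling(div * length(idx))
    pos <- sample(idx, k)
    for (p in pos) ch[p] <- sample(setdiff(aa20, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}
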