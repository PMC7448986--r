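#' Specification for a synthetic receptor-family genome
#'
#' Describes one forged gene family: how many genes to plant, their intron
#' structure, how many are disrupted into pseudogenes or truncated, tandem
#' cluster layout, and scaffold sizing. The defaults describe the standard
#' benchmark genome used throughout the package: a 2-Mb assembly (4 scaffolds
#' of 500 kb) carrying 60 receptor-like genes, of which 6 carry a premature
#' stop, 4 carry a 1-bp frameshift deletion, 5 are truncated partial genes,
#' and two groups of 4 genes form low-divergence tandem clusters.
#'
#' @param family_name family label ("OR", "GR", "IR" or custom).
#' @param n_genes number of genes to plant.
#' @param intron_count_range integer range of introns per gene (inclusive).
#' @param intron_length_range intron length range in bp (minimum 30).
#' @param protein_length_range protein length range in amino acids.
#' @param n_pseudo_stop,n_pseudo_frameshift,n_partial numbers of genes
#'   disrupted by a premature TAA stop, a 1-bp exonic deletion, or 5'
#'   truncation.
#' @param tandem_cluster_sizes sizes of tandem duplicate clusters; each
#'   cluster is placed within a 50-kb window.
#' @param within_cluster_divergence amino-acid divergence (fraction of sites
#'   substituted) between members of one tandem cluster.
#' @param ancestor_divergence divergence of each gene from the family
#'   ancestor (controls paralog relatedness).
#' @param ref_divergence divergence of the simulated outgroup reference
#'   protein from each planted gene's source protein.
#' @param scaffold_count,scaffold_length assembly layout.
#' @param rng_seed integer seed; identical spec + seed give byte-identical
#'   output.
#' @return an object of class `family_spec`.
#' @export
family_spec <- function(family_name = "OR", n_genes = 60L,
                        intron_count_range = c(2L, 6L),
                        intron_length_range = c(60L, 500L),
                        protein_length_range = c(380L, 460L),
                        n_pseudo_stop = 6L, n_pseudo_frameshift = 4L,
                        n_partial = 5L, tandem_cluster_sizes = c(4L, 4L),
                        within_cluster_divergence = 0.05,
                        ancestor_divergence = 0.30, ref_divergence = 0.15,
                        scaffold_count = 4L, scaffold_length = 500000L,
                        rng_seed = 1L) {
  spec <- list(family_name = family_name, n_genes = as.integer(n_genes),
               intron_count_range = as.integer(intron_count_range),
               intron_length_range = as.integer(intron_length_range),
               protein_length_range = as.integer(protein_length_range),
               n_pseudo_stop = as.integer(n_pseudo_stop),
               n_pseudo_frameshift = as.integer(n_pseudo_frameshift),
               n_partial = as.integer(n_partial),
               tandem_cluster_sizes = as.integer(tandem_cluster_sizes),
               within_cluster_divergence = within_cluster_divergence,
               ancestor_divergence = ancestor_divergence,
               ref_divergence = ref_divergence,
               scaffold_count = as.integer(scaffold_count),
               scaffold_length = as.integer(scaffold_length),
               rng_seed = as.integer(rng_seed))
  with(spec, {
    stopifnot(n_genes >= 0,
              n_pseudo_stop + n_pseudo_frameshift + n_partial <= n_genes,
              length(intron_count_range) == 2, diff(intron_count_range) >= 0,
              intron_count_range[1] >= 0,
              length(intron_length_range) == 2,
              intron_length_range[1] >= 30 || intron_count_range[2] == 0,
              diff(intron_length_range) >= 0,
              length(protein_length_range) == 2,
              protein_length_range[1] >= 60,
              sum(tandem_cluster_sizes) <= n_genes,
              within_cluster_divergence >= 0, within_cluster_divergence < 1,
              scaffold_count >= 1, scaffold_length >= 1000)
  })
  structure(spec, class = "family_spec")
}

# substitute a fraction `div` of residues for a random different amino acid
mutate_protein <- function(protein, div) {
  if (div <= 0) return(protein)
  aa20 <- CR_AA[1:20]
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  k <- round(div * length(ch))
  if (k == 0) return(protein)
  pos <- sample(length(ch), k)
  for (p in pos) {
    ch[p] <- sample(setdiff(aa20, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

random_protein <- function(len) {
  paste(sample(CR_AA[1:20], len, replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  if (len <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# reverse-translate with uniformly sampled synonymous codons
protein_to_cds <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(vapply(ch, function(a) {
    cods <- by_aa[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

#' Build one gene structure from a coding sequence
#'
#' Inserts `n_introns` GT..AG introns at distinct codon boundaries of `cds`
#' and returns the genic sequence together with local exon coordinates
#' (0-based half-open, coding strand).
#'
#' @param cds in-frame coding sequence (no terminal stop required).
#' @param n_introns number of introns; 0 gives a single-exon gene.
#' @param intron_length_range intron length range in bp (>= 30).
#' @param boundaries optional explicit intron positions (bp offsets into
#'   `cds`, sorted, interior); by default introns fall at random codon
#'   boundaries (phase 0). Explicit boundaries allow disrupted (e.g.
#'   frameshifted) coding sequences whose length is not a multiple of 3.
#' @return list with `seq`, `exons` (matrix), `cds`.
#' @export
forge_gene <- function(cds, n_introns, intron_length_range = c(60L, 500L),
                       boundaries = NULL) {
  if (is.null(boundaries)) {
    ncod <- nchar(cds) %/% 3L
    stopifnot(nchar(cds) %% 3L == 0L, n_introns <= ncod - 1L)
    boundaries <- if (n_introns > 0L)
      sort(sample(ncod - 1L, n_introns)) * 3L else integer(0)
  } else {
    n_introns <- length(boundaries)
    stopifnot(all(boundaries > 0), all(boundaries < nchar(cds)),
              !is.unsorted(boundaries, strictly = TRUE))
  }
  if (n_introns == 0L) {
    return(list(seq = cds, exons = matrix(c(0L, nchar(cds)), 1L),
                cds = cds))
  }
  bounds <- as.integer(boundaries)
  ilen <- sample(seq(intron_length_range[1], intron_length_range[2]),
                 n_introns, replace = TRUE)
  introns <- vapply(ilen, function(l) paste0("GT", random_dna(l - 4L), "AG"),
                    character(1))
  pieces <- character(0)
  exons <- matrix(0L, n_introns + 1L, 2L)
  prev <- 0L; cursor <- 0L
  for (i in seq_len(n_introns)) {
    ex <- substr(cds, prev + 1L, bounds[i])
    exons[i, ] <- c(cursor, cursor + nchar(ex))
    pieces <- c(pieces, ex, introns[i])
    cursor <- cursor + nchar(ex) + ilen[i]
    prev <- bounds[i]
  }
  ex <- substr(cds, prev + 1L, nchar(cds))
  exons[n_introns + 1L, ] <- c(cursor, cursor + nchar(ex))
  pieces <- c(pieces, ex)
  list(seq = paste(pieces, collapse = ""), exons = exons, cds = cds)
}

# introduce a premature TAA stop at a random internal codon
disrupt_stop <- function(cds) {
  ncod <- nchar(cds) %/% 3L
  lo <- max(2L, round(0.1 * ncod)); hi <- min(ncod - 1L, round(0.9 * ncod))
  cod <- sample(seq(lo, hi), 1L)
  paste0(substr(cds, 1L, (cod - 1L) * 3L), "TAA",
         substr(cds, cod * 3L + 1L, nchar(cds)))
}

# delete 1 bp at a random internal position (frameshift)
disrupt_frameshift <- function(cds) {
  pos <- sample(seq(31L, nchar(cds) - 30L), 1L)
  paste0(substr(cds, 1L, pos - 1L), substr(cds, pos + 1L, nchar(cds)))
}

#' Plant gene structures on synthetic scaffolds
#'
#' Low-level placement engine used by [forge_genome()]. Genes are laid out
#' left to right with random intergenic spacing over i.i.d. uniform
#' background sequence; genes sharing a `cluster` label are placed adjacently
#' (1-8 kb apart, same strand) so each cluster spans well under 50 kb.
#'
#' @param genes list of gene structures from [forge_gene()].
#' @param meta data.frame with one row per gene: `gene_id`, `status`,
#'   `cluster` (NA for singletons).
#' @param scaffold_count,scaffold_length assembly layout.
#' @param min_spacing,max_spacing intergenic gap range in bp.
#' @return list with `genome` (named character) and `truth` rows.
#' @export
plant_genes <- function(genes, meta, scaffold_count, scaffold_length,
                        min_spacing = 5000L, max_spacing = 20000L) {
  n <- length(genes)
  scaf_names <- sprintf("scaffold_%02d", seq_len(scaffold_count))
  # order: cluster blocks stay contiguous
  ord <- order(ifelse(is.na(meta$cluster), seq_len(n) + 1000L,
                      match(meta$cluster, unique(meta$cluster))))
  pieces <- rep(list(character(0)), scaffold_count)
  cursor <- rep(0L, scaffold_count)
  sc <- 1L
  rows <- list(); exon_rows <- list()
  cluster_strand <- list()
  prev_cluster <- NA_character_
  for (g in ord) {
    glen <- nchar(genes[[g]]$seq)
    in_cluster <- !is.na(meta$cluster[g])
    same_cluster_as_prev <- in_cluster && !is.na(prev_cluster) &&
      identical(meta$cluster[g], prev_cluster)
    gap <- if (same_cluster_as_prev) sample(seq(1000L, 8000L), 1L)
           else sample(seq(min_spacing, max_spacing), 1L)
    # move to the next scaffold if this gene (plus margin) does not fit
    tries <- 0L
    while (cursor[sc] + gap + glen + 1000L > scaffold_length) {
      sc <- sc %% scaffold_count + 1L
      tries <- tries + 1L
      if (tries > scaffold_count)
        stop("family_spec exceeds scaffold capacity: cannot place gene ",
             meta$gene_id[g])
      same_cluster_as_prev <- FALSE # cluster split avoided by capacity only
    }
    strand <- if (in_cluster) {
      key <- as.character(meta$cluster[g])
      if (is.null(cluster_strand[[key]]))
        cluster_strand[[key]] <- sample(c("+", "-"), 1L)
      cluster_strand[[key]]
    } else sample(c("+", "-"), 1L)
    pieces[[sc]] <- c(pieces[[sc]], random_dna(gap))
    start0 <- cursor[sc] + gap
    gseq <- genes[[g]]$seq
    ex <- genes[[g]]$exons
    if (strand == "+") {
      gex <- cbind(start0 + ex[, 1], start0 + ex[, 2])
    } else {
      gseq <- cr_revcomp(gseq)
      gex <- cbind(start0 + glen - ex[, 2], start0 + glen - ex[, 1])
    }
    pieces[[sc]] <- c(pieces[[sc]], gseq)
    cursor[sc] <- start0 + glen
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = meta$gene_id[g], scaffold = scaf_names[sc], strand = strand,
      start0 = start0, end0 = start0 + glen, status = meta$status[g],
      stringsAsFactors = FALSE)
    exon_rows[[length(exon_rows) + 1L]] <- data.frame(
      gene_id = meta$gene_id[g], exon_rank = seq_len(nrow(gex)),
      start0 = gex[, 1], end0 = gex[, 2], stringsAsFactors = FALSE)
    prev_cluster <- meta$cluster[g]
  }
  genome <- vapply(seq_len(scaffold_count), function(s) {
    pad <- scaffold_length - cursor[s]
    paste(c(pieces[[s]], random_dna(pad)), collapse = "")
  }, character(1))
  names(genome) <- scaf_names
  list(genome = genome, genes = do.call(rbind, rows),
       exons = do.call(rbind, exon_rows))
}

#' Forge a synthetic genome with planted receptor genes
#'
#' Generates a multi-scaffold genome carrying intact, pseudogenised and
#' truncated copies of a simulated receptor family, the ground-truth
#' annotation, and a set of diverged outgroup reference proteins for use as
#' homology-search queries. Every intact gene's concatenated exons translate
#' back to its recorded protein; stop-pseudogenes carry one internal TAA;
#' frameshift pseudogenes carry a 1-bp exonic deletion; partial genes retain
#' only the 5' part of the coding sequence.
#'
#' @param spec a [family_spec()].
#' @param proteins optional character vector of `n_genes` source proteins to
#'   plant instead of simulating them - used to forge a second, orthologous
#'   genome for a sister species (speciation-then-divergence scenarios).
#' @return list of class `forged_genome` with `genome` (named character
#'   scaffolds), `truth` (class `truth_set`: `genes`, `exons` data.frames,
#'   `proteins`, `cds` named vectors) and `refs` (named character proteins).
#' @export
forge_genome <- function(spec, proteins = NULL) {
  stopifnot(inherits(spec, "family_spec"))
  with_local_seed(spec$rng_seed, {
    n <- spec$n_genes
    fam <- spec$family_name
    ids <- sprintf("%s_g%03d", fam, seq_len(n))
    cluster <- rep(NA_character_, n)
    k <- 0L
    for (ci in seq_along(spec$tandem_cluster_sizes)) {
      sz <- spec$tandem_cluster_sizes[ci]
      cluster[k + seq_len(sz)] <- sprintf("clu%02d", ci)
      k <- k + sz
    }
    if (is.null(proteins)) {
      # family ancestor and per-gene source proteins
      anc <- random_protein(max(spec$protein_length_range))
      proteins <- character(n)
      for (clu in unique(cluster[!is.na(cluster)])) {
        canc <- mutate_protein(anc, spec$ancestor_divergence)
        for (g in which(cluster == clu))
          proteins[g] <- mutate_protein(canc,
                                        spec$within_cluster_divergence)
      }
      for (g in which(is.na(cluster)))
        proteins[g] <- mutate_protein(anc, spec$ancestor_divergence)
      # trim singletons to varying lengths
      lens <- sample(seq(spec$protein_length_range[1],
                         spec$protein_length_range[2]), n, replace = TRUE)
      for (g in seq_len(n)) {
        if (is.na(cluster[g]))
          proteins[g] <- substr(proteins[g], 1L, lens[g])
      }
    } else {
      stopifnot(length(proteins) == n)
      proteins <- unname(as.character(proteins))
    }
    # disruption assignment (never inside clusters twice over capacity)
    status <- rep("intact", n)
    pool <- sample(n)
    take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }
    if (spec$n_pseudo_stop > 0) status[take(spec$n_pseudo_stop)] <- "pseudo_stop"
    if (spec$n_pseudo_frameshift > 0)
      status[take(spec$n_pseudo_frameshift)] <- "pseudo_frameshift"
    if (spec$n_partial > 0) status[take(spec$n_partial)] <- "partial"
    genes <- vector("list", n)
    cds_out <- character(n)
    for (g in seq_len(n)) {
      src <- proteins[g]
      if (status[g] == "partial") {
        keep <- round(nchar(src) * runif(1, 0.55, 0.70))
        src_used <- substr(src, 1L, keep)
      } else src_used <- src
      cds <- protein_to_cds(src_used)
      if (status[g] == "pseudo_stop") cds <- disrupt_stop(cds)
      nint <- sample(seq(spec$intron_count_range[1],
                         spec$intron_count_range[2]), 1L)
      ncod <- nchar(cds) %/% 3L
      nint <- min(nint, ncod - 1L)
      bounds <- if (nint > 0L) sort(sample(ncod - 1L, nint)) * 3L
                else integer(0)
      if (status[g] == "pseudo_frameshift") {
        # 1-bp deletion strictly inside an exon
        repeat {
          pos <- sample(seq(31L, nchar(cds) - 30L), 1L)
          if (!length(bounds) || min(abs(bounds - pos)) >= 3L) break
        }
        cds <- paste0(substr(cds, 1L, pos - 1L),
                      substr(cds, pos + 1L, nchar(cds)))
        bounds[bounds >= pos] <- bounds[bounds >= pos] - 1L
      }
      genes[[g]] <- forge_gene(cds, length(bounds),
                               spec$intron_length_range,
                               boundaries = bounds)
      cds_out[g] <- cds
    }
    meta <- data.frame(gene_id = ids, status = status, cluster = cluster,
                       stringsAsFactors = FALSE)
    planted <- plant_genes(genes, meta, spec$scaffold_count,
                           spec$scaffold_length)
    planted$genes$family <- fam
    names(proteins) <- ids
    names(cds_out) <- ids
    refs <- vapply(proteins, mutate_protein, character(1),
                   div = spec$ref_divergence)
    names(refs) <- sprintf("REF_%s", ids)
    truth <- structure(list(genes = planted$genes, exons = planted$exons,
                            proteins = proteins, cds = cds_out,
                            family = fam), class = "truth_set")
    # round-trip guarantee for intact genes
    for (g in which(status == "intact")) {
      stopifnot(identical(cr_translate_cds(cds_out[g]), proteins[[g]]))
    }
    structure(list(genome = planted$genome, truth = truth, refs = refs),
              class = "forged_genome")
  })
}

#' Forge a spliced transcript set from a truth annotation
#'
#' Emits one mature transcript (the concatenated exons, optionally end
#' truncated) per intact gene, emulating the output of a de novo
#' transcriptome assembly. `extra_genes` are proteins with no counterpart in
#' the genome; their reverse-translated transcripts emulate family members
#' expressed but missing from the assembly.
#'
#' @param truth a `truth_set` from [forge_genome()].
#' @param extra_genes named character vector of proteins absent from the
#'   genome (may be empty).
#' @param seed integer seed.
#' @param truncation integer range of bases trimmed from each transcript end.
#' @return named character vector of transcripts.
#' @export
forge_transcripts <- function(truth, extra_genes = character(0), seed = 1L,
                              truncation = c(0L, 30L)) {
  stopifnot(inherits(truth, "truth_set"), nrow(truth$genes) > 0)
  with_local_seed(seed, {
    intact <- truth$genes$gene_id[truth$genes$status == "intact"]
    trim <- function(x) {
      a <- sample(seq(truncation[1], truncation[2]), 1L)
      b <- sample(seq(truncation[1], truncation[2]), 1L)
      if (a + b >= nchar(x)) x else substr(x, a + 1L, nchar(x) - b)
    }
    tx <- vapply(truth$cds[intact], trim, character(1))
    names(tx) <- sprintf("TX_%s", intact)
    if (length(extra_genes)) {
      ex <- vapply(extra_genes, function(p) trim(protein_to_cds(p)),
                   character(1))
      names(ex) <- sprintf("TX_%s", names(extra_genes))
      tx <- c(tx, ex)
    }
    tx
  })
}
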