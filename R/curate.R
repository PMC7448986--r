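#' Classify a gene model's retention status
#'
#' A model with one or more internal stop codons or frameshift events is a
#' pseudogene (exempt from length filters, and kept). Otherwise a clean model
#' is `full` when its protein reaches `full_length_fraction` of the reference
#' length, `partial` when it reaches at least half the reference length and
#' is strictly longer than 190 amino acids, and `rejected` otherwise.
#'
#' @param model a `gene_model`.
#' @param reference_length length (aa) of the reference protein the model
#'   was built from.
#' @param config a [pipeline_config()].
#' @return the model with `status` set.
#' @export
classify_status <- function(model, reference_length,
                            config = pipeline_config()) {
  plen <- nchar(model$protein)
  model$status <-
    if (model$internal_stop_count >= 1 || model$frameshift_events >= 1)
      "pseudogene"
    else if (plen >= config$full_length_fraction * reference_length) "full"
    else if (plen >= max(config$half_length_fraction * reference_length,
                         config$min_partial_aa + 1)) "partial"
    else "rejected"
  model
}

#' Assign a protein to a receptor family by best local-alignment hit
#'
#' Scores the protein against every labelled reference set (including decoy
#' non-chemosensory proteins) by Smith-Waterman bit score and returns the
#' best-scoring family label. The call is `"inconsistent"` (and the gene is
#' removed downstream) when the best hit is a decoy or when the best family
#' beats the runner-up family by fewer than `margin_bits` bits.
#'
#' @param protein amino-acid sequence (X tolerated).
#' @param family_db named list of named character vectors, one per family
#'   label; labels in `decoy_labels` count as decoys.
#' @param margin_bits minimum bit-score margin over the runner-up family.
#' @param decoy_labels family labels treated as decoys.
#' @param scoring a [scoring_scheme()].
#' @return a family label or `"inconsistent"`.
#' @export
assign_family <- function(protein, family_db, margin_bits = 5,
                          decoy_labels = "decoy",
                          scoring = scoring_scheme()) {
  if (!length(family_db)) stop("empty family reference database")
  penc <- cr_encode_aa(protein)
  bits <- vapply(family_db, function(refs) {
    best <- max(vapply(refs, function(r)
      .cpp_sw_pair(penc, cr_encode_aa(r), scoring$matrix, scoring$gap_open,
                   scoring$gap_extend)$score, numeric(1)))
    (scoring$lambda * best - log(scoring$K)) / log(2)
  }, numeric(1))
  ord <- order(bits, decreasing = TRUE)
  best <- names(bits)[ord[1]]
  if (best %in% decoy_labels) return("inconsistent")
  if (length(bits) > 1 && bits[ord[1]] - bits[ord[2]] < margin_bits)
    return("inconsistent")
  best
}

# one identification round: search -> chain -> flank -> model -> classify
annotate_round <- function(tg, genome, search_queries, model_refs, config,
                           hsps_cache = NULL) {
  scoring <- config$scoring
  new_q <- if (is.null(hsps_cache)) search_queries
           else search_queries[!names(search_queries) %in%
                               unique(hsps_cache$query_id)]
  hsps <- if (length(new_q))
    search_all(new_q, tg, scoring, config$evalue_cutoff) else empty_hsps()
  if (!is.null(hsps_cache)) hsps <- rbind(hsps_cache, hsps)
  loci <- chain_hits(hsps, config$max_intron, config$max_locus_span)
  loci <- lapply(loci, function(l)
    add_flanks(l, nchar(genome[[l$scaffold_id]]), config$flank_bp))
  list(hsps = hsps, loci = loci)
}

# sub-locus built from a subset of a locus's HSPs (locus fission)
sublocus <- function(l, h, suffix, genome, config) {
  scores <- tapply(h$bit_score, h$query_id, sum)
  depth <- if (is.null(l$fission_depth)) 0L else l$fission_depth
  sl <- structure(list(
    locus_id = paste0(l$locus_id, suffix), scaffold_id = l$scaffold_id,
    strand = l$strand, core_start0 = min(h$sstart0),
    core_end0 = max(h$send0), flank_start0 = min(h$sstart0),
    flank_end0 = max(h$send0), hsps = h,
    best_query = names(scores)[which.max(scores)],
    query_scores = sort(unlist(as.list(scores)), decreasing = TRUE),
    fission_depth = depth + 1L),
    class = "candidate_locus")
  add_flanks(sl, nchar(genome[[l$scaffold_id]]), config$flank_bp)
}

# a remainder worth modelling: substantial homology over a gene-sized span
fission_worthy <- function(h, n_parent) {
  nrow(h) > 0 && nrow(h) < n_parent && sum(h$bit_score) >= 100 &&
    (max(h$send0) - min(h$sstart0)) >= 300
}

build_models <- function(loci, model_refs, genome, config,
                         external_ref_ids = names(model_refs)) {
  models <- list()
  queue <- loci
  while (length(queue)) {
    l <- queue[[1]]; queue <- queue[-1]
    m <- select_best_model(l, model_refs, genome, config$top_n_references,
                           config$spliced)
    if (is.null(m)) next
    # a weak cross-paralog chain can fuse two adjacent genes into one
    # locus; after the best model claims its span, HSPs lying entirely
    # outside it are re-queued as their own loci so the neighbor is not
    # silently dropped
    span <- range(m$exons)
    depth <- if (is.null(l$fission_depth)) 0L else l$fission_depth
    if (depth < 2L) {
      left <- l$hsps[l$hsps$send0 <= span[1], , drop = FALSE]
      right <- l$hsps[l$hsps$sstart0 >= span[2], , drop = FALSE]
      if (fission_worthy(left, nrow(l$hsps)))
        queue <- c(queue, list(sublocus(l, left, "L", genome, config)))
      if (fission_worthy(right, nrow(l$hsps)))
        queue <- c(queue, list(sublocus(l, right, "R", genome, config)))
    }
    # length filters are relative to the external (cross-species) reference;
    # round-1 proteins serve as queries but not as the length yardstick
    ext <- intersect(names(l$query_scores), external_ref_ids)
    ref_len <- if (length(ext)) nchar(model_refs[[ext[1]]])
               else nchar(model_refs[[m$reference_id]])
    m <- classify_status(m, ref_len, config)
    if (m$status == "rejected") next
    models[[length(models) + 1L]] <- m
  }
  # fission sub-loci regain 2-kb flanks and can re-model an already
  # captured gene; keep the best-scoring model of any overlapping set
  if (length(models) > 1) {
    ord <- order(-vapply(models, `[[`, numeric(1), "model_score"))
    kept <- list()
    for (i in ord) {
      m <- models[[i]]
      span <- range(m$exons)
      dup <- any(vapply(kept, function(k) {
        if (k$scaffold_id != m$scaffold_id || k$strand != m$strand)
          return(FALSE)
        ks <- range(k$exons)
        ov <- max(0, min(span[2], ks[2]) - max(span[1], ks[1]))
        ov > 0.5 * min(span[2] - span[1], ks[2] - ks[1])
      }, logical(1)))
      if (!dup) kept[[length(kept) + 1L]] <- m
    }
    ord2 <- order(vapply(kept, `[[`, character(1), "scaffold_id"),
                  vapply(kept, function(k) min(k$exons), numeric(1)))
    models <- kept[ord2]
  }
  models
}

#' Two-round iterative identification of a receptor family
#'
#' Round 1 searches the external reference proteins against the genome,
#' chains the hits into candidate loci with 2-kb flanks, builds one best
#' spliced gene model per locus, and applies the retention and pseudogene
#' rules. In round 2 the retained round-1 proteins are added to the query
#' set, new loci are merged with the round-1 loci, and all models are rebuilt
#' and re-classified; candidates with inconsistent family annotation are then
#' removed.
#'
#' @param genome named character vector of scaffolds.
#' @param refs named character vector of family reference proteins (the
#'   search queries).
#' @param config a [pipeline_config()].
#' @param family_db optional labelled reference database (see
#'   [assign_family()]); when given, models whose family call is
#'   `"inconsistent"` are removed and the others carry their family label.
#' @param family family label of `refs` (annotated on the result).
#' @param species species label.
#' @return an `annotation_set`: `species`, `family`, `models` (list of
#'   `gene_model`), `counts`, plus the per-round locus lists.
#' @export
run_two_round <- function(genome, refs, config = pipeline_config(),
                          family_db = NULL, family = "OR",
                          species = "species") {
  if (methods::is(genome, "XStringSet")) genome <- as.character(genome)
  tg <- translate_genome(genome)
  r1 <- annotate_round(tg, genome, refs, refs, config)
  models1 <- build_models(r1$loci, refs, genome, config)
  round1_proteins <- vapply(models1, `[[`, character(1), "protein")
  if (length(round1_proteins))
    names(round1_proteins) <- paste0("R1_", vapply(models1, `[[`,
                                                   character(1), "gene_id"))
  queries2 <- c(refs, round1_proteins)
  r2 <- annotate_round(tg, genome, queries2, queries2, config,
                       hsps_cache = r1$hsps)
  merged <- merge_rounds(r1$loci, r2$loci)
  merged <- lapply(merged, function(l)
    add_flanks(l, nchar(genome[[l$scaffold_id]]), config$flank_bp))
  models <- build_models(merged, queries2, genome, config,
                         external_ref_ids = names(refs))
  if (!is.null(family_db) && length(models)) {
    fam <- vapply(models, function(m)
      assign_family(m$protein, family_db, config$family_margin_bits,
                    config$decoy_labels, config$scoring), character(1))
    keep <- fam != "inconsistent"
    models <- models[keep]
    for (i in seq_along(models)) models[[i]]$family <- fam[keep][i]
  } else {
    for (i in seq_along(models)) models[[i]]$family <- family
  }
  annotation_set(models, species = species, family = family,
                 round1_models = models1, loci = merged)
}

#' Bundle gene models into an annotation set
#'
#' @param models list of classified `gene_model`s.
#' @param species,family labels.
#' @param round1_models,loci optional provenance kept for reporting.
#' @return list of class `annotation_set` with a `counts` vector
#'   (total, full_length, partial, pseudogene).
#' @export
annotation_set <- function(models, species = "species", family = "OR",
                           round1_models = NULL, loci = NULL) {
  status <- vapply(models, `[[`, character(1), "status")
  ids <- vapply(models, `[[`, character(1), "gene_id")
  stopifnot(!anyDuplicated(ids))
  counts <- c(total = length(models),
              full_length = sum(status == "full"),
              partial = sum(status == "partial"),
              pseudogene = sum(status == "pseudogene"))
  structure(list(species = species, family = family, models = models,
                 counts = counts, round1_models = round1_models,
                 loci = loci), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %s %s - %d genes (%d full, %d partial, %d pseudo)\n",
              x$species, x$family, x$counts["total"], x$counts["full_length"],
              x$counts["partial"], x$counts["pseudogene"]))
  invisible(x)
}

#' Transcript-based completeness check of an annotation
#'
#' A transcript is a family candidate iff its best translated alignment to a
#' family reference protein spans at least the family threshold (120 aa for
#' ORs and GRs, 190 aa for IRs). A candidate counts as found in the
#' annotation iff it aligns to some annotated protein of the family at >=
#' `min_identity` over at least the threshold span; the remainder are
#' missing - either unannotated or absent from the genome.
#'
#' @param transcripts named character vector of assembled transcripts
#'   (nucleotide).
#' @param family_refs named character vector of family reference proteins.
#' @param annotation an `annotation_set`.
#' @param threshold_aa minimum homologous region (aa); defaults to the family
#'   value from `config`.
#' @param config a [pipeline_config()].
#' @return list of class `completeness_report`: `family`,
#'   `transcripts_total`, `transcripts_found_in_annotation`,
#'   `transcripts_missing`, `min_homology_aa`, and the per-transcript table.
#' @export
completeness_check <- function(transcripts, family_refs, annotation,
                               threshold_aa = NULL,
                               config = pipeline_config()) {
  fam <- annotation$family
  thr <- if (!is.null(threshold_aa)) threshold_aa
         else config$completeness_aa[[fam]]
  scoring <- config$scoring
  ann_prot <- vapply(annotation$models, `[[`, character(1), "protein")
  rows <- lapply(names(transcripts), function(txid) {
    frames <- six_frame_translate(transcripts[[txid]])
    encs <- lapply(frames, function(f) cr_encode_aa(f$protein))
    best_span <- 0L
    for (e in encs) {
      if (length(e) < 10) next
      for (r in family_refs) {
        hit <- .cpp_sw_pair(e, cr_encode_aa(r), scoring$matrix,
                            scoring$gap_open, scoring$gap_extend)
        if (hit$length > best_span) best_span <- hit$length
      }
    }
    found <- FALSE
    if (best_span >= thr && length(ann_prot)) {
      for (e in encs) {
        if (found || length(e) < 10) next
        for (p in ann_prot) {
          hit <- .cpp_sw_pair(e, cr_encode_aa(p), scoring$matrix,
                              scoring$gap_open, scoring$gap_extend)
          if (hit$length >= thr &&
              hit$nident / hit$length >= config$completeness_identity) {
            found <- TRUE; break
          }
        }
      }
    }
    data.frame(transcript = txid, homology_span = best_span,
               candidate = best_span >= thr, found = found,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  cand <- tab[tab$candidate, , drop = FALSE]
  structure(list(family = fam, transcripts_total = nrow(cand),
                 transcripts_found_in_annotation = sum(cand$found),
                 transcripts_missing = sum(!cand$found),
                 min_homology_aa = thr, table = tab),
            class = "completeness_report")
}
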