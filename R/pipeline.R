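#' Run the full annotation + selection pipeline
#'
#' Executes the stages in protocol order for one or two species: two-round
#' homology identification per genome, optional transcript completeness
#' check, and - with two species - a bootstrapped family tree over all
#' retained proteins (references included as outgroup leaves), 1:1
#' orthologue-pair extraction, and the pairwise M7-vs-M8 positive-selection
#' test per pair. All stage outputs are written to `outdir` when given.
#'
#' @param config a [pipeline_config()].
#' @param genomes named list: species -> named character vector of
#'   scaffolds (one or two species).
#' @param refs named character vector of family reference proteins.
#' @param family family label of `refs`.
#' @param transcripts optional named list: species -> named character
#'   vector of assembled transcripts.
#' @param family_db optional labelled protein database for the
#'   family-consistency filter (see [assign_family()]).
#' @param outgroup ids within `refs` used to root the tree; defaults to all
#'   reference ids.
#' @param outdir optional run directory.
#' @return list of class `pipeline_result`: `annotations`, `completeness`,
#'   `tree`, `pairs`, `selection`, `config`.
#' @export
run_pipeline <- function(config, genomes, refs, family = "OR",
                         transcripts = NULL, family_db = NULL,
                         outgroup = NULL, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"), length(genomes) >= 1,
            !is.null(names(genomes)))
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE,
                                   recursive = TRUE)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  annotations <- list()
  for (sp in names(genomes)) {
    log_stage("annotate", "species=%s scaffolds=%d", sp,
              length(genomes[[sp]]))
    ann <- run_two_round(genomes[[sp]], refs, config, family_db, family, sp)
    log_stage("annotate", "species=%s genes=%d (full=%d partial=%d pseudo=%d)",
              sp, ann$counts["total"], ann$counts["full_length"],
              ann$counts["partial"], ann$counts["pseudogene"])
    annotations[[sp]] <- ann
    if (!is.null(outdir)) {
      write_gff3(ann, file.path(outdir, paste0(sp, ".gff3")))
      write_fasta(annotation_sequences(ann, "protein"),
                  file.path(outdir, paste0(sp, ".proteins.fa")))
      write_fasta(annotation_sequences(ann, "cds"),
                  file.path(outdir, paste0(sp, ".cds.fa")))
    }
  }
  if (!is.null(outdir))
    write_counts_tsv(annotations, file.path(outdir, "counts.tsv"))
  completeness <- NULL
  if (!is.null(transcripts)) {
    completeness <- lapply(intersect(names(transcripts), names(genomes)),
                           function(sp) {
      rep <- completeness_check(transcripts[[sp]], refs, annotations[[sp]],
                                config = config)
      log_stage("completeness", "species=%s total=%d found=%d missing=%d",
                sp, rep$transcripts_total,
                rep$transcripts_found_in_annotation,
                rep$transcripts_missing)
      rep
    })
    names(completeness) <- intersect(names(transcripts), names(genomes))
    if (!is.null(outdir)) {
      tab <- do.call(rbind, lapply(names(completeness), function(sp)
        data.frame(species = sp, family = completeness[[sp]]$family,
                   found_in_genome =
                     completeness[[sp]]$transcripts_found_in_annotation,
                   total_by_rnaseq = completeness[[sp]]$transcripts_total)))
      write.table(tab, file.path(outdir, "completeness.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  } else {
    log_stage("completeness", "no transcripts supplied; stage skipped")
  }
  tree <- NULL; pairs <- NULL; selection <- NULL
  if (length(genomes) >= 2) {
    sp2 <- names(genomes)[1:2]
    prots <- list(); cdss <- list(); species_map <- character(0)
    for (sp in sp2) {
      p <- annotation_sequences(annotations[[sp]], "protein")
      p <- filter_for_tree(p, family, config)
      if (length(p)) names(p) <- paste(sp, names(p), sep = "__")
      prots[[sp]] <- p
      cc <- annotation_sequences(annotations[[sp]], "cds")
      names(cc) <- paste(sp, names(cc), sep = "__")
      cdss[[sp]] <- cc
      species_map <- c(species_map,
                       setNames(rep(sp, length(p)), names(p)))
    }
    og <- if (is.null(outgroup)) names(refs) else outgroup
    leaves <- c(prots[[1]], prots[[2]], refs[og])
    species_map <- c(species_map, setNames(rep("outgroup", length(og)), og))
    if (length(leaves) >= 4) {
      log_stage("tree", "family=%s leaves=%d bootstraps=%d", family,
                length(leaves), config$n_bootstrap)
      msa <- build_msa(leaves)
      tree <- build_tree(msa, family, config$n_bootstrap, config$rng_seed,
                         outgroup = og)
      pairs <- find_ortholog_pairs(tree, species_map, focal_species = sp2)
      log_stage("pairs", "orthologue pairs=%d", nrow(pairs))
      if (!is.null(outdir)) {
        write_fasta(unclass(msa), file.path(outdir,
                                            paste0(family, ".aln.fa")))
        ape::write.tree(tree, file.path(outdir, paste0(family, ".nwk")))
        write.table(pairs, file.path(outdir, "ortholog_pairs.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      all_cds <- c(cdss[[1]], cdss[[2]])
      selection <- list()
      for (i in seq_len(nrow(pairs))) {
        ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
        pid <- paste(ga, gb, sep = ":")
        pmsa <- build_msa(c(leaves[ga], leaves[gb]))
        aln <- tryCatch(
          suppressWarnings(codon_align(pmsa, all_cds[[ga]], all_cds[[gb]])),
          error = function(e) NULL)
        if (is.null(aln) || aln$n_codons < 30) {
          log_stage("select", "pair=%s skipped (unalignable or too short)",
                    pid)
          next
        }
        res <- selection_test(aln, pid, config)
        log_stage("select", "pair=%s p=%.4g selected=%s", pid, res$p_value,
                  res$positively_selected)
        selection[[pid]] <- res
      }
      if (!is.null(outdir) && length(selection))
        write_selection_tsv(selection, file.path(outdir, "selection.tsv"))
    } else {
      log_stage("tree", "fewer than 4 sequences; tree stage skipped")
    }
  }
  if (!is.null(outdir)) {
    manifest <- list(package = "chemrec",
                     version = as.character(utils::packageVersion("chemrec")),
                     family = family, species = names(genomes),
                     config = config[!vapply(config, is.function,
                                             logical(1))])
    manifest$config$scoring <- manifest$config$scoring[
      c("gap_open", "gap_extend", "K", "lambda")]
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(annotations = annotations, completeness = completeness,
                 tree = tree, pairs = pairs, selection = selection,
                 config = config), class = "pipeline_result")
}

# total exon overlap (bp) between two exon interval matrices
exon_overlap <- function(ex_a, ex_b) {
  tot <- 0
  for (i in seq_len(nrow(ex_a))) for (j in seq_len(nrow(ex_b))) {
    tot <- tot + max(0, min(ex_a[i, 2], ex_b[j, 2]) -
                       max(ex_a[i, 1], ex_b[j, 1]))
  }
  tot
}

#' Evaluate pipeline output against the forged truth
#'
#' A model matches a truth gene when they share scaffold and strand and
#' their exon sets overlap reciprocally by at least 50% of each side's
#' total exon length. Reports intact-gene sensitivity, model precision,
#' the status confusion table, and pseudogene status accuracy.
#'
#' @param annotation an `annotation_set`.
#' @param truth a `truth_set` from [forge_genome()].
#' @return list of class `evaluation_report`.
#' @export
evaluate_against_truth <- function(annotation, truth) {
  stopifnot(inherits(annotation, "annotation_set"),
            inherits(truth, "truth_set"))
  models <- annotation$models
  tg <- truth$genes
  match_of_model <- rep(NA_character_, length(models))
  status_model <- vapply(models, `[[`, character(1), "status")
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    mex <- m$exons
    mlen <- sum(mex[, 2] - mex[, 1])
    cand <- which(tg$scaffold == m$scaffold_id & tg$strand == m$strand)
    for (ti in cand) {
      tex <- as.matrix(truth$exons[truth$exons$gene_id == tg$gene_id[ti],
                                   c("start0", "end0")])
      ov <- exon_overlap(mex, tex)
      tlen <- sum(tex[, 2] - tex[, 1])
      if (ov >= 0.5 * mlen && ov >= 0.5 * tlen) {
        match_of_model[mi] <- tg$gene_id[ti]
        break
      }
    }
  }
  matched_truth <- unique(match_of_model[!is.na(match_of_model)])
  intact_ids <- tg$gene_id[tg$status == "intact"]
  pseudo_ids <- tg$gene_id[tg$status %in% c("pseudo_stop",
                                            "pseudo_frameshift")]
  sensitivity <- if (length(intact_ids))
    mean(intact_ids %in% matched_truth) else NA_real_
  precision <- if (length(models))
    mean(!is.na(match_of_model)) else NA_real_
  # status agreement on matched models
  truth_status <- tg$status[match(match_of_model, tg$gene_id)]
  conf <- table(truth = truth_status, model = status_model,
                useNA = "no")
  matched_pseudo <- which(!is.na(match_of_model) &
                            match_of_model %in% pseudo_ids)
  matched_intact <- which(!is.na(match_of_model) &
                            match_of_model %in% intact_ids)
  pseudo_calls_ok <- c(status_model[matched_pseudo] == "pseudogene",
                       status_model[matched_intact] != "pseudogene")
  pseudo_accuracy <- if (length(pseudo_calls_ok))
    mean(pseudo_calls_ok) else NA_real_
  structure(list(sensitivity = sensitivity, precision = precision,
                 status_confusion = conf,
                 pseudogene_accuracy = pseudo_accuracy,
                 matched = data.frame(
                   gene_id = vapply(models, `[[`, character(1), "gene_id"),
                   truth_gene = match_of_model, model_status = status_model,
                   stringsAsFactors = FALSE)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation: sensitivity=%.3f precision=%.3f pseudogene_accuracy=%.3f\n",
              x$sensitivity, x$precision, x$pseudogene_accuracy))
  print(x$status_confusion)
  invisible(x)
}
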