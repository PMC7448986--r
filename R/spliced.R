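#' Spliced alignment of a reference protein to locus DNA
#'
#' Builds a gene model by dynamic programming over codon matches (BLOSUM62 on
#' the translated codon), affine codon insertions/deletions, single-base
#' frameshifts (heavy penalty, emitted as X and counted), introns (flat
#' penalty, allowed only between codons at GT..AG donor/acceptor sites of at
#' least `min_intron` bp), and stop codons (fixed negative score, translated
#' X and counted as internal stops). The highest-scoring local path defines
#' the exon structure, CDS and model protein.
#'
#' @param reference reference protein (>= 50 aa).
#' @param locus_dna locus nucleotide sequence, already on the coding strand.
#' @param params list of scoring parameters; see [spliced_params()].
#' @return list of class `gene_model_raw`: `score`, `exons` (0-based
#'   half-open intervals in `locus_dna`, coding order), `cds`, `protein` (X
#'   at stop and frameshift positions), `frameshift_events`,
#'   `internal_stop_count`, `qstart`/`qend` (reference coverage), `aligned`.
#' @export
spliced_align <- function(reference, locus_dna, params = spliced_params()) {
  stopifnot(nchar(reference) >= 50)
  penc <- cr_encode_aa(reference)
  denc <- cr_encode_dna(locus_dna)
  r <- .cpp_spliced_align(penc, denc, cr_submat(), cr_codon2aa(),
                          params$gap_open, params$gap_extend,
                          params$frameshift_penalty, params$intron_penalty,
                          params$stop_score, params$min_intron,
                          CR_AA_STOP, CR_AA_X)
  if (!r$aligned) {
    return(structure(list(score = 0, exons = matrix(integer(0), 0, 2),
                          cds = "", protein = "", frameshift_events = 0L,
                          internal_stop_count = 0L, qstart = NA_integer_,
                          qend = NA_integer_, aligned = FALSE),
                     class = "gene_model_raw"))
  }
  ex <- r$exons[r$exons[, 2] > r$exons[, 1], , drop = FALSE]
  prot <- r$protein
  qs <- r$qstart; qe <- r$qend; score <- r$score
  # Bounded end completion: a local alignment drops a terminal codon whose
  # substituted residue scores negative. While unaligned reference residues
  # remain, extend each end by up to 2 in-frame, non-stop codons.
  sub <- cr_submat(); c2a <- cr_codon2aa()
  k <- 0L
  while (k < 2L && qe < length(penc) && ex[nrow(ex), 2] + 3L <= length(denc)) {
    cod <- denc[(ex[nrow(ex), 2] + 1L):(ex[nrow(ex), 2] + 3L)]
    if (any(cod == 4L)) break
    aa <- c2a[cod[1] * 25L + cod[2] * 5L + cod[3] + 1L]
    if (aa == CR_AA_STOP) break
    score <- score + sub[aa + 1L, penc[qe + 1L] + 1L]
    prot <- c(prot, aa)
    ex[nrow(ex), 2] <- ex[nrow(ex), 2] + 3L
    qe <- qe + 1L; k <- k + 1L
  }
  k <- 0L
  while (k < 2L && qs > 1L && ex[1, 1] - 3L >= 0L) {
    cod <- denc[(ex[1, 1] - 2L):ex[1, 1]]
    if (any(cod == 4L)) break
    aa <- c2a[cod[1] * 25L + cod[2] * 5L + cod[3] + 1L]
    if (aa == CR_AA_STOP) break
    score <- score + sub[aa + 1L, penc[qs - 1L] + 1L]
    prot <- c(aa, prot)
    ex[1, 1] <- ex[1, 1] - 3L
    qs <- qs - 1L; k <- k + 1L
  }
  cds <- paste(substring(locus_dna, ex[, 1] + 1L, ex[, 2]), collapse = "")
  structure(list(score = score, exons = ex, cds = cds,
                 protein = cr_decode_aa(prot),
                 frameshift_events = r$frameshift_events,
                 internal_stop_count = r$internal_stops,
                 qstart = qs, qend = qe, aligned = TRUE),
            class = "gene_model_raw")
}

#' Scoring parameters for the spliced aligner
#'
#' Defaults: frameshift -20 (one frameshift outweighs any single mismatch but
#' does not reject a model), intron -10 (flat, per intron), stop -15,
#' BLAST-convention codon gap penalties, and a 30-bp minimum intron.
#'
#' @param gap_open,gap_extend affine penalties per codon gap.
#' @param frameshift_penalty score of a 2-bp or 4-bp frameshift step.
#' @param intron_penalty flat score of one GT..AG intron.
#' @param stop_score score of aligning a stop codon (translated as X).
#' @param min_intron minimum intron length in bp.
#' @export
spliced_params <- function(gap_open = -11, gap_extend = -1,
                           frameshift_penalty = -20, intron_penalty = -10,
                           stop_score = -15, min_intron = 30L) {
  list(gap_open = gap_open, gap_extend = gap_extend,
       frameshift_penalty = frameshift_penalty,
       intron_penalty = intron_penalty, stop_score = stop_score,
       min_intron = as.integer(min_intron))
}

#' Select the best gene model for a candidate locus
#'
#' Runs the spliced aligner for the `top_n` references with the highest
#' summed HSP bit score against the locus, and keeps the single model with
#' the maximal score. Ties are broken by fewer frameshifts, fewer internal
#' stops, longer protein, then lexicographically smaller reference id.
#'
#' @param locus a `candidate_locus` with flanks attached.
#' @param references named character vector of reference proteins (must
#'   cover the locus query ids).
#' @param genome named character vector of scaffolds.
#' @param top_n number of candidate references to try.
#' @param params [spliced_params()].
#' @return a `gene_model` (genomic coordinates, see fields) or `NULL` if all
#'   candidates fail to align.
#' @export
select_best_model <- function(locus, references, genome, top_n = 5L,
                              params = spliced_params()) {
  stopifnot(inherits(locus, "candidate_locus"))
  dna_f <- substr(genome[[locus$scaffold_id]], locus$flank_start0 + 1L,
                  locus$flank_end0)
  dna <- if (locus$strand == "+") dna_f else cr_revcomp(dna_f)
  cand <- names(locus$query_scores)
  cand <- cand[cand %in% names(references)]
  # references far below the top summed bit score cannot win the model
  # contest in practice; skip them to bound runtime
  if (length(cand) > 1) {
    sc <- locus$query_scores[cand]
    cand <- cand[sc >= 0.5 * sc[1]]
  }
  cand <- head(cand, top_n)
  if (!length(cand)) return(NULL)
  fits <- lapply(cand, function(q)
    spliced_align(references[[q]], dna, params))
  ok <- vapply(fits, `[[`, logical(1), "aligned")
  if (!any(ok)) return(NULL)
  fits <- fits[ok]; cand <- cand[ok]
  key <- order(-vapply(fits, `[[`, numeric(1), "score"),
               vapply(fits, `[[`, integer(1), "frameshift_events"),
               vapply(fits, `[[`, integer(1), "internal_stop_count"),
               -vapply(fits, function(f) nchar(f$protein), integer(1)),
               cand)
  best <- fits[[key[1]]]
  ref_id <- cand[key[1]]
  # map coding-strand local exon coordinates to forward-strand genomic ones
  L <- nchar(dna)
  ex <- best$exons
  gex <- if (locus$strand == "+") {
    cbind(locus$flank_start0 + ex[, 1], locus$flank_start0 + ex[, 2])
  } else {
    cbind(locus$flank_start0 + L - ex[, 2], locus$flank_start0 + L - ex[, 1])
  }
  structure(list(
    gene_id = sub("^LOC", "GENE", locus$locus_id),
    locus_id = locus$locus_id, scaffold_id = locus$scaffold_id,
    strand = locus$strand, exons = gex, cds = best$cds,
    protein = best$protein, model_score = best$score,
    frameshift_events = best$frameshift_events,
    internal_stop_count = best$internal_stop_count,
    reference_id = ref_id, family = NA_character_,
    status = "unclassified"), class = "gene_model")
}
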