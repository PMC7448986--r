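#' Scoring scheme for the translated search
#'
#' BLOSUM62 with BLAST-convention affine gap penalties and fixed ungapped
#' Karlin-Altschul parameters. E-values are computed as
#' `K * m * n * exp(-lambda * S)` with `m` the query length and `n` the total
#' translated search-space length; because `K` and `lambda` are the standard
#' ungapped BLOSUM62 constants rather than estimated per search, absolute
#' e-values differ from NCBI tBLASTn, but the semantics of an e-value cutoff
#' are preserved. Stops in translated frames score -4 (mismatch floor) so
#' pseudogene exons can still seed hits.
#'
#' @param gap_open,gap_extend negative gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param K,lambda Karlin-Altschul parameters (ungapped BLOSUM62 defaults).
#' @return list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(gap_open = -11, gap_extend = -1,
                           K = 0.134, lambda = 0.3176) {
  stopifnot(gap_open < 0, gap_extend < 0, K > 0, lambda > 0)
  structure(list(matrix = cr_submat(), gap_open = gap_open,
                 gap_extend = gap_extend, K = K, lambda = lambda),
            class = "scoring_scheme")
}

#' Six-frame translation with coordinate maps
#'
#' Translates a nucleotide sequence in all six reading frames. Frames +1..+3
#' start at offsets 0..2 of the forward strand; -1..-3 at offsets 0..2 of the
#' reverse complement. Codons containing N translate to X; stop codons are
#' retained as `*`.
#'
#' @param dna a nucleotide string over A,C,G,T,N.
#' @return list of six entries, each with `frame`, `protein`, and `offset`
#'   (the strand-local bp offset); use [aa_to_genomic()] to map an amino-acid
#'   position to its forward-strand bp triple.
#' @export
six_frame_translate <- function(dna) {
  L <- nchar(dna)
  rc <- if (L > 0) cr_revcomp(dna) else ""
  one <- function(seqstr, frame, off) {
    if (nchar(seqstr) - off < 3)
      return(list(frame = frame, protein = "", offset = off))
    p <- cr_translate_cds(substr(seqstr, off + 1L, nchar(seqstr)))
    list(frame = frame, protein = p, offset = off)
  }
  out <- list(one(dna, 1L, 0L), one(dna, 2L, 1L), one(dna, 3L, 2L),
              one(rc, -1L, 0L), one(rc, -2L, 1L), one(rc, -3L, 2L))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  attr(out, "dna_length") <- L
  out
}

#' Map a translated amino-acid interval to forward-strand genomic coordinates
#'
#' @param frame frame in -3..-1, 1..3.
#' @param aa_start,aa_end 0-based half-open amino-acid interval in the frame
#'   translation.
#' @param dna_length length of the source sequence in bp.
#' @return integer `c(start0, end0)`: 0-based half-open forward-strand bp.
#' @export
aa_to_genomic <- function(frame, aa_start, aa_end, dna_length) {
  off <- abs(frame) - 1L
  s <- off + 3L * aa_start
  e <- off + 3L * aa_end
  if (frame > 0) c(s, e) else c(dna_length - e, dna_length - s)
}

#' Pre-translate a genome for repeated searches
#'
#' @param genome named character vector of scaffold sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @return list of class `translated_genome` caching all six encoded frame
#'   translations per scaffold plus the total search-space length.
#' @export
translate_genome <- function(genome) {
  if (methods::is(genome, "XStringSet")) genome <- as.character(genome)
  stopifnot(is.character(genome), !is.null(names(genome)))
  frames <- lapply(genome, function(s) {
    tr <- six_frame_translate(s)
    lapply(tr, function(f) {
      list(frame = f$frame, enc = cr_encode_aa(f$protein),
           offset = f$offset)
    })
  })
  n_space <- sum(vapply(frames, function(sc)
    sum(vapply(sc, function(f) length(f$enc), integer(1))), numeric(1)))
  structure(list(frames = frames,
                 scaffold_length = vapply(genome, nchar, integer(1)),
                 search_space = n_space),
            class = "translated_genome")
}

#' Translated homology search of a protein query against a genome
#'
#' Searches the query against all six translated frames of every scaffold
#' with local Smith-Waterman alignment (exhaustive dynamic programming on
#' small frames; exact 4-mer seeded windows on scaffold-scale frames, with
#' reported scores always equal to the full DP score of the reported region).
#' Only hits at or below the e-value cutoff are returned.
#'
#' @param query named length-1 character vector, or plain string, of >= 10
#'   amino acids.
#' @param genome named character vector of scaffolds, or a
#'   [translate_genome()] result for repeated searches.
#' @param scoring a [scoring_scheme()].
#' @param evalue_cutoff maximum e-value of a reported HSP.
#' @param max_hsps_per_frame cap on HSPs extracted per scaffold frame.
#' @return data.frame of HSPs sorted by (scaffold, subject start):
#'   `query_id`, `scaffold_id`, `frame`, `strand`, `qstart`, `qend` (1-based
#'   inclusive, amino acids), `sstart0`, `send0` (0-based half-open
#'   forward-strand bp), `raw_score`, `bit_score`, `evalue`, `pident`,
#'   `length`.
#' @export
search <- function(query, genome, scoring = scoring_scheme(),
                   evalue_cutoff = 1e-5, max_hsps_per_frame = 25L) {
  qid <- if (!is.null(names(query))) names(query)[1] else "query"
  qstr <- unname(query[1])
  if (nchar(qstr) < 10) stop("query must be at least 10 amino acids")
  qenc <- cr_encode_aa(qstr, strict = TRUE)
  tg <- if (inherits(genome, "translated_genome")) genome
        else translate_genome(genome)
  m <- length(qenc)
  n <- tg$search_space
  lam <- scoring$lambda; K <- scoring$K
  min_score <- if (is.finite(evalue_cutoff))
    (log(K * m * n) - log(evalue_cutoff)) / lam else 1
  min_score <- max(min_score, 1)
  res <- list()
  for (scaf in names(tg$frames)) {
    L <- tg$scaffold_length[[scaf]]
    for (f in tg$frames[[scaf]]) {
      if (length(f$enc) == 0) next
      hs <- .cpp_sw_hsps(qenc, f$enc, scoring$matrix, scoring$gap_open,
                         scoring$gap_extend, min_score, max_hsps_per_frame,
                         4e6, 4L, 50L, 80L)
      if (nrow(hs) == 0) next
      ev <- K * m * n * exp(-lam * hs$raw_score)
      keep <- ev <= evalue_cutoff
      if (!any(keep)) next
      hs <- hs[keep, , drop = FALSE]; ev <- ev[keep]
      g <- t(vapply(seq_len(nrow(hs)), function(i)
        aa_to_genomic(f$frame, hs$sstart0[i], hs$send0[i], L),
        integer(2)))
      res[[length(res) + 1L]] <- data.frame(
        query_id = qid, scaffold_id = scaf, frame = f$frame,
        strand = ifelse(f$frame > 0, "+", "-"),
        qstart = hs$qstart0 + 1L, qend = hs$qend0,
        sstart0 = g[, 1], send0 = g[, 2],
        raw_score = hs$raw_score,
        bit_score = (lam * hs$raw_score - log(K)) / log(2),
        evalue = ev,
        pident = 100 * hs$nident / pmax(hs$length, 1L),
        length = hs$length, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else empty_hsps(qid)
  out <- out[order(out$scaffold_id, out$sstart0), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_hsps <- function(qid = character(0)) {
  data.frame(query_id = character(0), scaffold_id = character(0),
             frame = integer(0), strand = character(0), qstart = integer(0),
             qend = integer(0), sstart0 = integer(0), send0 = integer(0),
             raw_score = numeric(0), bit_score = numeric(0),
             evalue = numeric(0), pident = numeric(0), length = integer(0),
             stringsAsFactors = FALSE)
}

#' Search many queries, reusing one genome translation
#'
#' @inheritParams search
#' @param queries named character vector of protein queries.
#' @return row-bound HSP data.frame (see [search()]).
#' @export
search_all <- function(queries, genome, scoring = scoring_scheme(),
                       evalue_cutoff = 1e-5) {
  tg <- if (inherits(genome, "translated_genome")) genome
        else translate_genome(genome)
  do.call(rbind, c(lapply(names(queries), function(q)
    search(queries[q], tg, scoring, evalue_cutoff)),
    list(make.row.names = FALSE)))
}

#' Write HSPs in BLAST tabular (outfmt 6) layout
#'
#' Columns: qseqid sseqid pident length qstart qend sstart send evalue
#' bitscore frame, with 1-based inclusive coordinates as in BLAST (subject
#' start > end on the minus strand).
#'
#' @param hsps HSP data.frame from [search()].
#' @param path output file.
#' @export
write_hsps_tab <- function(hsps, path) {
  sstart <- ifelse(hsps$strand == "+", hsps$sstart0 + 1L, hsps$send0)
  send <- ifelse(hsps$strand == "+", hsps$send0, hsps$sstart0 + 1L)
  tab <- data.frame(hsps$query_id, hsps$scaffold_id,
                    sprintf("%.2f", hsps$pident), hsps$length, hsps$qstart,
                    hsps$qend, sstart, send,
                    format(hsps$evalue, digits = 3),
                    sprintf("%.1f", hsps$bit_score), hsps$frame)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
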