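# Standard-format writers. Internal coordinates are 0-based half-open,
# strand-explicit; GFF3 output converts to 1-based closed as usual.

#' Write sequences as FASTA
#'
#' @param seqs named character vector (nucleotide or protein).
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (length(seqs) == 0) { writeLines(character(0), path); return(invisible(path)) }
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @param type `"DNA"` or `"AA"`.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- if (type == "DNA") Biostrings::readDNAStringSet(path)
       else Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write an annotation set as GFF3
#'
#' Emits gene/mRNA/exon/CDS features (1-based closed coordinates) with
#' `status`, `frameshifts` and `internal_stops` attributes on the gene rows.
#'
#' @param annotation an `annotation_set` (or a `truth_set`).
#' @param path output file.
#' @export
write_gff3 <- function(annotation, path) {
  lines <- "##gff-version 3"
  fmt <- function(scaf, src, type, s0, e0, strand, attrs)
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s", scaf, src, type,
            as.integer(s0) + 1L, as.integer(e0), strand, attrs)
  if (inherits(annotation, "truth_set")) {
    g <- annotation$genes
    for (i in seq_len(nrow(g))) {
      lines <- c(lines, fmt(g$scaffold[i], "forge", "gene", g$start0[i],
                            g$end0[i], g$strand[i],
                            sprintf("ID=%s;status=%s", g$gene_id[i],
                                    g$status[i])))
      ex <- annotation$exons[annotation$exons$gene_id == g$gene_id[i], ]
      for (j in seq_len(nrow(ex)))
        lines <- c(lines, fmt(g$scaffold[i], "forge", "exon", ex$start0[j],
                              ex$end0[j], g$strand[i],
                              sprintf("ID=%s.e%d;Parent=%s", g$gene_id[i],
                                      ex$exon_rank[j], g$gene_id[i])))
    }
  } else {
    for (m in annotation$models) {
      span <- range(m$exons)
      lines <- c(lines, fmt(m$scaffold_id, "chemrec", "gene", span[1],
                            span[2], m$strand,
                            sprintf("ID=%s;status=%s;frameshifts=%d;internal_stops=%d;reference=%s",
                                    m$gene_id, m$status, m$frameshift_events,
                                    m$internal_stop_count, m$reference_id)))
      lines <- c(lines, fmt(m$scaffold_id, "chemrec", "mRNA", span[1],
                            span[2], m$strand,
                            sprintf("ID=%s.t1;Parent=%s", m$gene_id,
                                    m$gene_id)))
      ex <- m$exons[order(m$exons[, 1]), , drop = FALSE]
      for (j in seq_len(nrow(ex))) {
        at <- sprintf("ID=%s.e%d;Parent=%s.t1", m$gene_id, j, m$gene_id)
        lines <- c(lines, fmt(m$scaffold_id, "chemrec", "exon", ex[j, 1],
                              ex[j, 2], m$strand, at),
                   fmt(m$scaffold_id, "chemrec", "CDS", ex[j, 1], ex[j, 2],
                       m$strand, sub("\\.e", ".c", at)))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write per-family gene counts as TSV
#'
#' Columns `family`, `total`, `full_length`, `partial`, `pseudogenes` -
#' one row per annotation set.
#'
#' @param annotations list of `annotation_set`.
#' @param path output file.
#' @export
write_counts_tsv <- function(annotations, path) {
  tab <- do.call(rbind, lapply(annotations, function(a)
    data.frame(family = a$family, total = a$counts[["total"]],
               full_length = a$counts[["full_length"]],
               partial = a$counts[["partial"]],
               pseudogenes = a$counts[["pseudogene"]])))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the proteins (or CDSs) of an annotation set
#'
#' @param annotation an `annotation_set`.
#' @param what `"protein"` or `"cds"`.
#' @return named character vector keyed by gene id.
#' @export
annotation_sequences <- function(annotation, what = c("protein", "cds")) {
  what <- match.arg(what)
  out <- vapply(annotation$models, `[[`, character(1), what)
  names(out) <- vapply(annotation$models, `[[`, character(1), "gene_id")
  out
}
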