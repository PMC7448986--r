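#' Chain translated-search hits into candidate gene loci
#'
#' Links HSPs "exon by exon": two hits of one query join the same chain iff
#' they lie on the same scaffold and strand, their genomic gap does not
#' exceed `max_intron`, their query intervals are colinear with the genomic
#' order on the coding strand (overlap of at most 10 aa - a backward query
#' reset, as produced by the next member of a tandem array, forces a chain
#' split), and the chain span stays within `max_locus_span`. Chains from
#' different queries whose genomic ranges overlap on the same strand are then
#' merged into a single locus, so every input HSP belongs to exactly one
#' locus.
#'
#' @param hsps HSP data.frame from [search()] / [search_all()].
#' @param max_intron largest genomic gap (bp) bridged within one chain.
#' @param max_locus_span largest genomic span (bp) of one chain.
#' @param colinear_overlap tolerated query overlap (aa) between consecutive
#'   exon hits.
#' @return list of `candidate_locus` objects, sorted by (scaffold, start),
#'   each with `locus_id`, `scaffold_id`, `strand`, `core_start0`,
#'   `core_end0`, `flank_start0`, `flank_end0`, `hsps`, `best_query` and
#'   `query_scores` (summed bit scores per query).
#' @export
chain_hits <- function(hsps, max_intron = 15000L, max_locus_span = 50000L,
                       colinear_overlap = 10L) {
  if (is.null(hsps) || nrow(hsps) == 0) return(list())
  # per-(scaffold, strand, query) greedy chaining over index vectors
  grp <- paste(hsps$scaffold_id, hsps$strand, hsps$query_id, sep = "\r")
  chain_idx <- list()
  for (key in unique(grp)) {
    idx <- which(grp == key)
    fwd <- hsps$strand[idx[1]] == "+"
    idx <- idx[order(if (fwd) hsps$sstart0[idx] else -hsps$send0[idx])]
    cur <- idx[1]
    cmin <- hsps$sstart0[idx[1]]; cmax <- hsps$send0[idx[1]]
    cqend <- hsps$qend[idx[1]]
    for (i in idx[-1]) {
      gap <- if (fwd) hsps$sstart0[i] - cmax else cmin - hsps$send0[i]
      span <- if (fwd) hsps$send0[i] - cmin else cmax - hsps$sstart0[i]
      colinear <- hsps$qstart[i] >= cqend - colinear_overlap
      if (gap <= max_intron && span <= max_locus_span && colinear) {
        cur <- c(cur, i)
        cmin <- min(cmin, hsps$sstart0[i]); cmax <- max(cmax, hsps$send0[i])
        cqend <- max(cqend, hsps$qend[i])
      } else {
        chain_idx[[length(chain_idx) + 1L]] <- cur
        cur <- i
        cmin <- hsps$sstart0[i]; cmax <- hsps$send0[i]
        cqend <- hsps$qend[i]
      }
    }
    chain_idx[[length(chain_idx) + 1L]] <- cur
  }
  chains <- lapply(chain_idx, function(ii) hsps[ii, , drop = FALSE])
  # merge overlapping chains across queries (same scaffold + strand)
  loci <- list()
  meta <- data.frame(
    scaffold = vapply(chains, function(c) c$scaffold_id[1], character(1)),
    strand = vapply(chains, function(c) c$strand[1], character(1)),
    s = vapply(chains, function(c) min(c$sstart0), numeric(1)),
    e = vapply(chains, function(c) max(c$send0), numeric(1)),
    stringsAsFactors = FALSE)
  for (key in unique(paste(meta$scaffold, meta$strand))) {
    idx <- which(paste(meta$scaffold, meta$strand) == key)
    idx <- idx[order(meta$s[idx])]
    grp <- list(); cur <- idx[1]; cure <- meta$e[idx[1]]
    for (i in idx[-1]) {
      if (meta$s[i] < cure) { cur <- c(cur, i); cure <- max(cure, meta$e[i]) }
      else { grp[[length(grp) + 1L]] <- cur; cur <- i; cure <- meta$e[i] }
    }
    grp[[length(grp) + 1L]] <- cur
    for (g in grp) {
      h <- do.call(rbind, chains[g])
      scores <- tapply(h$bit_score, h$query_id, sum)
      loci[[length(loci) + 1L]] <- structure(list(
        locus_id = NA_character_, scaffold_id = h$scaffold_id[1],
        strand = h$strand[1], core_start0 = min(h$sstart0),
        core_end0 = max(h$send0), flank_start0 = min(h$sstart0),
        flank_end0 = max(h$send0), hsps = h,
        best_query = names(scores)[which.max(scores)],
        query_scores = sort(unlist(as.list(scores)), decreasing = TRUE)),
        class = "candidate_locus")
    }
  }
  ord <- order(vapply(loci, `[[`, character(1), "scaffold_id"),
               vapply(loci, `[[`, numeric(1), "core_start0"))
  loci <- loci[ord]
  for (i in seq_along(loci)) loci[[i]]$locus_id <- sprintf("LOC%05d", i)
  loci
}

#' Attach flanking sequence to a candidate locus
#'
#' Extends the locus core by `flank` bp on each side (2 kb by default),
#' clipped to the scaffold bounds.
#'
#' @param locus a `candidate_locus`.
#' @param scaffold_length length of the locus scaffold in bp.
#' @param flank flank size in bp.
#' @return the locus with `flank_start0`/`flank_end0` set.
#' @export
add_flanks <- function(locus, scaffold_length, flank = 2000L) {
  stopifnot(inherits(locus, "candidate_locus"),
            locus$core_start0 >= 0, locus$core_end0 <= scaffold_length)
  locus$flank_start0 <- max(0L, locus$core_start0 - as.integer(flank))
  locus$flank_end0 <- min(as.integer(scaffold_length),
                          locus$core_end0 + as.integer(flank))
  locus
}

#' Merge candidate loci from two identification rounds
#'
#' Loci whose core ranges overlap on the same scaffold and strand are unified
#' into the envelope of both, pooling their supporting HSPs. Locus ids of
#' round-1 survivors are stable; purely round-2 loci get fresh ids.
#'
#' @param loci_round1,loci_round2 lists of `candidate_locus`.
#' @return deduplicated, coordinate-sorted locus list.
#' @export
merge_rounds <- function(loci_round1, loci_round2) {
  all_loci <- c(loci_round1, loci_round2)
  if (!length(all_loci)) return(list())
  round1_ids <- vapply(loci_round1, `[[`, character(1), "locus_id")
  n <- length(all_loci)
  meta <- data.frame(
    scaffold = vapply(all_loci, `[[`, character(1), "scaffold_id"),
    strand = vapply(all_loci, `[[`, character(1), "strand"),
    s = vapply(all_loci, `[[`, numeric(1), "core_start0"),
    e = vapply(all_loci, `[[`, numeric(1), "core_end0"),
    from1 = c(rep(TRUE, length(loci_round1)), rep(FALSE, length(loci_round2))),
    stringsAsFactors = FALSE)
  out <- list()
  for (key in unique(paste(meta$scaffold, meta$strand))) {
    idx <- which(paste(meta$scaffold, meta$strand) == key)
    idx <- idx[order(meta$s[idx])]
    grp <- list(); cur <- idx[1]; cure <- meta$e[idx[1]]
    for (i in idx[-1]) {
      if (meta$s[i] < cure) { cur <- c(cur, i); cure <- max(cure, meta$e[i]) }
      else { grp[[length(grp) + 1L]] <- cur; cur <- i; cure <- meta$e[i] }
    }
    grp[[length(grp) + 1L]] <- cur
    for (g in grp) {
      h <- unique(do.call(rbind, lapply(all_loci[g], `[[`, "hsps")))
      scores <- tapply(h$bit_score, h$query_id, sum)
      id1 <- meta$from1[g]
      lid <- if (any(id1)) all_loci[[g[which(id1)[1]]]]$locus_id
             else NA_character_
      out[[length(out) + 1L]] <- structure(list(
        locus_id = lid, scaffold_id = h$scaffold_id[1], strand = h$strand[1],
        core_start0 = min(meta$s[g]), core_end0 = max(meta$e[g]),
        flank_start0 = min(vapply(all_loci[g], `[[`, numeric(1),
                                  "flank_start0")),
        flank_end0 = max(vapply(all_loci[g], `[[`, numeric(1),
                                "flank_end0")),
        hsps = h, best_query = names(scores)[which.max(scores)],
        query_scores = sort(unlist(as.list(scores)), decreasing = TRUE)),
        class = "candidate_locus")
    }
  }
  ord <- order(vapply(out, `[[`, character(1), "scaffold_id"),
               vapply(out, `[[`, numeric(1), "core_start0"))
  out <- out[ord]
  nxt <- length(round1_ids)
  for (i in seq_along(out)) {
    if (is.na(out[[i]]$locus_id)) {
      nxt <- nxt + 1L
      out[[i]]$locus_id <- sprintf("LOC%05d", nxt)
    }
  }
  out
}

#' Write candidate loci as BED
#'
#' 0-based half-open intervals with locus id, best query and HSP count.
#'
#' @param loci list of `candidate_locus`.
#' @param path output file.
#' @export
write_locus_bed <- function(loci, path) {
  tab <- data.frame(
    chrom = vapply(loci, `[[`, character(1), "scaffold_id"),
    start = vapply(loci, `[[`, numeric(1), "core_start0"),
    end = vapply(loci, `[[`, numeric(1), "core_end0"),
    name = vapply(loci, `[[`, character(1), "locus_id"),
    score = vapply(loci, function(l) nrow(l$hsps), integer(1)),
    strand = vapply(loci, `[[`, character(1), "strand"),
    best_query = vapply(loci, `[[`, character(1), "best_query"))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
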