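#' Length-filter family proteins before tree building
#'
#' Partial ORs shorter than 230 aa and GRs shorter than 250 aa are excluded
#' from phylogenetic analysis; IRs have no additional tree filter.
#'
#' @param proteins named character vector.
#' @param family `"OR"`, `"GR"` or `"IR"`.
#' @param config a [pipeline_config()] (supplies the per-family minima).
#' @return the retained subset.
#' @export
filter_for_tree <- function(proteins, family, config = pipeline_config()) {
  min_aa <- config$tree_min_aa[[family]]
  if (is.null(min_aa)) return(proteins)
  proteins[nchar(proteins) >= min_aa]
}

#' Multiple sequence alignment of family proteins
#'
#' Aligns with MAFFT, the field's standard aligner for receptor families,
#' which must be on the PATH. The alignment is deterministic for a given
#' input.
#'
#' @param proteins named character vector (>= 2 sequences).
#' @return named character vector of equal-length aligned rows, class `msa`.
#' @export
build_msa <- function(proteins) {
  if (length(proteins) < 2) stop("need at least 2 sequences to align")
  if (Sys.which("mafft") == "") stop("mafft not found on PATH")
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_fasta(proteins, fin)
  status <- system2("mafft", c("--auto", "--quiet", "--anysymbol", fin),
                    stdout = fout, stderr = FALSE)
  if (status != 0) stop("mafft failed with status ", status)
  aln <- read_fasta(fout, "AA")
  aln <- toupper(aln)[names(proteins)] # mafft keeps order; be explicit
  stopifnot(!anyNA(names(aln)), length(unique(nchar(aln))) == 1)
  # round-trip: degapping reproduces each input
  stopifnot(identical(toupper(unname(gsub("-", "", aln))),
                      toupper(unname(proteins))))
  structure(aln, class = "msa")
}

msa_to_phydat <- function(msa) {
  mat <- do.call(rbind, strsplit(unclass(msa), "", fixed = TRUE))
  rownames(mat) <- names(msa)
  phangorn::phyDat(mat, type = "AA")
}

#' Maximum-likelihood JTT distance between two aligned rows
#'
#' Pairwise ML distance under the JTT substitution model, optionally with
#' discrete-gamma rate heterogeneity, after pairwise deletion of gap
#' columns.
#'
#' @param row_a,row_b aligned amino-acid strings of equal length.
#' @param gamma_shape gamma shape alpha (4 categories); `NULL` for uniform
#'   rates.
#' @return the distance (substitutions/site); attribute `unreliable` is TRUE
#'   when fewer than 30 ungapped columns are shared.
#' @export
jtt_distance <- function(row_a, row_b, gamma_shape = NULL) {
  stopifnot(nchar(row_a) == nchar(row_b))
  a <- strsplit(toupper(row_a), "")[[1]]
  b <- strsplit(toupper(row_b), "")[[1]]
  keep <- a %in% CR_AA[1:20] & b %in% CR_AA[1:20]
  shared <- sum(keep)
  mat <- rbind(a = a[keep], b = b[keep])
  pd <- phangorn::phyDat(mat, type = "AA")
  d <- if (is.null(gamma_shape))
    phangorn::dist.ml(pd, model = "JTT")
  else phangorn::dist.ml(pd, model = "JTT", k = 4L, shape = gamma_shape)
  out <- as.numeric(d)
  attr(out, "unreliable") <- shared < 30
  if (shared < 30)
    warning("fewer than 30 shared ungapped columns; distance unreliable")
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' The tree-construction step used by [build_tree()] and its bootstrap
#' replicates; exact on additive distance matrices.
#'
#' @param d a `dist` or symmetric matrix.
#' @return an unrooted `phylo`.
#' @export
nj_from_distances <- function(d) ape::nj(d)

# JTT(+G+F) distance matrix of a whole alignment
family_dist <- function(pd, gamma_shape = NULL, bf = NULL) {
  args <- list(x = pd, model = "JTT", exclude = "pairwise")
  if (!is.null(gamma_shape)) { args$k <- 4L; args$shape <- gamma_shape }
  if (!is.null(bf)) args$bf <- bf
  do.call(phangorn::dist.ml, args)
}

# estimate the gamma shape once per family (JTT + G, 4 categories) from the
# likelihood of the NJ starting tree; falls back to 1 if optimization fails
estimate_gamma_shape <- function(pd, start_tree) {
  fit <- tryCatch({
    f <- phangorn::pml(start_tree, pd, model = "JTT", k = 4L, shape = 1)
    f <- phangorn::optim.pml(f, optGamma = TRUE, optEdge = TRUE,
                             model = "JTT",
                             control = phangorn::pml.control(maxit = 3,
                                                             trace = 0))
    f$shape
  }, error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit)) 1 else min(max(fit, 0.05), 50)
}

#' Build a bootstrapped, rooted family tree
#'
#' Neighbor joining on maximum-likelihood JTT distances - JTT + G + F
#' (empirical frequencies, gamma shape estimated once per family) for ORs
#' and GRs, plain JTT for IRs. Node supports are the percentage of
#' `n_bootstrap` column-resampled replicates containing each bipartition.
#' The tree is rooted on the supplied outgroup leaves (the Orco lineage for
#' ORs, sugar receptors for GRs, the IR8a/25a lineage for IRs).
#'
#' @param msa an `msa` (or named character vector of aligned rows).
#' @param family family label; OR/GR get +G+F.
#' @param n_bootstrap bootstrap replicate count.
#' @param seed integer seed for the bootstrap resampling.
#' @param outgroup character vector of outgroup leaf ids (NULL or absent
#'   leaves give an unrooted tree with a warning).
#' @return an `ape::phylo` tree, node labels carrying bootstrap percentages;
#'   attribute `rooted_on` records the outgroup used.
#' @export
build_tree <- function(msa, family = "OR", n_bootstrap = 200L, seed = 1L,
                       outgroup = NULL) {
  if (length(msa) < 4) stop("need at least 4 sequences for a tree")
  pd <- msa_to_phydat(msa)
  use_gf <- family %in% c("OR", "GR")
  bf <- NULL; shape <- NULL
  if (use_gf) {
    tabf <- table(factor(unlist(strsplit(unclass(msa), "")),
                         levels = CR_AA[1:20]))
    bf <- as.numeric(tabf) / sum(tabf)
    d0 <- family_dist(pd, NULL, bf)
    shape <- estimate_gamma_shape(pd, nj_from_distances(d0))
  }
  d <- family_dist(pd, shape, bf)
  tree <- nj_from_distances(d)
  mat <- do.call(rbind, strsplit(unclass(msa), "", fixed = TRUE))
  rownames(mat) <- names(msa)
  boots <- with_local_seed(seed, lapply(seq_len(n_bootstrap), function(b) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    pdb <- phangorn::phyDat(mat[, cols, drop = FALSE], type = "AA")
    nj_from_distances(family_dist(pdb, shape, bf))
  }))
  if (n_bootstrap > 0) {
    counts <- ape::prop.clades(tree, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0
    tree$node.label <- round(100 * counts / n_bootstrap)
  }
  og <- intersect(outgroup, tree$tip.label)
  if (!is.null(outgroup) && length(og) &&
      length(og) < length(tree$tip.label)) {
    rooted <- tryCatch(ape::root(tree, outgroup = og, resolve.root = TRUE,
                                 edgelabel = TRUE), error = function(e) NULL)
    if (is.null(rooted)) {
      # outgroup leaves not monophyletic (e.g. per-gene orthologs); fall
      # back to a single-leaf root
      warning("outgroup not monophyletic; rooting on ", og[1])
      rooted <- ape::root(tree, outgroup = og[1], resolve.root = TRUE,
                          edgelabel = TRUE)
      og <- og[1]
    }
    tree <- rooted
    attr(tree, "rooted_on") <- og
  } else {
    if (!is.null(outgroup))
      warning("outgroup members missing from tree; returning unrooted tree")
    attr(tree, "rooted_on") <- character(0)
  }
  tree
}

#' Extract 1:1 orthologue pairs from a rooted family tree
#'
#' A pair is emitted iff two leaves from different focal species form an
#' exclusive two-leaf clade (their most recent common ancestor has exactly
#' those two descendants). Each gene therefore appears in at most one pair.
#' The pair's support is the bootstrap label of that node.
#'
#' @param tree rooted `phylo` with bootstrap node labels.
#' @param species_map named character vector mapping every leaf to a species.
#' @param focal_species the two species between which pairs are sought;
#'   defaults to the two most frequent species in the map.
#' @return data.frame with `gene_a`, `gene_b`, `support`.
#' @export
find_ortholog_pairs <- function(tree, species_map, focal_species = NULL) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  miss <- setdiff(tree$tip.label, names(species_map))
  if (length(miss)) stop("leaves missing from species_map: ",
                         paste(head(miss, 3), collapse = ", "))
  if (is.null(focal_species)) {
    sp <- sort(table(species_map[tree$tip.label]), decreasing = TRUE)
    if (length(sp) < 2) stop("need two species to pair")
    focal_species <- names(sp)[1:2]
  }
  ntip <- length(tree$tip.label)
  rows <- list()
  for (node in unique(tree$edge[, 1])) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(kids) == 2 && all(kids <= ntip)) {
      la <- tree$tip.label[kids[1]]; lb <- tree$tip.label[kids[2]]
      sa <- species_map[[la]]; sb <- species_map[[lb]]
      if (sa != sb && all(c(sa, sb) %in% focal_species)) {
        if (sa != focal_species[1]) { tmp <- la; la <- lb; lb <- tmp }
        supp <- if (!is.null(tree$node.label))
          suppressWarnings(as.numeric(tree$node.label[node - ntip]))
        else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = la, gene_b = lb, support = supp,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      support = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
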