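#' Pipeline configuration
#'
#' Collects every numeric threshold of the annotation and selection pipeline
#' in one validated object. Defaults follow standard receptor-annotation
#' practice (e-value 1e-5; 2-kb flanks; retention of incomplete genes at
#' half the reference length and strictly more than 190 aa; completeness
#' thresholds 120 aa for OR/GR and 190 aa for IR; tree length filters 230 aa
#' for ORs and 250 aa for GRs; 200 bootstrap replicates; LRT alpha 0.01 at
#' df 1; site posterior cutoff 0.95) and are declared package choices where
#' it is not (full-length fraction 0.9; chaining limits; family margin).
#'
#' @param evalue_cutoff translated-search e-value cutoff.
#' @param flank_bp flank attached to candidate loci.
#' @param min_partial_aa partial models must be strictly longer than this.
#' @param half_length_fraction,full_length_fraction retention fractions of
#'   the reference length.
#' @param completeness_aa per-family minimum homologous region (aa) for the
#'   transcript completeness check.
#' @param completeness_identity identity needed to count a transcript as
#'   found in the annotation.
#' @param tree_min_aa per-family minimum protein length for tree building.
#' @param n_bootstrap bootstrap replicates for node support.
#' @param lrt_alpha P-value cutoff of the M7-vs-M8 test.
#' @param posterior_cutoff NEB/BEB posterior cutoff for selected sites.
#' @param df LRT degrees of freedom (1 as published; 2 available).
#' @param max_intron,max_locus_span HSP chaining limits in bp.
#' @param top_n_references references tried per locus for gene models.
#' @param family_margin_bits bit-score margin for family consistency.
#' @param decoy_labels family-db labels treated as decoys.
#' @param scoring a [scoring_scheme()].
#' @param spliced a [spliced_params()].
#' @param rng_seed master seed fanned out to all stochastic stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(evalue_cutoff = 1e-5, flank_bp = 2000L,
                            min_partial_aa = 190L,
                            half_length_fraction = 0.5,
                            full_length_fraction = 0.9,
                            completeness_aa = list(OR = 120L, GR = 120L,
                                                   IR = 190L),
                            completeness_identity = 0.9,
                            tree_min_aa = list(OR = 230L, GR = 250L),
                            n_bootstrap = 200L, lrt_alpha = 0.01,
                            posterior_cutoff = 0.95, df = 1L,
                            max_intron = 15000L, max_locus_span = 50000L,
                            top_n_references = 5L, family_margin_bits = 5,
                            decoy_labels = "decoy",
                            scoring = scoring_scheme(),
                            spliced = spliced_params(), rng_seed = 1L) {
  cfg <- list(evalue_cutoff = evalue_cutoff, flank_bp = as.integer(flank_bp),
              min_partial_aa = as.integer(min_partial_aa),
              half_length_fraction = half_length_fraction,
              full_length_fraction = full_length_fraction,
              completeness_aa = completeness_aa,
              completeness_identity = completeness_identity,
              tree_min_aa = tree_min_aa, n_bootstrap = as.integer(n_bootstrap),
              lrt_alpha = lrt_alpha, posterior_cutoff = posterior_cutoff,
              df = as.integer(df), max_intron = as.integer(max_intron),
              max_locus_span = as.integer(max_locus_span),
              top_n_references = as.integer(top_n_references),
              family_margin_bits = family_margin_bits,
              decoy_labels = decoy_labels, scoring = scoring,
              spliced = spliced, rng_seed = as.integer(rng_seed))
  stopifnot(cfg$evalue_cutoff > 0, cfg$flank_bp >= 0,
            cfg$min_partial_aa > 0,
            cfg$half_length_fraction > 0, cfg$half_length_fraction <= 1,
            cfg$full_length_fraction > 0, cfg$full_length_fraction <= 1,
            cfg$n_bootstrap >= 0, cfg$lrt_alpha > 0, cfg$lrt_alpha < 1,
            cfg$posterior_cutoff > 0, cfg$posterior_cutoff <= 1,
            cfg$df %in% c(1L, 2L), cfg$max_intron > 0,
            cfg$max_locus_span >= cfg$max_intron)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields in the file override [pipeline_config()] defaults; unknown
#' fields are an error.
#'
#' @param path YAML file.
#' @param ... further overrides applied after the file.
#' @export
load_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  # YAML renders some numeric spellings (e.g. "1e-3") as strings
  vals <- lapply(vals, function(v) {
    if (is.character(v) && length(v) == 1 &&
        !is.na(suppressWarnings(as.numeric(v)))) as.numeric(v) else v
  })
  extra <- list(...)
  vals[names(extra)] <- extra
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}
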