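#' Build a codon alignment from a protein alignment and the source CDSs
#'
#' Back-translates a pairwise protein alignment: every aligned amino-acid
#' column expands to its source codon (or `---` opposite a gap). Columns in
#' which either codon is a stop are removed with a warning. The degapped
#' rows reproduce the input CDSs exactly.
#'
#' @param protein_msa named character vector of the two aligned protein rows
#'   (gap `-`).
#' @param cds_a,cds_b in-frame coding sequences of rows 1 and 2 (length
#'   divisible by 3, no terminal stop needed); `translate(cds)` must equal
#'   the degapped protein row, with X tolerated opposite any codon.
#' @return list of class `codon_alignment`: `ids`, `codons_a`, `codons_b`
#'   (per-column codons incl. `---`), `n_codons`.
#' @export
codon_align <- function(protein_msa, cds_a, cds_b) {
  stopifnot(length(protein_msa) == 2, nchar(cds_a) %% 3 == 0,
            nchar(cds_b) %% 3 == 0)
  rows <- strsplit(toupper(protein_msa), "", fixed = TRUE)
  stopifnot(length(rows[[1]]) == length(rows[[2]]))
  expand <- function(row, cds, label) {
    ncod <- nchar(cds) %/% 3
    cods <- substring(cds, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
    if (sum(row != "-") != ncod)
      stop(sprintf("%s: %d codons but %d aligned residues", label, ncod,
                   sum(row != "-")))
    tr <- vapply(cods, cr_translate_cds, character(1), USE.NAMES = FALSE)
    aa <- row[row != "-"]
    bad <- which(tr != aa & aa != "X" & tr != "X" & tr != "*")
    if (length(bad))
      stop(sprintf("%s: CDS/protein mismatch at codon %d (%s translates %s, row has %s)",
                   label, bad[1], cods[bad[1]], tr[bad[1]], aa[bad[1]]))
    out <- rep("---", length(row))
    out[row != "-"] <- cods
    out
  }
  ids <- names(protein_msa)
  if (is.null(ids)) ids <- c("seq_a", "seq_b")
  ca <- expand(rows[[1]], cds_a, ids[1])
  cb <- expand(rows[[2]], cds_b, ids[2])
  stops <- c("TAA", "TAG", "TGA")
  drop <- ca %in% stops | cb %in% stops
  if (any(drop)) {
    warning(sprintf("removed %d stop-containing codon column(s)", sum(drop)))
    ca <- ca[!drop]; cb <- cb[!drop]
  }
  if (length(ca) < 30)
    warning("codon alignment has fewer than 30 columns; estimates unreliable")
  structure(list(ids = ids, codons_a = ca, codons_b = cb,
                 n_codons = length(ca)), class = "codon_alignment")
}

#' Likelihood-ratio test of M8 against M7
#'
#' Computes `delta = 2 * (lnL(M8) - lnL(M7))`, floored at zero, and its
#' upper-tail chi-square P-value. By default delta is evaluated against
#' chi-square with one degree of freedom; `df = 2` (the conventional count
#' for the two extra M8 parameters) is available.
#'
#' @param fit_m7,fit_m8 `site_model_fit`s of both models on one alignment.
#' @param df degrees of freedom.
#' @return list: `delta`, `p_value`, `df`.
#' @export
lrt <- function(fit_m7, fit_m8, df = 1L) {
  stopifnot(inherits(fit_m7, "site_model_fit"),
            inherits(fit_m8, "site_model_fit"),
            fit_m7$model == "M7", fit_m8$model == "M8")
  if (fit_m7$n_codons != fit_m8$n_codons ||
      !identical(fit_m7$patterns$n, fit_m8$patterns$n))
    stop("fits come from different alignments")
  delta <- max(0, 2 * (fit_m8$lnL - fit_m7$lnL))
  list(delta = delta, p_value = pchisq(delta, df, lower.tail = FALSE),
       df = as.integer(df))
}

# per-class per-site likelihoods at given parameters; mu optionally frozen
site_class_liks <- function(pat, classes, kappa, t, mu = NULL) {
  tab <- cr_codon_tables()
  .cpp_codon_site_liks(classes$omega, classes$weight, kappa, t, pat$site_x,
                       pat$site_y, if (is.null(mu)) -1 else mu, tab$TS,
                       tab$NS, tab$ALLOWED)
}

#' Naive empirical Bayes posterior of positive selection per site
#'
#' With all parameters fixed at their M8 maximum-likelihood estimates, the
#' posterior probability that a site belongs to an omega > 1 class is the
#' normalized weighted class likelihood summed over classes whose omega
#' exceeds 1.
#'
#' @param fit_m8 converged M8 `site_model_fit`.
#' @param aln the `codon_alignment` that was fitted.
#' @return numeric vector over alignment columns; NA at columns excluded
#'   from the likelihood (gaps/ambiguity).
#' @export
neb_sites <- function(fit_m8, aln) {
  stopifnot(inherits(fit_m8, "site_model_fit"), fit_m8$model == "M8")
  pat <- codon_patterns(aln)
  cls <- site_model_classes("M8", fit_m8$p, fit_m8$q, fit_m8$p0,
                            fit_m8$omega_s, fit_m8$K)
  L <- site_class_liks(pat, cls, fit_m8$kappa, fit_m8$t)
  wL <- L * rep(cls$weight, each = nrow(L))
  post <- rowSums(wL[, cls$omega > 1, drop = FALSE]) / rowSums(wL)
  out <- rep(NA_real_, aln$n_codons)
  out[pat$site_idx] <- post
  out
}

#' Bayes empirical Bayes posterior of positive selection per site
#'
#' Averages NEB-style posteriors over a discrete grid on the omega
#' distribution parameters (p0, p, q, omega_s), weighting each grid point by
#' its data likelihood under a uniform prior; branch length, kappa and the
#' rate scaling stay fixed at their MLEs. This integrates the uncertainty in
#' the omega distribution that NEB ignores, shrinking posteriors on weakly
#' informative alignments.
#'
#' @param fit_m8 converged M8 `site_model_fit`.
#' @param aln the fitted `codon_alignment`.
#' @param grid_points grid resolution per dimension.
#' @return numeric vector over alignment columns (NA at excluded columns).
#' @export
beb_sites <- function(fit_m8, aln, grid_points = 6L) {
  stopifnot(inherits(fit_m8, "site_model_fit"), fit_m8$model == "M8")
  pat <- codon_patterns(aln)
  K <- fit_m8$K
  if (grid_points == 1L) {
    p0g <- fit_m8$p0; pg <- fit_m8$p; qg <- fit_m8$q; wsg <- fit_m8$omega_s
  } else {
    # midpoint quadrature over the declared bounds: interior points avoid
    # the degenerate corners (p0 = 0: every site selected; omega_s = 1)
    mid <- (seq_len(grid_points) - 0.5) / grid_points
    p0g <- mid
    pg <- exp(log(0.05) + mid * (log(50) - log(0.05)))
    qg <- pg
    wsg <- exp(log(1) + mid * (log(20) - log(1)))
  }
  # freeze the rate scaling at the MLE class structure
  cls_mle <- site_model_classes("M8", fit_m8$p, fit_m8$q, fit_m8$p0,
                                fit_m8$omega_s, K)
  pif <- rep(1 / cr_codon_tables()$n, cr_codon_tables()$n)
  mu <- sum(vapply(seq_along(cls_mle$omega), function(k)
    cls_mle$weight[k] * sum(pif * -diag(gy94_q(fit_m8$kappa,
                                               cls_mle$omega[k], pif))),
    numeric(1)))
  # distinct omegas across the grid -> one site-likelihood column each
  omega_by_pq <- lapply(seq_along(pg), function(i)
    lapply(seq_along(qg), function(j) beta_class_means(pg[i], qg[j], K)))
  all_omega <- sort(unique(signif(c(unlist(omega_by_pq), wsg), 12)))
  Lom <- site_class_liks(pat, list(omega = all_omega,
                                   weight = rep(1, length(all_omega))),
                         fit_m8$kappa, fit_m8$t, mu = mu)
  col_of <- function(om) match(signif(om, 12), all_omega)
  n_grid <- length(p0g) * length(pg) * length(qg) * length(wsg)
  logliks <- numeric(n_grid)
  posts <- matrix(0, nrow(Lom), n_grid)
  g <- 0L
  for (i in seq_along(pg)) for (j in seq_along(qg)) {
    om_idx <- col_of(omega_by_pq[[i]][[j]])
    Lbeta <- Lom[, om_idx, drop = FALSE]
    for (wsi in seq_along(wsg)) {
      Lsel <- Lom[, col_of(wsg[wsi])]
      sel_gt1 <- wsg[wsi] > 1
      beta_gt1 <- all_omega[om_idx] > 1
      for (p0i in seq_along(p0g)) {
        g <- g + 1L
        w <- c(rep(p0g[p0i] / K, K), 1 - p0g[p0i])
        lik_beta <- Lbeta %*% (w[1:K])
        lik <- lik_beta + w[K + 1] * Lsel
        logliks[g] <- sum(log(pmax(lik, 1e-300)))
        num <- as.vector(Lbeta[, beta_gt1, drop = FALSE] %*%
                           w[1:K][beta_gt1])
        if (sel_gt1) num <- num + w[K + 1] * Lsel
        posts[, g] <- num / pmax(as.vector(lik), 1e-300)
      }
    }
  }
  gw <- exp(logliks - max(logliks))
  gw <- gw / sum(gw)
  beb <- as.vector(posts %*% gw)
  out <- rep(NA_real_, aln$n_codons)
  out[pat$site_idx] <- beb
  out
}

#' Apply the positive-selection decision rule to one orthologue pair
#'
#' A pair is positively selected iff the M7-vs-M8 likelihood-ratio test
#' P-value is below `lrt_alpha` (0.01) AND at least one site reaches the
#' posterior cutoff (0.95) under BOTH the naive and the Bayes empirical
#' Bayes methods. The reported selected sites are exactly those passing
#' both.
#'
#' @param pair_id label of the orthologue pair.
#' @param lrt_result output of [lrt()].
#' @param neb,beb per-site posteriors from [neb_sites()] / [beb_sites()].
#' @param lrt_alpha P-value cutoff.
#' @param posterior_cutoff site posterior cutoff.
#' @return list of class `selection_result`: `pair_id`, `delta`, `df`,
#'   `p_value`, `neb_posteriors`, `beb_posteriors`, `selected_sites`
#'   (1-based codon indices), `positively_selected`.
#' @export
call_selection <- function(pair_id, lrt_result, neb, beb, lrt_alpha = 0.01,
                           posterior_cutoff = 0.95) {
  sites <- which(!is.na(neb) & !is.na(beb) & neb >= posterior_cutoff &
                   beb >= posterior_cutoff)
  structure(list(pair_id = pair_id, delta = lrt_result$delta,
                 df = lrt_result$df, p_value = lrt_result$p_value,
                 neb_posteriors = neb, beb_posteriors = beb,
                 selected_sites = sites,
                 positively_selected = lrt_result$p_value < lrt_alpha &&
                   length(sites) > 0),
            class = "selection_result")
}

#' Full site-model selection analysis of one codon alignment
#'
#' Fits M7, warm-starts M8 from it, runs the LRT, computes NEB and BEB
#' posteriors, and applies the decision rule.
#'
#' @param aln a `codon_alignment`.
#' @param pair_id label for the result.
#' @param config a [pipeline_config()] (supplies df, alpha, cutoff).
#' @return a `selection_result` with the two fits attached as `fit_m7`,
#'   `fit_m8`.
#' @export
selection_test <- function(aln, pair_id = paste(aln$ids, collapse = "-"),
                           config = pipeline_config()) {
  f7 <- fit_site_model(aln, "M7")
  f8 <- fit_site_model(aln, "M8", init = f7)
  lr <- lrt(f7, f8, config$df)
  neb <- neb_sites(f8, aln)
  beb <- beb_sites(f8, aln)
  res <- call_selection(pair_id, lr, neb, beb, config$lrt_alpha,
                        config$posterior_cutoff)
  res$fit_m7 <- f7
  res$fit_m8 <- f8
  res
}

#' Write selection results as TSV
#'
#' One row per pair: lnL of both models, LRT delta and P-value, M8
#' parameter estimates, and the selected sites with both posteriors.
#'
#' @param results list of `selection_result` (with fits attached).
#' @param path output file.
#' @export
write_selection_tsv <- function(results, path) {
  tab <- do.call(rbind, lapply(results, function(r) {
    sites <- if (length(r$selected_sites))
      paste(sprintf("%d(NEB=%.3f,BEB=%.3f)", r$selected_sites,
                    r$neb_posteriors[r$selected_sites],
                    r$beb_posteriors[r$selected_sites]), collapse = ";")
    else "."
    data.frame(pair = r$pair_id, lnL_M7 = r$fit_m7$lnL,
               lnL_M8 = r$fit_m8$lnL, delta = r$delta,
               p_value = r$p_value, kappa = r$fit_m8$kappa, t = r$fit_m8$t,
               p = r$fit_m8$p, q = r$fit_m8$q, p0 = r$fit_m8$p0,
               omega_s = r$fit_m8$omega_s,
               positively_selected = r$positively_selected,
               selected_sites = sites, stringsAsFactors = FALSE)
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
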