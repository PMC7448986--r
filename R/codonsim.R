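#' Specification for a simulated pairwise codon alignment
#'
#' Describes the generating process for one orthologue-pair alignment: a
#' GY94 codon model in which each site's omega is drawn from beta(p, q)
#' (M7), or, under M8, from beta(p, q) with probability `p0` and set to
#' `omega_s > 1` otherwise.
#'
#' @param model `"M7"` or `"M8"`.
#' @param n_codons number of codon sites.
#' @param t branch length separating the two sequences (expected
#'   substitutions per codon under the site-averaged model).
#' @param kappa transition/transversion rate ratio.
#' @param beta_p,beta_q beta shape parameters.
#' @param p0 proportion of sites in the beta class (M8 only).
#' @param omega_s omega of the selected class (M8 only; must exceed 1).
#' @param n_replicates replicate count (consumed by callers that loop).
#' @param rng_seed integer seed.
#' @return list of class `codon_sim_spec`.
#' @export
codon_sim_spec <- function(model = c("M7", "M8"), n_codons = 300L, t = 0.5,
                           kappa = 2, beta_p = 0.5, beta_q = 1.5, p0 = 1,
                           omega_s = 2, n_replicates = 1L, rng_seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_codons >= 1, t >= 0, kappa > 0, beta_p > 0, beta_q > 0,
            p0 >= 0, p0 <= 1, model == "M7" || omega_s > 1,
            n_replicates >= 1)
  structure(list(model = model, n_codons = as.integer(n_codons), t = t,
                 kappa = kappa, beta_p = beta_p, beta_q = beta_q, p0 = p0,
                 omega_s = omega_s, n_replicates = as.integer(n_replicates),
                 rng_seed = as.integer(rng_seed)),
            class = "codon_sim_spec")
}

#' Simulate one pairwise codon alignment under a site model
#'
#' Draws each site's omega from the spec's distribution, samples an
#' ancestral codon from the stationary distribution, and evolves one lineage
#' for branch length `t` by exact stochastic simulation (Gillespie) of the
#' GY94 process - the same rate matrix the likelihood machinery uses. Rates
#' are scaled so `t` is in expected substitutions per codon averaged over
#' the omega distribution.
#'
#' @param spec a [codon_sim_spec()].
#' @param replicate replicate index (shifts the seed deterministically).
#' @return list: `cds_a`, `cds_b` (in-frame coding sequences),
#'   `codons_a`/`codons_b` (codon vectors), `category` (per-site,
#'   `"beta"` or `"selected"`), `omega` (per-site true omega).
#' @export
simulate_codon_pair <- function(spec, replicate = 1L) {
  stopifnot(inherits(spec, "codon_sim_spec"))
  tab <- cr_codon_tables()
  n <- tab$n
  pi <- rep(1 / n, n)
  with_local_seed(spec$rng_seed + 7919L * (as.integer(replicate) - 1L), {
    sel <- if (spec$model == "M8")
      runif(spec$n_codons) > spec$p0 else rep(FALSE, spec$n_codons)
    omega <- ifelse(sel, spec$omega_s,
                    rbeta(spec$n_codons, spec$beta_p, spec$beta_q))
    omega <- pmax(omega, 1e-8)
    # scale: expected rate under the generating omega distribution,
    # computed from a fine discretization of the same model
    cls <- site_model_classes(spec$model, spec$beta_p, spec$beta_q,
                              spec$p0, spec$omega_s, K = 50L)
    mu <- sum(vapply(seq_along(cls$omega), function(k)
      cls$weight[k] * sum(pi * -diag(gy94_q(spec$kappa, cls$omega[k], pi))),
      numeric(1)))
    # per-row synonymous / nonsynonymous rate components (kappa fixed)
    pimat <- matrix(pi, n, n, byrow = TRUE)
    Msyn <- tab$ALLOWED * spec$kappa^tab$TS * (1 - tab$NS) * pimat
    Mns <- tab$ALLOWED * spec$kappa^tab$TS * tab$NS * pimat
    anc <- sample.int(n, spec$n_codons, replace = TRUE, prob = pi)
    der <- anc
    if (spec$t > 0) {
      for (i in seq_len(spec$n_codons)) {
        cur <- anc[i]
        time <- 0
        repeat {
          rates <- (Msyn[cur, ] + omega[i] * Mns[cur, ]) / mu
          tot <- sum(rates)
          time <- time + rexp(1, tot)
          if (time > spec$t) break
          cur <- sample.int(n, 1L, prob = rates)
        }
        der[i] <- cur
      }
    }
    list(cds_a = paste(tab$codons[anc], collapse = ""),
         cds_b = paste(tab$codons[der], collapse = ""),
         codons_a = tab$codons[anc], codons_b = tab$codons[der],
         category = ifelse(sel, "selected", "beta"), omega = omega)
  })
}
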