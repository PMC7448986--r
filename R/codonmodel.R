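# GY94-style codon substitution model over the 61 sense codons, with the
# omega distributions of the M7 (beta) and M8 (beta plus a class with
# omega > 1) site models, fitted to a pairwise codon alignment by maximum
# likelihood. Rates: q_xy = pi_y * kappa^[transition] * omega^[nonsynonymous]
# for single-nucleotide changes, 0 otherwise; the matrix is scaled so that
# one unit of branch length t is one expected substitution per codon under
# the fitted omega distribution (averaged over classes).

cr_codon_tables <- function() {
  if (!is.null(.cr_env$codon_tab)) return(.cr_env$codon_tab)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  aa <- unname(gc[codons])
  n <- length(codons)
  base <- do.call(rbind, strsplit(codons, ""))
  ts_pair <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  ALLOWED <- matrix(0, n, n); TS <- matrix(0, n, n); NS <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    diff <- base[i, ] != base[j, ]
    if (sum(diff) != 1L) next
    ALLOWED[i, j] <- 1
    d <- which(diff)
    TS[i, j] <- as.numeric(ts_pair(base[i, d], base[j, d]))
    NS[i, j] <- as.numeric(aa[i] != aa[j])
  }
  .cr_env$codon_tab <- list(codons = codons, aa = aa, n = n,
                            ALLOWED = ALLOWED, TS = TS, NS = NS)
  .cr_env$codon_tab
}

# unscaled GY94 rate matrix for one omega class
gy94_q <- function(kappa, omega, pi = NULL) {
  tab <- cr_codon_tables()
  if (is.null(pi)) pi <- rep(1 / tab$n, tab$n)
  Q <- tab$ALLOWED * kappa^tab$TS * omega^tab$NS *
    matrix(pi, tab$n, tab$n, byrow = TRUE)
  diag(Q) <- -rowSums(Q)
  Q
}

# mean-within-interval discretization of beta(p, q) into K equal-probability
# classes (the class value is the conditional mean of omega in its decile)
beta_class_means <- function(p, q, K = 10L) {
  cuts <- qbeta(seq(0, 1, length.out = K + 1), p, q)
  up <- pbeta(cuts[-1], p + 1, q)
  lo <- pbeta(cuts[-(K + 1)], p + 1, q)
  m <- (p / (p + q)) * (up - lo) * K
  pmax(m, 1e-8)
}

# omega classes and weights of a site model
site_model_classes <- function(model, p, q, p0 = 1, omega_s = 1, K = 10L) {
  om <- beta_class_means(p, q, K)
  if (model == "M7") {
    list(omega = om, weight = rep(1 / K, K))
  } else {
    list(omega = c(om, omega_s), weight = c(rep(p0 / K, K), 1 - p0))
  }
}

# transition probability matrices for all classes, jointly scaled so the
# expected rate over classes is 1 per unit t
class_pmats <- function(classes, kappa, t, pi = NULL) {
  tab <- cr_codon_tables()
  if (is.null(pi)) pi <- rep(1 / tab$n, tab$n)
  sp <- sqrt(pi)
  Qs <- lapply(classes$omega, gy94_q, kappa = kappa, pi = pi)
  mu <- sum(vapply(seq_along(Qs), function(k)
    classes$weight[k] * sum(pi * -diag(Qs[[k]])), numeric(1)))
  lapply(Qs, function(Q) {
    A <- (sp * Q) %*% diag(1 / sp) # symmetric for reversible GY94
    e <- eigen(A, symmetric = TRUE)
    P <- (e$vectors * rep(exp(e$values * t / mu), each = tab$n)) %*%
      t(e$vectors)
    P <- P / sp * rep(sp, each = tab$n)
    P[P < 0] <- 0
    P
  })
}

# collapse a codon alignment into pattern counts over sense-codon pairs;
# columns with gaps or ambiguity are excluded
codon_patterns <- function(aln) {
  tab <- cr_codon_tables()
  xi <- match(aln$codons_a, tab$codons)
  yi <- match(aln$codons_b, tab$codons)
  keep <- !is.na(xi) & !is.na(yi)
  key <- paste(xi[keep], yi[keep])
  cnt <- table(key)
  idx <- do.call(rbind, lapply(strsplit(names(cnt), " "), as.integer))
  list(x = idx[, 1], y = idx[, 2], n = as.vector(cnt),
       n_sites = sum(keep), site_x = xi[keep], site_y = yi[keep],
       site_idx = which(keep))
}

pair_loglik <- function(par, model, pat, K = 10L, pi = NULL) {
  t <- par[1]; kappa <- par[2]; p <- par[3]; q <- par[4]
  p0 <- if (model == "M8") par[5] else 1
  ws <- if (model == "M8") par[6] else 1
  cls <- site_model_classes(model, p, q, p0, ws, K)
  tab <- cr_codon_tables()
  if (is.null(pi)) {
    # uniform frequencies: cached symmetric-eigen kernel
    return(.cpp_codon_lnL(cls$omega, cls$weight, kappa, t, pat$x, pat$y,
                          pat$n, tab$TS, tab$NS, tab$ALLOWED))
  }
  Ps <- class_pmats(cls, kappa, t, pi)
  lik <- numeric(length(pat$n))
  for (k in seq_along(Ps)) {
    lik <- lik + cls$weight[k] * pi[pat$x] * Ps[[k]][cbind(pat$x, pat$y)]
  }
  sum(pat$n * log(pmax(lik, 1e-300)))
}

#' Fit a codon site model (M7 or M8) to a pairwise codon alignment
#'
#' Maximizes the likelihood of a GY94 codon model in which omega varies
#' across sites: M7 draws omega from a beta(p, q) distribution discretized
#' into `K` equal-probability classes; M8 adds one class with omega_s > 1
#' and weight 1 - p0. Parameters (t, kappa, p, q and, for M8, p0 and
#' omega_s) are optimized by bounded quasi-Newton search from several
#' deterministic starting points (plus the supplied `init`, so an M8 fit
#' warm-started from an M7 fit can never fall below it).
#'
#' @param aln a `codon_alignment` from [codon_align()].
#' @param model `"M7"` or `"M8"`.
#' @param K number of beta discretization classes.
#' @param init optional `site_model_fit` (typically the M7 fit when fitting
#'   M8) used as an extra start.
#' @param extra_starts additional deterministic starting points (list of
#'   numeric vectors).
#' @return list of class `site_model_fit`: `model`, `lnL`, `t`, `kappa`,
#'   `p`, `q`, `p0`, `omega_s`, `K`, `converged`, `n_codons`.
#' @export
fit_site_model <- function(aln, model = c("M7", "M8"), K = 10L, init = NULL,
                           extra_starts = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(aln, "codon_alignment"))
  pat <- codon_patterns(aln)
  lower <- c(1e-4, 0.1, 0.05, 0.05); upper <- c(20, 20, 50, 50)
  starts <- list(c(0.3, 2, 0.5, 1.5), c(1, 1, 2, 2))
  if (model == "M8") {
    lower <- c(lower, 0, 1); upper <- c(upper, 1, 20)
    starts <- lapply(starts, function(s) c(s, 0.9, 2))
    if (!is.null(init) && init$model == "M7") {
      # nesting start: M8 at p0 = 1 equals the M7 fit exactly
      starts <- c(list(c(init$t, init$kappa, init$p, init$q, 1, 1.5),
                       c(init$t, init$kappa, init$p, init$q, 0.8, 2)),
                  starts)
    }
  } else if (!is.null(init)) {
    starts <- c(list(c(init$t, init$kappa, init$p, init$q)), starts)
  }
  if (!is.null(extra_starts)) starts <- c(starts, extra_starts)
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower), upper)
    fit <- tryCatch(
      optim(s, function(par) -pair_loglik(par, model, pat, K),
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 300, factr = 1e9,
                           parscale = pmax(abs(s), 0.1))),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("site-model optimization failed on all starts")
  par <- best$par
  structure(list(model = model, lnL = -best$value, t = par[1],
                 kappa = par[2], p = par[3], q = par[4],
                 p0 = if (model == "M8") par[5] else 1,
                 omega_s = if (model == "M8") par[6] else NA_real_,
                 K = K, converged = best$convergence == 0,
                 n_codons = pat$n_sites, patterns = pat),
            class = "site_model_fit")
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL=%.4f t=%.3f kappa=%.2f p=%.3f q=%.3f", x$model,
              x$lnL, x$t, x$kappa, x$p, x$q))
  if (x$model == "M8")
    cat(sprintf(" p0=%.3f omega_s=%.2f", x$p0, x$omega_s))
  cat(if (x$converged) " (converged)\n" else " (not converged)\n")
  invisible(x)
}
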