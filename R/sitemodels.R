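# Codon site-class model fitting (M0, M1a, M2a, M7, M8), likelihood ratio
# tests, naive empirical Bayes site classification, and a FEL-style
# fixed-effects per-site scan.

MODEL_IDS <- c("M0", "M1a", "M2a", "M7", "M8")

# discretise a beta(p, q) into ncat equal-probability categories (means
# approximated by the category-midpoint quantiles)
beta_categories <- function(p, q, ncat = 10L) {
  qbeta((2 * seq_len(ncat) - 1) / (2 * ncat), p, q)
}

# model parameter space: names, bounds, fixed deterministic starts
.model_space <- function(model, ncat_beta) {
  switch(model,
    M0 = list(
      names = c("kappa", "omega"),
      lower = c(0.1, 1e-4), upper = c(20, 50),
      starts = list(c(2, 0.3), c(4, 1.2), c(1, 0.05)),
      classes = function(par, ncat) list(omegas = par[["omega"]], weights = 1)),
    M1a = list(
      names = c("kappa", "p0", "omega0"),
      lower = c(0.1, 1e-6, 1e-4), upper = c(20, 1 - 1e-6, 0.999),
      starts = list(c(2, 0.7, 0.2), c(4, 0.5, 0.05), c(1, 0.9, 0.5)),
      classes = function(par, ncat)
        list(omegas = c(par[["omega0"]], 1),
             weights = c(par[["p0"]], 1 - par[["p0"]]))),
    M2a = list(
      names = c("kappa", "p0", "p2frac", "omega0", "omega2"),
      lower = c(0.1, 1e-6, 1e-6, 1e-4, 1 + 1e-6),
      upper = c(20, 1 - 1e-6, 1 - 1e-6, 0.999, 50),
      starts = list(c(2, 0.7, 0.3, 0.2, 3), c(4, 0.5, 0.1, 0.05, 8),
                    c(1, 0.85, 0.5, 0.4, 1.5)),
      classes = function(par, ncat) {
        p0 <- par[["p0"]]; p2 <- (1 - p0) * par[["p2frac"]]
        list(omegas = c(par[["omega0"]], 1, par[["omega2"]]),
             weights = c(p0, 1 - p0 - p2, p2))
      }),
    M7 = list(
      names = c("kappa", "p", "q"),
      lower = c(0.1, 0.005, 0.005), upper = c(20, 99, 99),
      starts = list(c(2, 0.5, 1.5), c(4, 2, 2), c(1, 0.2, 0.5)),
      classes = function(par, ncat)
        list(omegas = beta_categories(par[["p"]], par[["q"]], ncat),
             weights = rep(1 / ncat, ncat))),
    M8 = list(
      names = c("kappa", "p", "q", "p0", "omegas"),
      lower = c(0.1, 0.005, 0.005, 1e-6, 1 + 1e-6),
      upper = c(20, 99, 99, 1 - 1e-6, 50),
      starts = list(c(2, 0.5, 1.5, 0.9, 3), c(4, 2, 2, 0.7, 8),
                    c(1, 0.2, 0.5, 0.95, 1.5)),
      classes = function(par, ncat) {
        w <- beta_categories(par[["p"]], par[["q"]], ncat)
        list(omegas = c(w, par[["omegas"]]),
             weights = c(rep(par[["p0"]] / ncat, ncat), 1 - par[["p0"]]))
      }),
    stop("unknown model: ", model))
}

#' Fit a codon site-class model by maximum likelihood
#'
#' Bounded quasi-Newton (nlminb) maximisation of the mixture likelihood over
#' the model parameters and kappa, from several fixed starting points to
#' mitigate local optima. Branch lengths are taken from the input tree and,
#' by default, rescaled by a jointly estimated factor (so a
#' nucleotide-substitution NJ tree can be converted to substitutions/codon
#' in the fit itself); set `optimize_scale = FALSE` to use them as given.
#'
#' @param aln a [codon_alignment()] (or named character vector).
#' @param tree `ape::phylo` with branch lengths, tips matching the alignment.
#' @param model one of `"M0"`, `"M1a"`, `"M2a"`, `"M7"`, `"M8"`.
#' @param pi codon frequencies; default F3x4 from the alignment.
#' @param optimize_scale jointly estimate a branch-length scale factor
#'   (default); with `FALSE` the branch lengths (times `fixed_scale`) are
#'   used as given, the fixed-input-tree workflow.
#' @param fixed_scale branch-length multiplier used when
#'   `optimize_scale = FALSE` (e.g. the scale of an M0 pre-fit).
#' @param n_starts number of fixed starting points (1-3).
#' @param init optional named vector of model parameters used as an
#'   additional warm start (e.g. the MLE of a nested null model).
#' @param ncat_beta categories for the discretised beta of M7/M8.
#' @param control passed to [stats::nlminb()].
#' @return a `site_model_fit`: list with `model`, `loglik`, `params`
#'   (named MLEs incl. `scale`), `omegas`, `weights`, `pi`, `convergence`.
#' @export
fit_site_model <- function(aln, tree, model = "M1a", pi = NULL,
                           optimize_scale = TRUE, fixed_scale = 1,
                           n_starts = 3L, init = NULL, ncat_beta = 10L,
                           control = list(rel.tol = 1e-8)) {
  model <- match.arg(model, MODEL_IDS)
  if (!inherits(aln, "codon_alignment")) aln <- codon_alignment(aln)
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  ctx <- loglik_context(aln, tree, pi)
  sp <- .model_space(model, ncat_beta)
  nm <- sp$names; lower <- sp$lower; upper <- sp$upper
  if (optimize_scale) {
    nm <- c(nm, "scale"); lower <- c(lower, 1e-3); upper <- c(upper, 100)
  }
  obj <- function(par) {
    names(par) <- nm
    cl <- sp$classes(par, ncat_beta)
    sc <- if (optimize_scale) par[["scale"]] else fixed_scale
    ll <- tryCatch(
      .ctx_loglik(ctx, par[["kappa"]], cl$omegas, cl$weights, scale = sc),
      error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- sp$starts[seq_len(min(n_starts, length(sp$starts)))]
  if (!is.null(init)) {
    iv <- vapply(sp$names, function(p)
      if (p %in% names(init)) unname(init[[p]]) else NA_real_, numeric(1))
    # fill gaps from the first fixed start, clip into bounds
    iv[is.na(iv)] <- sp$starts[[1]][is.na(iv)]
    iv <- pmin(pmax(iv, sp$lower + 1e-8), sp$upper - 1e-8)
    starts <- c(list(iv), starts)
  }
  best <- NULL
  fits <- list()
  for (s in seq_along(starts)) {
    start <- starts[[s]]
    if (optimize_scale)
      start <- c(start, if (!is.null(init) && "scale" %in% names(init) && s == 1L)
        unname(init[["scale"]]) else 1)
    f <- nlminb(start, obj, lower = lower, upper = upper, control = control)
    fits[[s]] <- f
    if (is.null(best) || f$objective < best$objective) best <- f
  }
  if (is.null(best) || !is.finite(best$objective))
    stop("site-model fit failed to converge for ", model)
  par <- setNames(best$par, nm)
  cl <- sp$classes(par, ncat_beta)
  structure(list(model = model, loglik = -best$objective, params = par,
                 omegas = cl$omegas, weights = cl$weights, pi = pi,
                 tree = tree, ncat_beta = ncat_beta,
                 scale = if (optimize_scale) par[["scale"]] else fixed_scale,
                 convergence = best$convergence,
                 n_starts = length(fits)),
            class = "site_model_fit")
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat("<site_model_fit> ", x$model, "  lnL = ", sprintf("%.4f", x$loglik),
      "\n", sep = "")
  print(signif(x$params, 4))
  invisible(x)
}

#' Likelihood ratio test between nested site models
#'
#' Statistic 2(lnL_alt - lnL_null), clamped at zero, against chi-squared
#' with 2 degrees of freedom (the two extra parameters of the
#' positive-selection class).
#'
#' @param null_fit,alt_fit `site_model_fit`s; the pair must be M1a/M2a or
#'   M7/M8.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(null_fit, alt_fit) {
  pair <- paste(null_fit$model, alt_fit$model)
  if (!pair %in% c("M1a M2a", "M7 M8"))
    stop("models are not a supported nested pair: ", pair)
  stat <- max(0, 2 * (alt_fit$loglik - null_fit$loglik))
  list(statistic = stat, df = 2L,
       p_value = pchisq(stat, df = 2L, lower.tail = FALSE))
}

#' Run a null/alternative site-model pair with the fixed-tree workflow
#'
#' Mirrors the standard codeml usage on an input NJ tree: a single-omega
#' (M0) pre-fit estimates kappa-independent branch scaling, then the null
#' and alternative site models are fitted with branch lengths fixed at that
#' scale (the alternative warm-started from the null's MLEs) and compared
#' by [lrt()].
#'
#' @inheritParams fit_site_model
#' @param pair `c("M1a", "M2a")` or `c("M7", "M8")`.
#' @return list with `m0`, `null`, `alt`, `lrt`.
#' @export
positive_selection_test <- function(aln, tree, pair = c("M1a", "M2a"),
                                    pi = NULL, n_starts = 3L,
                                    ncat_beta = 10L) {
  if (!inherits(aln, "codon_alignment")) aln <- codon_alignment(aln)
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  # the warm start counts as one of the n_starts starting points
  m0 <- fit_site_model(aln, tree, "M0", pi = pi, n_starts = n_starts)
  null <- fit_site_model(aln, tree, pair[1], pi = pi,
                         optimize_scale = FALSE, fixed_scale = m0$scale,
                         n_starts = max(1L, n_starts - 1L),
                         ncat_beta = ncat_beta,
                         init = c(kappa = unname(m0$params[["kappa"]])))
  alt <- fit_site_model(aln, tree, pair[2], pi = pi,
                        optimize_scale = FALSE, fixed_scale = m0$scale,
                        n_starts = max(1L, n_starts - 1L),
                        ncat_beta = ncat_beta,
                        init = null$params)
  list(m0 = m0, null = null, alt = alt, lrt = lrt(null, alt))
}

#' Naive empirical Bayes site classification
#'
#' Per-site posterior probability of each omega class at the MLEs:
#' posterior(c | site) is proportional to weight_c times the site likelihood
#' under omega_c. Sites with posterior > `threshold` in the
#' positive-selection class (the last class, omega > 1) are flagged.
#' Anti-conservative when parameter estimates are poor (no integration over
#' parameter uncertainty).
#'
#' @param fit a `site_model_fit` for M2a or M8.
#' @param aln,tree data the fit was produced from.
#' @param threshold posterior probability threshold for flagging.
#' @return data.frame with one row per codon site: `site`, one posterior
#'   column per class (`post_1`, ...), `post_positive`, `flagged`.
#' @export
neb_sites <- function(fit, aln, tree, threshold = 0.95) {
  if (!fit$model %in% c("M2a", "M8"))
    stop("site classification requires an M2a or M8 fit")
  if (!inherits(aln, "codon_alignment")) aln <- codon_alignment(aln)
  cs <- class_site_loglik(aln, tree, fit$params[["kappa"]], fit$omegas,
                          fit$weights, fit$pi, scale = fit$scale)
  lw <- log(fit$weights)
  post <- t(apply(cs$loglik, 1L, function(r) {
    z <- r + lw; z <- exp(z - max(z)); z / sum(z)
  }))
  post <- post[cs$pattern_of_site, , drop = FALSE]
  pos <- post[, ncol(post)]
  out <- data.frame(site = seq_len(nrow(post)))
  for (c1 in seq_len(ncol(post))) out[[paste0("post_", c1)]] <- post[, c1]
  out$post_positive <- pos
  out$flagged <- pos > threshold
  out
}

#' FEL-style fixed-effects per-site selection scan
#'
#' Global kappa and branch-length scale are estimated once under a
#' single-omega (M0) fit; then for each codon site the site likelihood is
#' maximised over separate synonymous (alpha) and nonsynonymous (beta)
#' rates and compared by LRT (df = 1) with the constrained alpha = beta
#' model. A site is flagged positively selected iff p < `alpha_level` and
#' beta_hat > alpha_hat (one-sided).
#'
#' @param aln a [codon_alignment()] (or named character vector).
#' @param tree `ape::phylo` with branch lengths.
#' @param alpha_level significance threshold.
#' @param m0 optional precomputed M0 `site_model_fit`.
#' @return data.frame with `site`, `alpha`, `beta`, `statistic`, `p_value`,
#'   `flagged`, `excluded` (all-gap sites).
#' @export
fel_scan <- function(aln, tree, alpha_level = 0.05, m0 = NULL) {
  if (!inherits(aln, "codon_alignment")) aln <- codon_alignment(aln)
  if (is.null(m0)) m0 <- fit_site_model(aln, tree, "M0")
  pi <- m0$pi; kappa <- m0$params[["kappa"]]
  # Per-site generator alpha * Q_syn + beta * Q_nonsyn in units where
  # alpha = beta = 1 gives one expected substitution/codon.  codon_loglik()
  # normalises its matrix by the expected rate mu(omega), so the site
  # likelihood at (alpha, beta) equals an omega = beta/alpha evaluation with
  # branch lengths rescaled by alpha * mu(omega) / mu(1).
  support <- which(pi > 0)
  pis <- pi[support] / sum(pi[support])
  mu_of <- function(w) {
    Q <- build_codon_Q(kappa, w, pi)[support, support, drop = FALSE]
    diag(Q) <- 0; diag(Q) <- -rowSums(Q)
    -sum(pis * diag(Q))
  }
  mu_ref <- mu_of(1)
  site_ll <- function(site_aln, alpha, beta) {
    if (alpha <= 0) return(-Inf)
    w <- beta / alpha
    tryCatch(
      codon_loglik(site_aln, tree, kappa, w, 1, pi,
                   scale = m0$scale * alpha * mu_of(w) / mu_ref),
      error = function(e) -Inf)
  }
  n <- aln$n_codon
  out <- data.frame(site = seq_len(n), alpha = NA_real_, beta = NA_real_,
                    statistic = NA_real_, p_value = NA_real_,
                    flagged = FALSE, excluded = FALSE)
  for (s in seq_len(n)) {
    idx <- aln$codon_idx[, s, drop = FALSE]
    if (all(is.na(idx))) { out$excluded[s] <- TRUE; next }
    sub <- structure(list(codon_idx = idx, n_seq = aln$n_seq, n_codon = 1L,
                          names = aln$names), class = "codon_alignment")
    null <- optimize(function(r) -site_ll(sub, r, r), c(1e-6, 50))
    alt <- nlminb(c(max(null$minimum, 0.01), max(null$minimum, 0.01)),
                  function(p) -site_ll(sub, p[1], p[2]),
                  lower = c(1e-6, 1e-6), upper = c(50, 50))
    stat <- max(0, 2 * (-alt$objective - (-null$objective)))
    p <- pchisq(stat, df = 1L, lower.tail = FALSE)
    out$alpha[s] <- alt$par[1]; out$beta[s] <- alt$par[2]
    out$statistic[s] <- stat; out$p_value[s] <- p
    out$flagged[s] <- (p < alpha_level) && (alt$par[2] > alt$par[1])
  }
  out
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha nominal family-wise level, in (0, 1).
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1)
  if (m < 1) stop("m must be >= 1")
  alpha / m
}
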