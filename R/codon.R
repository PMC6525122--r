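# GY94-style codon substitution machinery: universal code over the 61 sense
# codons, F3x4 equilibrium frequencies, rate-matrix eigensystems, the
# site-class mixture likelihood (pruning kernel in compiled code), and a
# forward simulator used for parameter-recovery and calibration studies.

.codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  all64 <- sort(all64)
  gc <- Biostrings::GENETIC_CODE
  sense <- all64[gc[all64] != "*"]
  K <- length(sense)  # 61
  aa <- unname(gc[sense])
  # classify single-nucleotide changes
  is_ts <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  cmat <- do.call(rbind, strsplit(sense, ""))
  type <- matrix(0L, K, K)  # 0 none; 1 syn ts; 2 syn tv; 3 nonsyn ts; 4 nonsyn tv
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    d <- which(cmat[i, ] != cmat[j, ])
    if (length(d) != 1L) next
    ts <- is_ts(cmat[i, d], cmat[j, d])
    syn <- aa[i] == aa[j]
    type[i, j] <- if (syn && ts) 1L else if (syn) 2L else if (ts) 3L else 4L
  }
  .codon_env$tab <- list(codons = sense, aa = aa, type = type, K = K)
  .codon_env$tab
}

#' Codon alignment container
#'
#' @param sequences named character vector of aligned, in-frame nucleotide
#'   sequences (equal lengths divisible by 3). Codons containing characters
#'   other than A/C/G/T (gaps, N) are treated as missing data; internal stop
#'   codons are rejected.
#' @return a `codon_alignment`: list with `codon_idx` (N x L matrix of
#'   1-based indices into the 61 sense codons, NA = missing), `n_seq`,
#'   `n_codon`, `names`.
#' @export
codon_alignment <- function(sequences) {
  stopifnot(length(sequences) >= 1L)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  n <- unique(nchar(sequences))
  if (length(n) != 1L) stop("sequences must be aligned (equal lengths)")
  if (n %% 3L != 0L) stop("alignment length not divisible by 3")
  tab <- codon_tables()
  L <- n / 3L
  idx <- t(vapply(sequences, function(s) {
    cods <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    cods <- toupper(cods)
    i <- match(cods, tab$codons)
    stop_hit <- cods %in% STOP_CODONS
    if (any(stop_hit))
      stop("internal stop codon at codon position ", which(stop_hit)[1])
    i[!grepl("^[ACGT]{3}$", cods)] <- NA_integer_
    i
  }, integer(L)))
  if (L == 1L) idx <- matrix(idx, ncol = 1L)
  structure(list(codon_idx = idx, n_seq = length(sequences), n_codon = L,
                 names = names(sequences)), class = "codon_alignment")
}

#' F3x4 codon equilibrium frequencies
#'
#' Position-specific nucleotide frequencies (codon positions 1-3) multiplied
#' per codon, stop codons excluded, renormalised to sum 1 over the 61 sense
#' codons.
#'
#' @param aln a [codon_alignment()] or named character vector of sequences.
#' @return numeric vector of length 61 (named by codon) summing to 1.
#' @export
f3x4_frequencies <- function(aln) {
  if (!inherits(aln, "codon_alignment")) aln <- codon_alignment(aln)
  tab <- codon_tables()
  cods <- tab$codons[aln$codon_idx[!is.na(aln$codon_idx)]]
  if (length(cods) == 0L) stop("no codons in alignment")
  pos_freq <- lapply(1:3, function(p) {
    b <- substr(cods, p, p)
    f <- table(factor(b, levels = c("A", "C", "G", "T")))
    as.numeric(f) / sum(f)
  })
  bases <- c("A", "C", "G", "T")
  pi <- vapply(tab$codons, function(cd) {
    prod(vapply(1:3, function(p) pos_freq[[p]][match(substr(cd, p, p), bases)],
                numeric(1)))
  }, numeric(1))
  if (sum(pi) <= 0) stop("all codon frequencies are zero")
  pi / sum(pi)
}

# GY94 rate matrix for one omega class (unscaled, diagonal set)
build_codon_Q <- function(kappa, omega, pi) {
  tab <- codon_tables()
  R <- matrix(0, tab$K, tab$K)
  R[tab$type == 1L] <- kappa
  R[tab$type == 2L] <- 1
  R[tab$type == 3L] <- kappa * omega
  R[tab$type == 4L] <- omega
  Q <- R * rep(pi, each = tab$K)  # q_ij = r_ij * pi_j
  diag(Q) <- -rowSums(Q)
  Q
}

# eigensystem of a reversible Q via symmetrisation; zero-frequency codons
# are dropped from the state space (they are unreachable at stationarity).
# Eigensystems of the UNSCALED per-class matrices depend only on
# (kappa, omega, pi); the class-weighted rate normalisation only rescales
# eigenvalues, so decompositions are memoised across optimiser evaluations
# (the cache is reset whenever pi changes).
codon_eigen_system <- function(kappa, omegas, weights, pi) {
  if (!identical(.codon_env$cache_pi, pi)) {
    .codon_env$eigcache <- new.env(parent = emptyenv())
    .codon_env$cache_pi <- pi
  }
  cache <- .codon_env$eigcache
  support <- which(pi > 0)
  pis <- pi[support] / sum(pi[support])
  sq <- sqrt(pis)
  one_class <- function(w) {
    key <- sprintf("%.17g|%.17g", kappa, w)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    Q <- build_codon_Q(kappa, w, pi)[support, support, drop = FALSE]
    diag(Q) <- 0; diag(Q) <- -rowSums(Q)
    Sym <- Q * (sq %o% (1 / sq))
    Sym <- (Sym + t(Sym)) / 2
    e <- eigen(Sym, symmetric = TRUE)
    out <- list(U = e$vectors / sq,            # diag(1/sq) %*% V
                Uinv = t(e$vectors * sq),      # t(V) %*% diag(sq)
                lambda = e$values,
                rho = -sum(pis * diag(Q)))
    n <- get0("..n", envir = cache, ifnotfound = 0L)
    if (n > 512L) {                            # bound the memo
      rm(list = ls(cache), envir = cache)
      n <- 0L
    }
    assign("..n", n + 1L, envir = cache)
    cache[[key]] <- out
    out
  }
  es <- lapply(omegas, one_class)
  rho <- vapply(es, `[[`, numeric(1), "rho")
  mu <- sum(weights * rho)
  if (mu <= 0) stop("degenerate rate matrix (zero expected rate)")
  # fold the normalisation into the eigenvalues
  es <- lapply(es, function(e) list(U = e$U, Uinv = e$Uinv,
                                    lambda = e$lambda / mu))
  list(eigens = es, support = support, pis = pis, mu = mu)
}

# map alignment to compressed site patterns over the support state space
.pattern_data <- function(aln, support) {
  idx <- aln$codon_idx
  remap <- match(idx, support)  # index within support, NA if gap or off-support
  if (any(!is.na(idx) & is.na(remap)))
    stop("alignment contains a codon with zero equilibrium frequency")
  m <- matrix(remap, nrow = nrow(idx))
  m[is.na(m)] <- 0L
  key <- apply(m, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[first])))
  list(tips = m[, first, drop = FALSE] - 1L, weights = w,
       pattern_of_site = match(key, key[first]))
}

# postorder edge list with tips ordered to match the alignment
.tree_data <- function(aln, tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (!setequal(tree$tip.label, aln$names))
    stop("tree tip labels must match alignment sequence names")
  tr <- ape::reorder.phylo(tree, "postorder")
  perm <- match(tr$tip.label, aln$names)
  list(edge = tr$edge, edge_len = tr$edge.length, tip_perm = perm,
       n_node = tr$Nnode)
}

# precomputed likelihood context: site patterns + postorder tree data, so
# repeated evaluations during optimisation do not redo the bookkeeping
loglik_context <- function(aln, tree, pi) {
  support <- which(pi > 0)
  pd <- .pattern_data(aln, support)
  if (aln$n_seq > 1L) {
    td <- .tree_data(aln, tree)
    tips <- pd$tips[td$tip_perm, , drop = FALSE]
  } else {
    td <- list(edge = matrix(0L, 0L, 2L), edge_len = numeric(), n_node = 0L)
    tips <- pd$tips
  }
  list(tips = tips, edge = td$edge, edge_len = td$edge_len,
       n_node = td$n_node, support = support,
       pat_weights = pd$weights, pattern_of_site = pd$pattern_of_site,
       n_seq = aln$n_seq, pi = pi)
}

# per-pattern, per-class log-likelihood matrix from a context
.ctx_class_loglik <- function(ctx, kappa, omegas, weights, scale = 1) {
  sys <- codon_eigen_system(kappa, omegas, weights, ctx$pi)
  if (ctx$n_seq == 1L) {
    ll <- vapply(seq_len(ncol(ctx$tips)), function(s) {
      st <- ctx$tips[1L, s]
      if (st < 0L) 0 else log(sys$pis[st + 1L])
    }, numeric(1))
    lmat <- matrix(rep(ll, length(omegas)), ncol = length(omegas))
  } else {
    res <- .codon_class_loglik_cpp(ctx$tips, ctx$edge, ctx$edge_len * scale,
                                   sys$eigens, sys$pis, ctx$n_node)
    lmat <- do.call(cbind, res)
  }
  lmat
}

.ctx_loglik <- function(ctx, kappa, omegas, weights, scale = 1) {
  lmat <- .ctx_class_loglik(ctx, kappa, omegas, weights, scale)
  lw <- log(weights)
  site_ll <- apply(lmat, 1L, function(r) {
    m <- max(r + lw)
    m + log(sum(exp(r + lw - m)))
  })
  sum(site_ll * ctx$pat_weights)
}

# per-pattern, per-class log-likelihood matrix (patterns x classes)
class_site_loglik <- function(aln, tree, kappa, omegas, weights, pi,
                              scale = 1) {
  ctx <- loglik_context(aln, tree, pi)
  list(loglik = .ctx_class_loglik(ctx, kappa, omegas, weights, scale),
       weights = ctx$pat_weights,
       pattern_of_site = ctx$pattern_of_site)
}

#' Codon site-class mixture log-likelihood
#'
#' GY94-style model: single-nucleotide codon changes at relative rate
#' kappa^(transition) * omega^(nonsynonymous) * pi_target, the matrix scaled
#' so the class-weighted expected rate is one substitution per codon. The
#' per-site likelihood is the weighted mixture over omega classes of the
#' pruning likelihood; gap codons contribute unit partial likelihoods.
#'
#' @param aln a [codon_alignment()].
#' @param tree an `ape::phylo` with branch lengths (substitutions/codon) and
#'   tip labels matching the alignment names.
#' @param kappa transition/transversion rate ratio.
#' @param omegas numeric vector of dN/dS values, one per class.
#' @param weights class probabilities (non-negative, summing to 1).
#' @param pi codon equilibrium frequencies (length 61), e.g. from
#'   [f3x4_frequencies()].
#' @param scale multiplier applied to all branch lengths.
#' @return total log-likelihood (numeric scalar).
#' @export
codon_loglik <- function(aln, tree, kappa, omegas, weights, pi, scale = 1) {
  stopifnot(length(omegas) == length(weights),
            abs(sum(weights) - 1) < 1e-8, all(weights >= 0))
  if (!inherits(aln, "codon_alignment")) aln <- codon_alignment(aln)
  ctx <- loglik_context(aln, tree, pi)
  total <- .ctx_loglik(ctx, kappa, omegas, weights, scale)
  if (!is.finite(total)) stop("non-finite log-likelihood")
  total
}

#' Simulate a codon alignment under a site-class model
#'
#' Sites draw an omega class from `weights`; the root codon is drawn from
#' `pi` and evolved along the tree under the class's GY94 matrix (scaled as
#' in [codon_loglik()]).
#'
#' @inheritParams codon_loglik
#' @param n_codon number of codons.
#' @param seed RNG seed.
#' @return named character vector of sequences (one per tip), with the true
#'   per-site class in `attr(, "site_class")`.
#' @export
simulate_codon_alignment <- function(tree, n_codon, kappa, omegas, weights,
                                     pi, seed = 1L, scale = 1) {
  sys <- codon_eigen_system(kappa, omegas, weights, pi)
  tab <- codon_tables()
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  root <- n_tip + 1L
  K <- length(sys$support)
  with_seed(seed, {
    classes <- sample(seq_along(omegas), n_codon, replace = TRUE,
                      prob = weights)
    states <- matrix(NA_integer_, n_tip + tr$Nnode, n_codon)
    states[root, ] <- sample.int(K, n_codon, replace = TRUE, prob = sys$pis)
    # preorder = reverse postorder edges
    Pmats <- lapply(seq_along(omegas), function(c1) {
      lapply(seq_len(nrow(tr$edge)), function(e) {
        es <- sys$eigens[[c1]]
        P <- es$U %*% diag(exp(es$lambda * tr$edge.length[e] * scale)) %*% es$Uinv
        P[P < 0] <- 0
        P / rowSums(P)
      })
    })
    for (e in rev(seq_len(nrow(tr$edge)))) {
      par <- tr$edge[e, 1L]; chl <- tr$edge[e, 2L]
      for (s in seq_len(n_codon)) {
        P <- Pmats[[classes[s]]][[e]]
        states[chl, s] <- sample.int(K, 1L, prob = P[states[par, s], ])
      }
    }
    seqs <- vapply(seq_len(n_tip), function(i)
      paste(tab$codons[sys$support[states[i, ]]], collapse = ""), character(1))
    names(seqs) <- tr$tip.label
    attr(seqs, "site_class") <- classes
    seqs
  })
}
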