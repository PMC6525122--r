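# Distance-based DQB phylogeny and locus assignment.  K80 distances with
# pairwise deletion, neighbour-joining (ape) with negative branch lengths
# clamped, nonparametric bootstrap over alignment columns, and assignment of
# query alleles to the locus whose reference clade contains them across
# replicates.

#' Kimura two-parameter (K80) distance
#'
#' Positions where either sequence has a gap or N are excluded pairwise, so
#' exon-2-only fragments remain comparable with full-length alleles.
#'
#' @param seq1,seq2 equal-length aligned sequences.
#' @return list with `d` (substitutions/site), `P` (transition proportion),
#'   `Q` (transversion proportion), `n_sites` (included positions).
#' @export
k80_distance <- function(seq1, seq2) {
  a <- strsplit(toupper(seq1), "")[[1]]
  b <- strsplit(toupper(seq2), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n == 0L) stop("no comparable positions")
  diff <- a != b
  ts <- diff & ((a == "A" & b == "G") | (a == "G" & b == "A") |
                  (a == "C" & b == "T") | (a == "T" & b == "C"))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
    stop("saturated pair (P=", signif(P, 4), ", Q=", signif(Q, 4),
         "): K80 distance undefined")
  d <- 0.5 * log(1 / (1 - 2 * P - Q)) + 0.25 * log(1 / (1 - 2 * Q))
  list(d = d, P = P, Q = Q, n_sites = n)
}

#' Pairwise K80 distance matrix
#'
#' @param sequences named character vector of aligned sequences.
#' @return symmetric matrix of distances with zero diagonal.
#' @export
k80_matrix <- function(sequences) {
  n <- length(sequences)
  labs <- names(sequences)
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  if (n < 2L) return(m)
  for (i in 2:n) for (j in 1:(i - 1L)) {
    d <- tryCatch(k80_distance(sequences[[i]], sequences[[j]])$d,
                  error = function(e)
                    stop("saturated pair: ", labs[i], " vs ", labs[j],
                         call. = FALSE))
    m[i, j] <- m[j, i] <- d
  }
  m
}

#' Neighbour-joining tree with clamped branch lengths
#'
#' Standard Saitou-Nei agglomeration (via `ape::nj`); negative branch
#' lengths, which NJ can produce on non-additive matrices, are clamped to
#' zero with the deficit moved to the sister edge so path lengths are
#' approximately preserved.
#'
#' @param m symmetric distance matrix with labels (>= 3 taxa).
#' @return an unrooted `ape::phylo`.
#' @export
nj_tree <- function(m) {
  if (nrow(m) < 3L) stop("neighbour-joining needs at least 3 taxa")
  tr <- ape::nj(as.dist(m))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1L]
    sisters <- which(tr$edge[, 1L] == parent & seq_len(nrow(tr$edge)) != e)
    if (length(sisters))
      tr$edge.length[sisters[1L]] <- max(0, tr$edge.length[sisters[1L]] + deficit)
  }
  tr
}

# leaf-label sets on both sides of every internal edge of an unrooted tree
.edge_sides <- function(tree) {
  labs <- tree$tip.label
  n_tip <- length(labs)
  desc <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- labs[i]
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1L]; c1 <- edges[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[c1]])
  }
  sides <- list()
  for (e in seq_len(nrow(edges))) {
    s <- desc[[edges[e, 2L]]]
    sides[[length(sides) + 1L]] <- s
    sides[[length(sides) + 1L]] <- setdiff(labs, s)
  }
  sides
}

# smallest side containing all of `members`; NULL only if tree is degenerate
.min_side_containing <- function(sides, members) {
  ok <- Filter(function(s) all(members %in% s), sides)
  if (length(ok) == 0L) return(NULL)
  ok[[which.min(lengths(ok))]]
}

#' Bootstrap support for a neighbour-joining tree
#'
#' Columns of the alignment are resampled with replacement `B` times, an NJ
#' tree is built from K80 distances on each replicate, and the proportion of
#' replicates containing each bipartition of the full-data tree is recorded.
#'
#' @param alignment named character vector of aligned sequences.
#' @param B number of replicates (>= 1).
#' @param seed RNG seed.
#' @return the full-data `nj_tree` with `node.label` support fractions on
#'   internal nodes.
#' @export
bootstrap_support <- function(alignment, B = 200L, seed = 1L) {
  if (B < 1L) stop("B must be >= 1")
  cols <- nchar(alignment[[1]])
  if (cols < 2L) stop("alignment must have at least 2 columns")
  full <- nj_tree(k80_matrix(alignment))
  mat <- do.call(rbind, strsplit(unname(alignment), ""))
  rownames(mat) <- names(alignment)
  reps <- with_seed(seed, lapply(seq_len(B), function(b) {
    idx <- sample.int(cols, cols, replace = TRUE)
    seqs <- apply(mat[, idx, drop = FALSE], 1L, paste, collapse = "")
    tryCatch(nj_tree(k80_matrix(seqs)), error = function(e) NULL)
  }))
  reps <- Filter(Negate(is.null), reps)
  part <- ape::prop.part(reps)
  support <- ape::prop.clades(full, part = part, rooted = FALSE) / length(reps)
  full$node.label <- support
  full
}

#' Assign query alleles to loci by bootstrap clade membership
#'
#' For each bootstrap replicate an NJ/K80 tree of references plus queries is
#' built; a query votes for a locus when it falls inside the smallest
#' bipartition side containing all of that locus's references (and votes for
#' no locus when it falls in none or several). The final assignment is the
#' majority locus across replicates with its vote fraction as support;
#' support below 0.5 yields `"unassigned"`. If a locus's references are not
#' separated on the full-data tree (its minimal side contains another
#' locus's references), assignment falls back to nearest mean K80 distance
#' with a warning and a flag.
#'
#' @param queries named character vector of aligned query sequences.
#' @param references named list: locus -> named character vector of aligned
#'   reference sequences (>= 2 per locus), all aligned with the queries.
#' @param B bootstrap replicates.
#' @param seed RNG seed.
#' @param min_overlap queries overlapping fewer aligned positions than this
#'   with any reference are flagged `low_confidence` (exon-2-only fragments
#'   lack the region where signal is strongest).
#' @return data.frame with `query`, `locus`, `support`, `method`,
#'   `low_confidence`.
#' @export
assign_locus <- function(queries, references, B = 200L, seed = 1L,
                         min_overlap = NULL) {
  if (any(lengths(references) < 2L))
    stop("need at least 2 reference alleles per candidate locus")
  ref_flat <- unlist(unname(lapply(names(references), function(l)
    setNames(references[[l]], names(references[[l]])))))
  all_seq <- c(ref_flat, queries)
  if (anyDuplicated(names(all_seq)))
    stop("duplicate sequence names across references and queries")
  loci <- names(references)
  full <- nj_tree(k80_matrix(all_seq))
  sides_full <- .edge_sides(full)
  monophyletic <- vapply(loci, function(l) {
    side <- .min_side_containing(sides_full, names(references[[l]]))
    others <- unlist(lapply(references[setdiff(loci, l)], names))
    !is.null(side) && !any(others %in% side)
  }, logical(1))

  mat <- do.call(rbind, strsplit(unname(all_seq), ""))
  rownames(mat) <- names(all_seq)
  cols <- ncol(mat)
  votes <- matrix(0, length(queries), length(loci),
                  dimnames = list(names(queries), loci))
  n_rep <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(cols, cols, replace = TRUE)
      seqs <- apply(mat[, idx, drop = FALSE], 1L, paste, collapse = "")
      tr <- tryCatch(nj_tree(k80_matrix(seqs)), error = function(e) NULL)
      if (is.null(tr)) next
      n_rep <- n_rep + 1L
      sides <- .edge_sides(tr)
      clades <- lapply(loci, function(l)
        .min_side_containing(sides, names(references[[l]])))
      for (q in names(queries)) {
        inside <- vapply(clades, function(s) !is.null(s) && q %in% s, logical(1))
        if (sum(inside) == 1L)
          votes[q, which(inside)] <- votes[q, which(inside)] + 1
      }
    }
  })
  # pairwise overlap with references, for the fragment flag
  overlap <- vapply(names(queries), function(q) {
    min(vapply(names(ref_flat), function(r)
      k80_distance(all_seq[[q]], all_seq[[r]])$n_sites, numeric(1)))
  }, numeric(1))
  if (is.null(min_overlap)) min_overlap <- max(nchar(queries)) * 0.8

  out <- lapply(names(queries), function(q) {
    if (all(monophyletic)) {
      frac <- votes[q, ] / max(n_rep, 1L)
      best <- which.max(frac)
      data.frame(query = q,
                 locus = if (frac[best] >= 0.5) loci[best] else "unassigned",
                 support = unname(frac[best]), method = "bootstrap_clade",
                 low_confidence = overlap[q] < min_overlap,
                 stringsAsFactors = FALSE)
    } else {
      warning("reference clades not monophyletic on the full-data tree; ",
              "falling back to nearest mean K80 distance")
      md <- vapply(loci, function(l)
        mean(vapply(references[[l]], function(r)
          k80_distance(all_seq[[q]], r)$d, numeric(1))), numeric(1))
      data.frame(query = q, locus = loci[which.min(md)], support = NA_real_,
                 method = "nearest_distance", low_confidence = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}
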