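# Nei-Gojobori (1986) pairwise dN/dS: per-codon synonymous/nonsynonymous
# site counts averaged between the two sequences, codon differences resolved
# by averaging over all minimal mutational paths (paths through stop codons
# excluded), and Jukes-Cantor correction of the proportions.

# synonymous site count of one codon: at each position, the fraction of the
# three possible changes that are synonymous (changes to stops count as
# nonsynonymous)
.ng86_syn_sites <- function(codon) {
  tab <- codon_tables()
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(bases, substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- b
      if (!(alt %in% STOP_CODONS) && gc[[alt]] == gc[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

# average (syn, nonsyn) difference counts over all stop-free minimal paths
.ng86_path_diffs <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(d) == 0L) return(c(0, 0))
  perms <- if (length(d) == 1L) list(d) else {
    if (length(d) == 2L) list(d, rev(d)) else {
      p <- list()
      for (i in 1:3) for (j in setdiff(1:3, i))
        p[[length(p) + 1L]] <- d[c(i, j, setdiff(1:3, c(i, j)))]
      p
    }
  }
  step <- function(from, pos) {
    to <- from
    substr(to, pos, pos) <- substr(c2, pos, pos)
    to
  }
  walk <- function(order) {
    cur <- c1; syn <- 0; non <- 0
    for (pos in order) {
      nxt <- step(cur, pos)
      if (nxt %in% STOP_CODONS) return(NULL)
      if (gc[[cur]] == gc[[nxt]]) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    c(syn, non)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk))
  if (length(res) == 0L)  # every path blocked by a stop: count over all paths
    res <- lapply(perms, function(order) {
      cur <- c1; syn <- 0; non <- 0
      for (pos in order) {
        nxt <- step(cur, pos)
        if (gc[[cur]] == gc[[nxt]]) syn <- syn + 1 else non <- non + 1
        cur <- nxt
      }
      c(syn, non)
    })
  Reduce(`+`, res) / length(res)
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) method
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per codon (averaged
#' between the two sequences), resolves multi-step codon differences by
#' averaging over all minimal mutational paths that avoid stop codons, and
#' applies the Jukes-Cantor correction d = -3/4 ln(1 - 4p/3) to both
#' proportions. Codons containing gaps or ambiguity characters in either
#' sequence are excluded pairwise.
#'
#' @param seq1,seq2 in-frame nucleotide sequences of equal length.
#' @return list with `dN`, `dS`, `ratio` (NA when dS = 0), the raw counts
#'   `Sd`, `Nd`, `S_sites`, `N_sites`, and the uncorrected proportions
#'   `pS`, `pN`.
#' @export
ng86_dnds <- function(seq1, seq2) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2)) stop("sequences must be of equal length")
  if (nchar(seq1) %% 3L != 0L) stop("sequence length not divisible by 3")
  n <- nchar(seq1)
  starts <- seq(1L, n, 3L)
  c1 <- substring(seq1, starts, starts + 2L)
  c2 <- substring(seq2, starts, starts + 2L)
  ok <- grepl("^[ACGT]{3}$", c1) & grepl("^[ACGT]{3}$", c2) &
    !(c1 %in% STOP_CODONS) & !(c2 %in% STOP_CODONS)
  c1 <- c1[ok]; c2 <- c2[ok]
  if (length(c1) == 0L) stop("no comparable codons")
  S1 <- sum(vapply(c1, .ng86_syn_sites, numeric(1)))
  S2 <- sum(vapply(c2, .ng86_syn_sites, numeric(1)))
  S_sites <- (S1 + S2) / 2
  N_sites <- 3 * length(c1) - S_sites
  diffs <- mapply(.ng86_path_diffs, c1, c2)
  Sd <- sum(diffs[1L, ]); Nd <- sum(diffs[2L, ])
  pS <- Sd / S_sites; pN <- Nd / N_sites
  jc <- function(p) {
    if (p == 0) return(0)
    if (4 * p / 3 >= 1)
      stop("saturation: proportion ", signif(p, 4),
           " exceeds the Jukes-Cantor domain")
    -3 / 4 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS); dN <- jc(pN)
  list(dN = dN, dS = dS,
       ratio = if (dS > 0) dN / dS else NA_real_,
       Sd = Sd, Nd = Nd, S_sites = S_sites, N_sites = N_sites,
       pS = pS, pN = pN)
}
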