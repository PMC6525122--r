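# Independent test oracles, deliberately implemented with different
# machinery than the package (character sets instead of bitmasks, full
# subset enumeration, dense matrix exponentials).

# IUPAC code of a base set, via a literal table
oracle_code_of_set <- function(bases) {
  tab <- c(A = "A", C = "C", G = "G", T = "T",
           AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
           CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N")
  tab[[paste(sort(unique(bases)), collapse = "")]]
}

# positionwise set-union of unambiguous sequences
oracle_union <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  paste(apply(m, 2L, oracle_code_of_set), collapse = "")
}

# all cardinality-minimal subsets (by full enumeration over 2^n subsets)
# whose union equals the observed codes; 'N' positions ignored
oracle_explain <- function(observed, candidates, kmax = length(candidates)) {
  n <- length(candidates)
  keep <- strsplit(observed, "")[[1]] != "N"
  strip <- function(s) paste(strsplit(s, "")[[1]][keep], collapse = "")
  obs <- strip(observed)
  hits <- list()
  for (size in seq_len(min(kmax, n))) {
    for (j in seq_len(2^n - 1)) {
      members <- which(bitwAnd(j, 2^(seq_len(n) - 1L)) > 0)
      if (length(members) != size) next
      u <- strip(oracle_union(unname(candidates[members])))
      if (identical(u, obs))
        hits[[length(hits) + 1L]] <- sort(names(candidates)[members])
    }
    if (length(hits)) break
  }
  hits
}

# random unambiguous sequences
rand_seqs <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# brute-force codon mixture log-likelihood for a star/3-taxon tree via dense
# matrix exponentials and explicit summation over root states
oracle_codon_loglik <- function(tip_codons, branch_lens, kappa, omegas,
                                weights, pi) {
  tab <- ampliphase:::codon_tables()
  rho <- sapply(omegas, function(w) {
    Q <- ampliphase:::build_codon_Q(kappa, w, pi)
    -sum(pi * diag(Q))
  })
  mu <- sum(weights * rho)
  n_site <- length(tip_codons[[1]])
  total <- 0
  for (site in seq_len(n_site)) {
    mix <- 0
    for (ci in seq_along(omegas)) {
      Q <- ampliphase:::build_codon_Q(kappa, omegas[ci], pi) / mu
      P <- lapply(branch_lens, function(t) as.matrix(Matrix::expm(Q * t)))
      s <- 0
      for (root in seq_along(tab$codons)) {
        term <- pi[root]
        for (k in seq_along(tip_codons)) {
          st <- match(tip_codons[[k]][site], tab$codons)
          term <- term * P[[k]][root, st]
        }
        s <- s + term
      }
      mix <- mix + weights[ci] * s
    }
    total <- total + log(mix)
  }
  total
}

# tiny two-haplotype toy panel + database used across haplotyper tests
toy_reference <- function() {
  db <- allele_db(
    name = c("DRB1*01:01", "DRB1*02:01", "DQA1*01:01", "DQA1*02:01",
             "DQA2*01:01", "DQA2*02:01"),
    locus = c("DRB1", "DRB1", "DQA1", "DQA1", "DQA2", "DQA2"),
    sequence = with_seed(7L, {
      anc1 <- rand_seqs(1, 60); anc2 <- rand_seqs(1, 60); anc3 <- rand_seqs(1, 60)
      c(anc1, ampliphase:::mutate_string(anc1, 6L),
        anc2, ampliphase:::mutate_string(anc2, 6L),
        anc3, ampliphase:::mutate_string(anc3, 6L))
    }))
  panel <- haplotype_panel(list(
    X = list("DRB1" = "DRB1*01:01", "DQA1" = "DQA1*01:01", "DQA2" = "DQA2*01:01"),
    Y = list("DRB1" = "DRB1*02:01", "DQA1" = "DQA1*02:01", "DQA2" = "DQA2*02:01")),
    db = db)
  assays <- list(DRB1 = assay_profile("DRB1", "DRB1"),
                 DQA1 = assay_profile("DQA1", "DQA1"),
                 DQA2 = assay_profile("DQA2", "DQA2"))
  list(db = db, panel = panel, assays = assays)
}

# simulate + genotype a cohort from a panel in one step
simulate_and_call <- function(panel, db, assays, freqs, n, seed,
                              novel_allele_rate = 0) {
  sc <- sim_config(freqs, n, seed = seed,
                   novel_allele_rate = novel_allele_rate)
  pop <- sample_population(panel, sc)
  obs <- simulate_observations(pop, panel, db, assays, sc)$observations
  list(population = pop, observations = obs,
       table = genotype_population(obs, db, assays))
}
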