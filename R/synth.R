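# Synthetic-data generator: diploid individuals formed by random union of
# panel haplotypes (Hardy-Weinberg sampling), per-assay amplification and
# superposition into IUPAC consensus observations, and novel-allele
# injection at a stated divergence.  There is deliberately no sequencing
# noise model: the consumed inputs are curated consensus sequences, so
# deviations enter only through the dropout and novel-allele knobs.

# child seeds derived from one master seed by fixed enumeration, so adding
# operations does not perturb earlier draws; kept below 2^31
child_seed <- function(master, index) {
  (as.numeric(master) * 48271 + 1009 * index) %% 2147483629
}

#' Simulation configuration
#'
#' @param freqs named numeric vector of haplotype frequencies (names are
#'   panel labels; non-negative, summing to 1 within 1e-9).
#' @param n number of diploid individuals (>= 0).
#' @param seed master seed; every stochastic step derives a child seed from
#'   it by fixed enumeration.
#' @param novel_allele_rate probability that an individual carries one novel
#'   (mutated) allele in place of a panel allele.
#' @param novel_divergence substitutions separating a novel allele from its
#'   parent.
#' @param dropout_enabled honour per-assay dropout sets (TRUE) or ignore
#'   them (FALSE).
#' @export
sim_config <- function(freqs, n, seed = 1L, novel_allele_rate = 0,
                       novel_divergence = 2L, dropout_enabled = TRUE) {
  stopifnot(is.numeric(freqs), !is.null(names(freqs)), n >= 0,
            novel_allele_rate >= 0, novel_allele_rate <= 1)
  if (any(freqs < 0)) stop("negative haplotype frequency")
  if (abs(sum(freqs) - 1) > 1e-9) stop("haplotype frequencies must sum to 1")
  structure(list(freqs = freqs, n = as.integer(n), seed = seed,
                 novel_allele_rate = novel_allele_rate,
                 novel_divergence = as.integer(novel_divergence),
                 dropout_enabled = isTRUE(dropout_enabled)),
            class = "sim_config")
}

#' Sample a diploid population from a haplotype panel
#'
#' Each individual's two haplotypes are drawn independently from the
#' frequency vector (random union / Hardy-Weinberg), reproducibly for a
#' given seed.
#'
#' @param panel a [haplotype_panel()].
#' @param config a [sim_config()]; frequency names must match the panel's
#'   haplotype labels exactly.
#' @return data.frame with columns `id`, `hap1`, `hap2`.
#' @export
sample_population <- function(panel, config) {
  if (!setequal(names(config$freqs), names(panel$rows)) ||
      length(config$freqs) != length(panel$rows))
    stop("frequency vector does not match panel haplotypes")
  with_seed(child_seed(config$seed, 1L), {
    labs <- names(config$freqs)
    n <- config$n
    if (n == 0L)
      return(data.frame(id = character(), hap1 = character(),
                        hap2 = character(), stringsAsFactors = FALSE))
    h1 <- sample(labs, n, replace = TRUE, prob = config$freqs)
    h2 <- sample(labs, n, replace = TRUE, prob = config$freqs)
    data.frame(id = sprintf("ind%04d", seq_len(n)), hap1 = h1, hap2 = h2,
               stringsAsFactors = FALSE)
  })
}

#' Simulate one assay on one individual
#'
#' Collects the alleles carried on both haplotypes at the assay's loci,
#' removes dropouts, and superposes the amplified region sub-sequences into
#' an IUPAC consensus. Zero remaining alleles is a [no_product()] value;
#' unequal region lengths yield a length-conflict marker.
#'
#' @param haps character vector of the two haplotype labels.
#' @param assay an [assay_profile()].
#' @param panel,db reference panel and allele database.
#' @param dropout_enabled honour the assay's dropout set.
#' @param seq_override optional named character vector of replacement
#'   sequences (novel-allele injection), keyed by allele name.
#' @return a `mixed_sequence` or `no_product` object.
#' @export
simulate_assay <- function(haps, assay, panel, db, dropout_enabled = TRUE,
                           seq_override = NULL) {
  entries <- unique(unlist(lapply(haps, function(h)
    haplotype_alleles(panel, h, loci = assay$loci, expand_groups = FALSE))))
  if (dropout_enabled && length(entries)) {
    dropped <- vapply(entries, function(e) {
      members <- strsplit(e, "/", fixed = TRUE)[[1]]
      all(members %in% assay$dropout)
    }, logical(1))
    entries <- entries[!dropped]
  }
  if (length(entries) == 0L) return(no_product(assay$name))
  seqs <- vapply(entries, function(e) {
    first <- strsplit(e, "/", fixed = TRUE)[[1]][1]
    s <- if (!is.null(seq_override) && first %in% names(seq_override))
      seq_override[[first]] else db_sequences(db, first)
    s
  }, character(1))
  region <- vapply(seqs, function(s) assay_region_seq(assay, s), character(1))
  if (length(unique(nchar(region))) > 1L) return(mixed_length_conflict(assay$name))
  iupac_union(unique(region), assay = assay$name)
}

#' Derive a novel allele by point substitution
#'
#' Exactly `n_subs` substitutions at distinct positions of the parent
#' sequence; the result has a fresh name and `novel_unnamed` status. A pure
#' function of its inputs: the same parent, count and seed reproduce the
#' same allele.
#'
#' @param db an `allele_db`.
#' @param parent name of the parent allele.
#' @param n_subs substitution count (>= 0).
#' @param seed seed for position/base choice.
#' @param new_name optional name; default `parent.novelN`.
#' @return one-row `allele_db` (not inserted into `db`).
#' @export
mutate_allele <- function(db, parent, n_subs, seed = 1L, new_name = NULL) {
  if (n_subs < 0L) stop("negative substitution count")
  i <- match(parent, db$name)
  if (is.na(i)) stop("unknown allele: ", parent)
  seqn <- with_seed(seed, mutate_string(db$sequence[i], n_subs, frame_offset = -1L))
  if (is.null(new_name)) new_name <- paste0(parent, ".novel", n_subs)
  allele_db(name = new_name, locus = db$locus[i], sequence = seqn,
            status = "novel_unnamed", accession = NA_character_,
            full_length = db$full_length[i])
}

#' Simulate assay observations for a whole population
#'
#' For every individual and every assay, generates the consensus the assay
#' would read. With a positive `novel_allele_rate`, selected individuals
#' carry one mutated (novel) allele in place of a panel allele on their
#' first haplotype; the injected truth is recorded.
#'
#' @param population data.frame from [sample_population()].
#' @param panel,db references.
#' @param assays named list of [assay_profile()]s.
#' @param config a [sim_config()].
#' @return list with `observations` (individual -> assay -> mixed sequence /
#'   no_product) and `novel` (data.frame of injected novel alleles).
#' @export
simulate_observations <- function(population, panel, db, assays, config) {
  novel_rows <- list()
  overrides <- rep(list(NULL), nrow(population))
  if (config$novel_allele_rate > 0 && nrow(population) > 0L) {
    with_seed(child_seed(config$seed, 2L), {
      pick <- runif(nrow(population)) < config$novel_allele_rate
      for (i in which(pick)) {
        alleles <- haplotype_alleles(panel, population$hap1[i])
        target <- sample(alleles, 1L)
        nov <- mutate_allele(db, target, config$novel_divergence,
                             seed = child_seed(config$seed, 100L + i))
        overrides[[i]] <- setNames(nov$sequence, target)
        novel_rows[[length(novel_rows) + 1L]] <-
          data.frame(id = population$id[i], parent = target,
                     locus = nov$locus, stringsAsFactors = FALSE)
      }
    })
  }
  obs <- lapply(seq_len(nrow(population)), function(i) {
    haps <- c(population$hap1[i], population$hap2[i])
    setNames(lapply(assays, function(a)
      simulate_assay(haps, a, panel, db,
                     dropout_enabled = config$dropout_enabled,
                     seq_override = overrides[[i]])), names(assays))
  })
  names(obs) <- population$id
  list(observations = obs,
       novel = if (length(novel_rows)) do.call(rbind, novel_rows)
               else data.frame(id = character(), parent = character(),
                               locus = character(), stringsAsFactors = FALSE))
}

#' Write / read a population truth table
#'
#' TSV with columns `id`, `hap1`, `hap2`, for parameter-recovery scoring.
#' @param population data.frame from [sample_population()].
#' @param path file path.
#' @export
write_truth <- function(population, path) {
  write.table(population, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.delim(path, sep = "\t", colClasses = "character")
}
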