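# Packaged reference fixture: the published Soay sheep haplotype panel
# (haplotypes A-H across DRB1, DQA1, DQA2, DQA2-like, DQB1, DQB2, DQB2-like)
# paired with SYNTHETIC stand-in sequences.  The real exon-2 alignments are
# not machine-readable, so sequences are generated deterministically here
# with the combinatorial structure the analysis needs: alleles within a locus
# a few substitutions apart, loci strongly diverged (so DQB1/DQB2/DQB2-like
# form three separable phylogenetic clusters), everything in frame and
# stop-free, and the DRB1*13:01 allele carrying a 1-bp deletion in the 5'
# flank of the full-exon amplicon.

#' Evaluate code with a private, restorable RNG state
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so
#' seeded helpers do not perturb the surrounding random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

rand_codon_string <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  sense <- setdiff(apply(expand.grid(bases, bases, bases), 1L, paste, collapse = ""),
                   STOP_CODONS)
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# k substitutions at distinct positions; in-frame stop codons avoided when
# frame_offset >= 0 (frame starts at frame_offset + 1)
mutate_string <- function(seq, k, frame_offset = 0L) {
  x <- strsplit(seq, "")[[1]]
  if (k < 0L) stop("negative substitution count")
  if (k == 0L) return(seq)
  if (k > length(x)) stop("more substitutions than positions")
  pos <- sample(seq_along(x), k)
  for (p in pos) {
    repeat {
      cand <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1L)
      old <- x[p]; x[p] <- cand
      if (frame_offset < 0L || p <= frame_offset) break
      cstart <- frame_offset + 3L * ((p - frame_offset - 1L) %/% 3L) + 1L
      if (cstart + 2L > length(x) ||
          !(paste(x[cstart:(cstart + 2L)], collapse = "") %in% STOP_CODONS)) break
      x[p] <- old
    }
  }
  paste(x, collapse = "")
}

#' Synthetic reference database and haplotype panel
#'
#' Builds the packaged eight-haplotype panel (A-H) with deterministic
#' synthetic stand-in sequences for its 35 allele names. Regenerating with
#' the default seed reproduces the files under `inst/extdata/` exactly.
#'
#' @param seed integer seed controlling sequence generation.
#' @return list with `db` (an [allele_db()]) and `panel` (a
#'   [haplotype_panel()]).
#' @export
synthetic_reference <- function(seed = 60909L) {
  with_seed(seed, {
    flank_len <- 30L; exon_codons <- 80L
    # independent ancestors per gene family; locus ancestors diverged from them
    dqa_root <- rand_codon_string(exon_codons)
    dqb_root <- rand_codon_string(exon_codons)
    anc <- list(
      "DRB1"      = paste0(paste(sample(c("A","C","G","T"), flank_len, TRUE), collapse = ""),
                           rand_codon_string(exon_codons)),
      "DQA1"      = mutate_string(dqa_root, 30L),
      "DQA2"      = mutate_string(dqa_root, 30L),
      "DQA2-like" = mutate_string(dqa_root, 30L),
      "DQB1"      = mutate_string(dqb_root, 36L),
      "DQB2"      = mutate_string(dqb_root, 36L),
      "DQB2-like" = mutate_string(dqb_root, 36L))

    derive <- function(locus, k = 8L) {
      off <- if (locus == "DRB1") flank_len else 0L
      mutate_string(anc[[locus]], k, frame_offset = off)
    }

    spec <- list(
      # name, locus, status, accession, full_length
      list("DRB1*01:01", "DRB1", "official", NA, TRUE),
      list("DRB1*01:02", "DRB1", "official", NA, TRUE),
      list("DRB1*03:02", "DRB1", "official", NA, TRUE),
      list("DRB1*10:01", "DRB1", "official", NA, TRUE),
      list("DRB1*13:01", "DRB1", "official", NA, TRUE),
      list("DRB1*22:01", "DRB1", "official", NA, TRUE),
      list("DQA1*03:01:01", "DQA1", "official", NA, TRUE),
      list("DQA1*Z28420", "DQA1", "temporary_accession", "Z28420", FALSE),
      list("DQA1*03:02:01", "DQA1", "official", "LR025209", TRUE),
      list("DQA1*04:02:01", "DQA1", "official", "LR025208", TRUE),
      list("DQA2*10:01:01", "DQA2", "official", "LR025213", TRUE),
      list("DQA2*01:01:01", "DQA2", "official", NA, TRUE),
      list("DQA2*07:01:01", "DQA2", "official", NA, TRUE),
      list("DQA2*02:01:01", "DQA2", "official", NA, TRUE),
      list("DQA2*01:02:01", "DQA2", "official", NA, TRUE),
      list("DQA2*09:01:02", "DQA2", "official", "LR025211", TRUE),
      list("DQA2*04:02:01", "DQA2", "official", "LR025212", TRUE),
      list("DQA2-like*03:01:01", "DQA2-like", "official", "LR025210", TRUE),
      list("DQA2-like*01:01:01", "DQA2-like", "official", NA, TRUE),
      list("DQB1*02:01:01", "DQB1", "official", NA, TRUE),
      list("DQB1*LN868258", "DQB1", "temporary_accession", "LN868258", FALSE),
      list("DQB1*07:01:01", "DQB1", "official", NA, TRUE),
      list("DQB1*07:02:01", "DQB1", "official", NA, TRUE),
      list("DQB1*AJ23941", "DQB1", "temporary_accession", "AJ23941", FALSE),
      list("NewB1-H", "DQB1", "temporary_haplotype", "LR025788", FALSE),
      list("DQB2*09:01:01", "DQB2", "official", "LR025203", TRUE),
      list("DQB2*04:01:01", "DQB2", "official", NA, TRUE),
      list("DQB2*AJ238945", "DQB2", "temporary_accession", "AJ238945", FALSE),
      list("SoayB2-D", "DQB2", "temporary_haplotype", "LR025789", FALSE),
      list("DQB2*10:01:01", "DQB2", "official", "LR025204", TRUE),
      list("SoayB2-F", "DQB2", "temporary_haplotype", "LR025790", FALSE),
      list("DQB2*12:01:01", "DQB2", "official", "LR025205", TRUE),
      list("DQB2*11:01:01", "DQB2", "official", "LR025206", TRUE),
      list("DQB2-like*03:01:01", "DQB2-like", "official", "LR025207", TRUE),
      list("DQB2-like*01:01:01", "DQB2-like", "official", NA, TRUE))

    name <- vapply(spec, `[[`, "", 1L)
    locus <- vapply(spec, `[[`, "", 2L)
    sequence <- vapply(locus, derive, character(1))
    names(sequence) <- name
    # the two DQB1*07 alleles are indistinguishable over the assayed region
    sequence[["DQB1*07:02:01"]] <- sequence[["DQB1*07:01:01"]]
    # DRB1*13:01: 1-bp deletion within the 5' flank of the full amplicon
    s <- sequence[["DRB1*13:01"]]
    sequence[["DRB1*13:01"]] <- paste0(substr(s, 1L, 14L),
                                       substr(s, 16L, nchar(s)))

    db <- allele_db(
      name = name, locus = locus, sequence = unname(sequence),
      status = vapply(spec, `[[`, "", 3L),
      accession = vapply(spec, function(s) as.character(s[[4]]), character(1)),
      full_length = vapply(spec, `[[`, TRUE, 5L))

    rows <- list(
      A = list("DRB1" = "DRB1*01:01", "DQA2" = "DQA2*10:01:01",
               "DQA2-like" = "DQA2-like*03:01:01",
               "DQB2" = "DQB2*09:01:01", "DQB2-like" = "DQB2-like*03:01:01"),
      B = list("DRB1" = "DRB1*01:02", "DQA1" = "DQA1*03:01:01",
               "DQA2" = "DQA2*01:01:01",
               "DQB1" = "DQB1*02:01:01", "DQB2" = "DQB2*04:01:01"),
      C = list("DRB1" = "DRB1*03:02", "DQA1" = "DQA1*Z28420",
               "DQA2" = "DQA2*07:01:01",
               "DQB1" = "DQB1*LN868258", "DQB2" = "DQB2*AJ238945"),
      D = list("DRB1" = "DRB1*10:01", "DQA1" = "DQA1*03:01:01",
               "DQA2" = "DQA2*02:01:01",
               "DQB1" = "DQB1*07:01:01/DQB1*07:02:01", "DQB2" = "SoayB2-D"),
      E = list("DRB1" = "DRB1*13:01", "DQA2" = "DQA2*01:02:01",
               "DQA2-like" = "DQA2-like*01:01:01",
               "DQB2" = "DQB2*10:01:01", "DQB2-like" = "DQB2-like*01:01:01"),
      F = list("DRB1" = "DRB1*22:01", "DQA1" = "DQA1*03:02:01",
               "DQA2" = "DQA2*09:01:02",
               "DQB1" = "DQB1*AJ23941", "DQB2" = "SoayB2-F"),
      G = list("DRB1" = "DRB1*01:01", "DQA2" = "DQA2*01:02:01",
               "DQA2-like" = "DQA2-like*01:01:01",
               "DQB2" = c("DQB2*09:01:01", "DQB2*12:01:01"),
               "DQB2-like" = "DQB2-like*01:01:01"),
      H = list("DRB1" = "DRB1*22:01", "DQA1" = "DQA1*04:02:01",
               "DQA2" = "DQA2*04:02:01",
               "DQB1" = "NewB1-H", "DQB2" = "DQB2*11:01:01"))
    notes <- list(
      "D:DQB1" = "ambiguity group: alleles identical throughout the assayed exon",
      "F:DQB1" = "locus designated by phylogenetic analysis",
      "F:DQB2" = "locus designated by phylogenetic analysis",
      "G:DQB2" = "DQB2*09:01:01 gDNA only; DQB2*12:01:01 cDNA only")
    panel <- haplotype_panel(rows, db = db, notes = notes)
    list(db = db, panel = panel)
  })
}

# amplicon layout constants shared with the assay profiles
.FIXTURE_FLANK <- 30L
.FIXTURE_EXON <- 240L

#' Load the packaged panel fixture
#'
#' Reads `soay_alleles_synthetic.fasta` and `soay_panel.tsv` from the
#' installed package. Content is identical to [synthetic_reference()] with
#' the default seed.
#'
#' @return list with `db` and `panel`.
#' @export
soay_fixture <- function() {
  fa <- system.file("extdata", "soay_alleles_synthetic.fasta",
                    package = "ampliphase", mustWork = TRUE)
  tsv <- system.file("extdata", "soay_panel.tsv",
                     package = "ampliphase", mustWork = TRUE)
  db <- read_allele_fasta(fa)
  list(db = db, panel = load_panel(tsv, db = db))
}
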