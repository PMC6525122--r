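# Allele database: named, locus-labelled reference sequences with
# nomenclature status, plus FASTA I/O and ungapped best-offset matching
# (the role played by the custom BLAST databases in sequence-based
# genotyping workflows).

#' Construct an allele database
#'
#' @param name character vector of unique allele names (locus prefix +
#'   colon-separated fields for official nomenclature, e.g. `"DQA2*10:01:01"`).
#' @param locus locus of each allele; one of `r paste(LOCI, collapse=", ")`.
#' @param sequence upper-case nucleotide sequences over A/C/G/T (no ambiguity
#'   codes: reference alleles are fully resolved).
#' @param status nomenclature status.
#' @param accession optional archive accession.
#' @param full_length whether the sequence is a full transcript (TRUE) or an
#'   exon-2-only genomic fragment (FALSE).
#' @return An `allele_db`: a data.frame with one row per allele.
#' @export
allele_db <- function(name = character(), locus = character(),
                      sequence = character(),
                      status = rep("official", length(name)),
                      accession = rep(NA_character_, length(name)),
                      full_length = rep(TRUE, length(name))) {
  name <- as.character(name); locus <- as.character(locus)
  sequence <- toupper(as.character(sequence))
  status <- as.character(status)
  stopifnot(length(locus) == length(name), length(sequence) == length(name))
  if (anyDuplicated(name))
    stop("duplicate allele name(s): ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  bad_locus <- setdiff(unique(locus), LOCI)
  if (length(bad_locus))
    stop("invalid locus: ", paste(bad_locus, collapse = ", "))
  bad_status <- setdiff(unique(status), ALLELE_STATUS)
  if (length(bad_status))
    stop("invalid status: ", paste(bad_status, collapse = ", "))
  if (length(sequence) && any(!nzchar(sequence)))
    stop("empty sequence for: ", paste(name[!nzchar(sequence)], collapse = ", "))
  amb <- grepl("[^ACGT]", sequence)
  if (any(amb))
    stop("ambiguity codes not allowed in reference sequences: ",
         paste(name[amb], collapse = ", "))
  # official names must carry their locus as prefix
  off <- status == "official"
  if (any(off)) {
    pref <- sub("\\*.*$", "", name[off])
    if (any(pref != locus[off]))
      stop("official allele name/locus mismatch: ",
           paste(name[off][pref != locus[off]], collapse = ", "))
  }
  db <- data.frame(name = name, locus = locus, sequence = sequence,
                   status = status, accession = as.character(accession),
                   full_length = as.logical(full_length),
                   stringsAsFactors = FALSE)
  rownames(db) <- NULL
  class(db) <- c("allele_db", "data.frame")
  db
}

#' @export
print.allele_db <- function(x, ...) {
  cat("<allele_db> ", nrow(x), " alleles across ",
      length(unique(x$locus)), " loci\n", sep = "")
  print(table(x$locus))
  invisible(x)
}

#' Names of alleles at given loci
#' @param db an `allele_db`.
#' @param loci character vector of loci.
#' @export
db_locus_names <- function(db, loci) db$name[db$locus %in% loci]

#' Sequences for named alleles
#' @param db an `allele_db`.
#' @param names allele names; all must resolve.
#' @export
db_sequences <- function(db, names) {
  idx <- match(names, db$name)
  if (anyNA(idx))
    stop("unknown allele name(s): ", paste(names[is.na(idx)], collapse = ", "))
  setNames(db$sequence[idx], names)
}

#' Read an allele database from FASTA
#'
#' Headers are pipe-delimited: `name|locus|status[|accession]`. A record whose
#' sequence contains ambiguity codes, or whose name duplicates an earlier one,
#' is rejected.
#'
#' @param path FASTA file path.
#' @return An `allele_db`.
#' @export
read_allele_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) return(allele_db())
  fields <- strsplit(names(seqs), "|", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L | nf > 5L))
    stop("malformed FASTA header (need name|locus|status[|accession[|fragment]]): ",
         names(seqs)[which(nf < 3L | nf > 5L)[1]])
  get <- function(i, default = NA_character_)
    vapply(fields, function(f) if (length(f) >= i && nzchar(f[i])) f[i] else default,
           character(1))
  frag <- get(5L, "full")
  allele_db(name = get(1L), locus = get(2L), sequence = as.character(seqs),
            status = get(3L), accession = get(4L),
            full_length = frag != "fragment")
}

#' Write an allele database to FASTA
#'
#' Inverse of [read_allele_fasta()]: writing then reading reproduces the
#' database exactly.
#'
#' @param db an `allele_db`.
#' @param path output path.
#' @export
write_allele_fasta <- function(db, path) {
  hdr <- paste(db$name, db$locus, db$status,
               ifelse(is.na(db$accession), "", db$accession),
               ifelse(db$full_length, "full", "fragment"),
               sep = "|")
  x <- Biostrings::BStringSet(setNames(db$sequence, hdr))
  Biostrings::writeXStringSet(x, filepath = path, width = 70L)
  invisible(NULL)
}

#' Match a query sequence against the database
#'
#' Ungapped identity at the best offset: the shorter of query and subject must
#' be a contained segment of the longer (amplicons and references are
#' co-linear). Hits are ranked by identity, ties broken alphabetically by
#' allele name.
#'
#' @param query unambiguous nucleotide string.
#' @param db an `allele_db`.
#' @param locus_filter optional vector of loci to restrict the search to.
#' @param min_identity hits below this identity are dropped. The default 1.0
#'   mirrors exact-accounting genotype calling: anything less than a perfect
#'   match is a novel-allele candidate.
#' @return data.frame with columns `name`, `identity`, `aligned_length`;
#'   zero rows when nothing reaches `min_identity`.
#' @export
match_sequence <- function(query, db, locus_filter = NULL, min_identity = 1.0) {
  if (!is.character(query) || length(query) != 1L || !nzchar(query))
    stop("empty query")
  query <- toupper(query)
  if (grepl("[^ACGT]", query)) stop("query must be unambiguous (A/C/G/T only)")
  if (!is.null(locus_filter)) db <- db[db$locus %in% locus_filter, , drop = FALSE]
  if (nrow(db) == 0L) stop("no alleles to match against after locus filtering")
  qc <- strsplit(query, "")[[1]]
  hits <- lapply(seq_len(nrow(db)), function(i) {
    sc <- strsplit(db$sequence[i], "")[[1]]
    if (length(qc) <= length(sc)) { short <- qc; long <- sc } else { short <- sc; long <- qc }
    n_off <- length(long) - length(short) + 1L
    best <- 0L
    for (off in seq_len(n_off)) {
      m <- sum(short == long[off:(off + length(short) - 1L)])
      if (m > best) best <- m
    }
    data.frame(name = db$name[i], identity = best / length(short),
               aligned_length = length(short), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  out <- out[out$identity >= min_identity - 1e-12, , drop = FALSE]
  out <- out[order(-out$identity, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Register a novel allele under the temporary-nomenclature rules
#'
#' Naming priority: (1) full-length transcript obtained: the allele is flagged
#' `novel_unnamed` with a placeholder name, pending official nomenclature
#' submission; (2) fragment matching an existing archive entry: named
#' `locus*accession` with status `temporary_accession` (the `DQA1*Z28420`
#' pattern); (3) otherwise named `locus-haplotype` with status
#' `temporary_haplotype` (the `DQB2-F` pattern).
#'
#' @param db an `allele_db`.
#' @param sequence novel nucleotide sequence; must be absent from `db`.
#' @param locus locus of origin.
#' @param haplotype_label haplotype on which the allele was found.
#' @param full_length was a full-length transcript obtained?
#' @param genbank_match optional accession of a matching archive entry.
#' @return list with the updated database (`db`) and the new allele's `name`.
#' @export
register_novel <- function(db, sequence, locus, haplotype_label,
                           full_length = FALSE, genbank_match = NULL) {
  sequence <- toupper(sequence)
  hit <- db$name[db$sequence == sequence]
  if (length(hit))
    stop("sequence already registered as: ", hit[1])
  if (full_length) {
    name <- paste0(locus, "*novel-", haplotype_label)
    status <- "novel_unnamed"
    accession <- NA_character_
  } else if (!is.null(genbank_match) && !is.na(genbank_match)) {
    name <- paste0(locus, "*", genbank_match)
    status <- "temporary_accession"
    accession <- as.character(genbank_match)
  } else {
    name <- paste0(locus, "-", haplotype_label)
    status <- "temporary_haplotype"
    accession <- NA_character_
  }
  if (name %in% db$name) stop("name already in database: ", name)
  new <- allele_db(name = name, locus = locus, sequence = sequence,
                   status = status, accession = accession,
                   full_length = full_length)
  db2 <- rbind(db, new)
  class(db2) <- c("allele_db", "data.frame")
  list(db = db2, name = name)
}
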