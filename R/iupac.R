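# IUPAC ambiguity-code algebra: superposition of co-amplified alleles into a
# single consensus, and the compatibility predicate used to prune candidates
# before mixture deconvolution.

# base-set <-> code lookup tables built from Biostrings' IUPAC map
.iupac_env <- new.env(parent = emptyenv())

.iupac_tables <- function() {
  if (is.null(.iupac_env$code_of)) {
    map <- Biostrings::IUPAC_CODE_MAP  # e.g. R -> "AG"
    key <- vapply(strsplit(unname(map), ""),
                  function(b) paste(sort(b), collapse = ""), character(1))
    code_of <- setNames(names(map), key)          # sorted base string -> code
    bases_of <- lapply(strsplit(unname(map), ""), sort)
    names(bases_of) <- names(map)
    .iupac_env$code_of <- code_of
    .iupac_env$bases_of <- bases_of
  }
  .iupac_env
}

#' Superpose unambiguous sequences into an IUPAC consensus
#'
#' Position by position, the set union of the bases contributed by each
#' sequence is encoded as the corresponding IUPAC ambiguity code, emulating a
#' direct Sanger read of a mixed PCR product in which up to four alleles
#' co-amplify. The operation is commutative and idempotent.
#'
#' @param sequences character vector (or list) of equal-length, upper-case,
#'   unambiguous nucleotide sequences over A, C, G, T.
#' @param assay optional assay name attached to the result.
#' @return A `mixed_sequence` object: list with `codes` (IUPAC string),
#'   `assay`, and `length_conflict = FALSE`.
#' @seealso [mixed_length_conflict()] for the unequal-length case.
#' @export
iupac_union <- function(sequences, assay = NA_character_) {
  sequences <- as.character(unlist(sequences, use.names = FALSE))
  if (length(sequences) < 1L) stop("iupac_union() needs at least one sequence")
  n <- nchar(sequences)
  if (length(unique(n)) != 1L)
    stop("iupac_union(): sequences have unequal lengths; signal a length conflict instead")
  if (length(sequences) == 1L) {
    codes <- sequences
  } else {
    if (any(grepl("[^ACGT]", sequences)))
      stop("iupac_union() inputs must be unambiguous (A/C/G/T only)")
    u <- Reduce(bitwOr, lapply(sequences, encode_mask))
    codes <- paste(.mask_to_code()[u], collapse = "")
  }
  mixed_sequence(codes, assay = assay)
}

#' Construct a mixed (IUPAC consensus) sequence
#'
#' @param codes string over the 15 IUPAC nucleotide codes.
#' @param assay assay name.
#' @param length_conflict was the mixture composed of unequal-length alleles?
#' @export
mixed_sequence <- function(codes, assay = NA_character_, length_conflict = FALSE) {
  stopifnot(is.character(codes), length(codes) == 1L, nzchar(codes))
  bad <- setdiff(unique(strsplit(codes, "")[[1]]), names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad))
    stop("invalid IUPAC code(s) in sequence: ", paste(bad, collapse = ", "))
  structure(list(codes = codes, assay = assay,
                 length_conflict = isTRUE(length_conflict)),
            class = "mixed_sequence")
}

#' Marker for a mixture of unequal-length alleles
#'
#' Length-polymorphic mixtures (the DRB1 frameshift-deletion situation) cannot
#' be read as a positionwise superposition; downstream calling reports them as
#' `uncallable_frameshift`.
#'
#' @param assay assay name.
#' @export
mixed_length_conflict <- function(assay = NA_character_) {
  structure(list(codes = NA_character_, assay = assay, length_conflict = TRUE),
            class = "mixed_sequence")
}

#' Marker for an assay that yields no PCR product
#'
#' A value, not an error: locus-specific primers on a null haplotype (e.g.
#' DQA1 primers on a DQA1-null homozygote) legitimately amplify nothing.
#'
#' @param assay assay name.
#' @export
no_product <- function(assay = NA_character_) {
  structure(list(assay = assay), class = "no_product")
}

#' @export
is_no_product <- function(x) inherits(x, "no_product")

#' Is an unambiguous allele sequence compatible with an observed consensus?
#'
#' TRUE iff at every position the allele's base belongs to the base set of the
#' observed IUPAC code. Positions where the observation is 'N' are treated as
#' missing data and skipped (see `na_code`).
#'
#' @param sequence unambiguous nucleotide string.
#' @param observed a `mixed_sequence` (or IUPAC string).
#' @param na_code observed code treated as missing data (default `"N"`);
#'   set to `NULL` to require literal containment at every position.
#' @export
is_compatible <- function(sequence, observed, na_code = "N") {
  codes <- if (inherits(observed, "mixed_sequence")) observed$codes else observed
  if (nchar(sequence) != nchar(codes))
    stop("length mismatch: allele has ", nchar(sequence),
         " bases, observation has ", nchar(codes))
  tab <- .iupac_tables()
  a <- strsplit(sequence, "")[[1]]
  o <- strsplit(codes, "")[[1]]
  keep <- if (is.null(na_code)) rep(TRUE, length(o)) else o != na_code
  all(mapply(function(base, code) base %in% tab$bases_of[[code]],
             a[keep], o[keep]))
}
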