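# Genotype calling by mixture deconvolution: decompose an observed IUPAC
# consensus into the cardinality-minimal sets of known alleles whose
# positionwise superposition reproduces it exactly.  "Exactly" encodes the
# calling rule that a genotype is only accepted when every observed variant
# is accounted for: a subset whose union is a strict refinement of the
# observed codes does not explain it.

# bitmask encoding of base sets: A=1, C=2, G=4, T=8
.mask_env <- new.env(parent = emptyenv())
.mask_table <- function() {
  if (is.null(.mask_env$tab)) {
    map <- Biostrings::IUPAC_CODE_MAP
    base_bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
    tab <- vapply(strsplit(unname(map), ""), function(b) sum(base_bit[b]), 0L)
    names(tab) <- names(map)
    .mask_env$tab <- tab
  }
  .mask_env$tab
}

encode_mask <- function(seq) {
  tab <- .mask_table()
  unname(tab[strsplit(seq, "")[[1]]])
}

# inverse lookup: bitmask value (1..15) -> IUPAC code
.mask_to_code <- function() {
  if (is.null(.mask_env$inv)) {
    tab <- .mask_table()
    inv <- character(15L)
    inv[tab] <- names(tab)
    .mask_env$inv <- inv
  }
  .mask_env$inv
}

#' Enumerate minimal allele sets explaining an observed mixture
#'
#' Searches subsets of the candidate alleles in increasing size (1 up to
#' `kmax`), stopping at the first size at which at least one subset's IUPAC
#' union equals the observed codes exactly. Candidates incompatible with the
#' observation are pruned first. Positions where the observation is 'N' are
#' treated as missing and excluded from both compatibility and equality.
#'
#' @param observed a `mixed_sequence` (or IUPAC string).
#' @param candidates named character vector: allele (or ambiguity-group)
#'   label -> unambiguous sequence, all the same length as the observation.
#' @param kmax maximum subset size (>= 1).
#' @param max_subsets guard against pathological inputs: error if more than
#'   this many subsets would be enumerated at one size.
#' @return list of character vectors of candidate labels; empty list when no
#'   subset of size <= kmax explains the observation (novel-allele signal).
#' @export
explain_mixture <- function(observed, candidates, kmax = 4L,
                            max_subsets = 500000) {
  if (kmax < 1L) stop("kmax must be >= 1")
  codes <- if (inherits(observed, "mixed_sequence")) observed$codes else observed
  obs_mask <- encode_mask(codes)
  keep <- obs_mask != 15L  # 'N' = missing data
  if (!any(keep)) stop("observation is all missing data")
  cand_len_ok <- nchar(candidates) == nchar(codes)
  candidates <- candidates[cand_len_ok]
  if (length(candidates) == 0L) return(list())
  masks <- lapply(candidates, encode_mask)
  compatible <- vapply(masks, function(m)
    all(bitwAnd(m[keep], obs_mask[keep]) == m[keep]), logical(1))
  labels <- names(candidates)[compatible]
  masks <- masks[compatible]
  m <- length(labels)
  if (m == 0L) return(list())
  obs_keep <- obs_mask[keep]
  masks_keep <- lapply(masks, function(x) x[keep])
  for (k in seq_len(min(kmax, m))) {
    if (choose(m, k) > max_subsets)
      stop("candidate subset space too large at size ", k,
           " (", m, " compatible candidates); tighten the locus filter")
    found <- list()
    idx <- combn(m, k)
    for (j in seq_len(ncol(idx))) {
      u <- masks_keep[[idx[1L, j]]]
      if (k > 1L) for (t in 2:k) u <- bitwOr(u, masks_keep[[idx[t, j]]])
      if (all(u == obs_keep))
        found[[length(found) + 1L]] <- labels[idx[, j]]
    }
    if (length(found)) return(found)
  }
  list()
}

#' Call a genotype from one assay observation
#'
#' Applies the exact-accounting calling rule to a single observation:
#' * `no_product` input -> status `no_product`;
#' * a length-conflicted mixture -> `uncallable_frameshift` (the situation a
#'   1-bp deletion allele creates under a full-exon assay);
#' * otherwise candidate alleles at the assay's loci that are
#'   indistinguishable over the assayed region are collapsed into ambiguity
#'   groups, and [explain_mixture()] is run: 0 explanations ->
#'   `novel_suspected`, exactly 1 -> `called`, several -> `ambiguous`.
#'
#' @param observed a `mixed_sequence` or `no_product` object.
#' @param db an `allele_db`.
#' @param assay an [assay_profile()].
#' @param kmax maximum explaining-set size; defaults to the assay's `kmax`.
#' @param candidates optional precomputed [assay_candidates()] result (a
#'   per-assay cache used when calling many individuals).
#' @return a `genotype_call`: list with `status`, `explanations` (list of
#'   character vectors of allele / group labels) and `assay`.
#' @export
call_genotype <- function(observed, db, assay, kmax = assay$kmax,
                          candidates = NULL) {
  mk <- function(status, explanations = list())
    structure(list(status = status, explanations = explanations,
                   assay = assay$name), class = "genotype_call")
  if (is_no_product(observed)) return(mk("no_product"))
  if (isTRUE(observed$length_conflict)) return(mk("uncallable_frameshift"))
  cand <- if (is.null(candidates)) assay_candidates(db, assay) else candidates
  ex <- explain_mixture(observed, cand, kmax = kmax)
  if (length(ex) == 0L) return(mk("novel_suspected"))
  if (length(ex) == 1L) return(mk("called", ex))
  mk("ambiguous", ex)
}

#' Candidate sequences for an assay
#'
#' Assay-region sub-sequences of every database allele at the assay's loci,
#' with alleles indistinguishable over that region collapsed into `"a/b"`
#' ambiguity-group labels.
#'
#' @param db an `allele_db`.
#' @param assay an [assay_profile()].
#' @return named character vector: group label -> region sequence.
#' @export
assay_candidates <- function(db, assay) {
  names <- db_locus_names(db, assay$loci)
  if (length(names) == 0L) stop("no alleles in database for loci: ",
                                paste(assay$loci, collapse = ", "))
  seqs <- vapply(db_sequences(db, names), function(s)
    tryCatch(assay_region_seq(assay, s), error = function(e) NA_character_),
    character(1))
  ok <- !is.na(seqs)
  names <- names[ok]; seqs <- seqs[ok]
  grp <- split(names, seqs)
  labels <- vapply(grp, function(g) paste(sort(g), collapse = "/"), character(1))
  setNames(names(grp), labels)
}

#' @export
print.genotype_call <- function(x, ...) {
  cat("<genotype_call> ", x$assay, ": ", x$status, sep = "")
  if (length(x$explanations))
    cat(" [", paste(vapply(x$explanations, paste, "", collapse = " + "),
                    collapse = " | "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Call genotypes for a whole observation set
#'
#' @param observations individual -> assay -> observation, as produced by
#'   [simulate_observations()] or [read_observations_fasta()].
#' @param db an `allele_db`.
#' @param assays named list of [assay_profile()]s covering every assay name
#'   appearing in the observations.
#' @return a `genotype_table`: individual -> assay -> `genotype_call`.
#' @export
genotype_population <- function(observations, db, assays) {
  cand_cache <- list()
  out <- lapply(observations, function(per_assay) {
    setNames(lapply(names(per_assay), function(a) {
      if (is.null(assays[[a]])) stop("undefined assay in observations: ", a)
      if (is.null(cand_cache[[a]]))
        cand_cache[[a]] <<- assay_candidates(db, assays[[a]])
      call_genotype(per_assay[[a]], db, assays[[a]],
                    candidates = cand_cache[[a]])
    }), names(per_assay))
  })
  structure(out, class = "genotype_table")
}

#' Tabulate a genotype table
#'
#' @param table a `genotype_table`.
#' @return data.frame with columns `id`, `assay`, `status`, `explanation`
#'   (alleles joined with `+`, alternative explanations with `|`, ambiguity
#'   groups shown as `a/b`).
#' @export
calls_as_data_frame <- function(table) {
  rows <- list()
  for (id in names(table)) for (a in names(table[[id]])) {
    call <- table[[id]][[a]]
    rows[[length(rows) + 1L]] <- data.frame(
      id = id, assay = a, status = call$status,
      explanation = if (length(call$explanations))
        paste(vapply(call$explanations, paste, "", collapse = "+"),
              collapse = "|") else "",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write genotype calls as TSV
#' @param table a `genotype_table`.
#' @param path output path.
#' @export
write_calls <- function(table, path) {
  write.table(calls_as_data_frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(NULL)
}

#' Read observations from a consensus FASTA
#'
#' Headers `individual|assay`; the record sequence is the IUPAC consensus
#' read for that individual under that assay. Records whose sequence is the
#' literal token `no_product` (or empty) are taken as no-product outcomes.
#'
#' @param path FASTA path.
#' @return nested list individual -> assay -> observation.
#' @export
read_observations_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  fields <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(fields) != 2L)) stop("headers must be individual|assay")
  ids <- vapply(fields, `[`, "", 1L)
  assays <- vapply(fields, `[`, "", 2L)
  obs <- list()
  for (i in seq_along(seqs)) {
    s <- as.character(seqs[[i]])
    val <- if (!nzchar(s) || toupper(s) == "NOPRODUCT") no_product(assays[i])
           else mixed_sequence(s, assay = assays[i])
    obs[[ids[i]]][[assays[i]]] <- val
  }
  obs
}

#' Write observations to a consensus FASTA
#' @param observations nested list individual -> assay -> observation.
#' @param path output path.
#' @export
write_observations_fasta <- function(observations, path) {
  recs <- character(); hdrs <- character()
  for (id in names(observations)) for (a in names(observations[[id]])) {
    o <- observations[[id]][[a]]
    hdrs <- c(hdrs, paste(id, a, sep = "|"))
    recs <- c(recs, if (is_no_product(o)) "NOPRODUCT" else o$codes)
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(setNames(recs, hdrs)),
                              filepath = path, width = 70L)
  invisible(NULL)
}
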