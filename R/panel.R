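# Haplotype panel: mapping haplotype label -> locus -> allele entries.
# An entry is either one allele name or an ambiguity group "a/b" of alleles
# indistinguishable over the assayed region (e.g. two DQB1 alleles identical
# throughout exon 2).  A locus may carry 0, 1 or 2 entries per haplotype;
# absence (a null locus) is a dash in the tabular form.

PANEL_LOCI <- c("DRB1", "DQA1", "DQA2", "DQA2-like", "DQB1", "DQB2", "DQB2-like")

#' Construct a haplotype panel
#'
#' @param rows named list: haplotype label -> named list locus -> character
#'   vector of entries (0-2 per locus; each entry an allele name or an
#'   ambiguity group `"a/b"`). Empty vector or missing locus = absent.
#' @param db optional `allele_db`; when given, every allele name (including
#'   group members) must resolve in it.
#' @param notes optional named list of provenance notes, keyed
#'   `"haplotype:locus"`.
#' @return A `haplotype_panel`.
#' @export
haplotype_panel <- function(rows, db = NULL, notes = list()) {
  stopifnot(is.list(rows))
  if (anyDuplicated(names(rows))) stop("duplicate haplotype labels")
  rows <- lapply(rows, function(r) {
    bad <- setdiff(names(r), PANEL_LOCI)
    if (length(bad)) stop("invalid locus in panel: ", paste(bad, collapse = ", "))
    over <- names(r)[vapply(r, length, 1L) > 2L]
    if (length(over))
      stop("more than 2 allele entries at locus: ", paste(over, collapse = ", "))
    r[vapply(r, length, 1L) > 0L]
  })
  if (!is.null(db)) {
    all_names <- panel_allele_names(structure(list(rows = rows), class = "haplotype_panel"))
    missing <- setdiff(all_names, db$name)
    if (length(missing))
      stop("panel allele(s) absent from database: ", paste(missing, collapse = ", "))
  }
  structure(list(rows = rows, notes = notes), class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", length(x$rows), " haplotypes\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}

#' @method as.data.frame haplotype_panel
#' @export
as.data.frame.haplotype_panel <- function(x, ...) {
  out <- data.frame(haplotype = names(x$rows), stringsAsFactors = FALSE)
  for (loc in PANEL_LOCI)
    out[[loc]] <- vapply(x$rows, function(r) {
      e <- r[[loc]]
      if (is.null(e) || length(e) == 0L) "-" else paste(e, collapse = ";")
    }, character(1))
  rownames(out) <- NULL
  out
}

#' Alleles of a haplotype at given loci
#'
#' @param panel a `haplotype_panel`.
#' @param haplotype haplotype label.
#' @param loci loci to collect (default: all).
#' @param expand_groups if TRUE, ambiguity groups are expanded into their
#'   member allele names; if FALSE, group entries are kept as `"a/b"` strings.
#' @export
haplotype_alleles <- function(panel, haplotype, loci = PANEL_LOCI,
                              expand_groups = TRUE) {
  r <- panel$rows[[haplotype]]
  if (is.null(r)) stop("unknown haplotype: ", haplotype)
  entries <- unlist(r[intersect(loci, names(r))], use.names = FALSE)
  if (is.null(entries)) entries <- character()
  if (expand_groups) entries <- unlist(strsplit(entries, "/", fixed = TRUE))
  entries
}

#' All distinct allele names referenced by a panel
#' @param panel a `haplotype_panel`.
#' @param expand_groups expand ambiguity groups into member names (default).
#' @export
panel_allele_names <- function(panel, expand_groups = TRUE) {
  unique(unlist(lapply(names(panel$rows), function(h)
    haplotype_alleles(panel, h, expand_groups = expand_groups))))
}

#' Load a haplotype panel from a tab-separated table
#'
#' One row per haplotype, one column per locus (header `haplotype` +
#' locus names); `-` marks an absent locus, `;` separates two entries at one
#' locus, `/` joins the members of an ambiguity group.
#'
#' @param path TSV path.
#' @param db optional `allele_db` used to validate allele names.
#' @return A `haplotype_panel`; an empty file yields an empty panel.
#' @export
load_panel <- function(path, db = NULL) {
  if (file.size(path) == 0L) return(haplotype_panel(list()))
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character")
  if (nrow(tab) == 0L) return(haplotype_panel(list()))
  loci <- intersect(names(tab), PANEL_LOCI)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    r <- lapply(loci, function(loc) {
      cell <- tab[[loc]][i]
      if (is.na(cell) || cell == "-" || cell == "") character() else
        strsplit(cell, ";", fixed = TRUE)[[1]]
    })
    names(r) <- loci
    r
  })
  names(rows) <- tab$haplotype
  haplotype_panel(rows, db = db)
}

#' Write a haplotype panel as a tab-separated table
#' @param panel a `haplotype_panel`.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(NULL)
}

#' Canonical content signature of a panel
#'
#' Label-free representation used to compare an inferred haplotype set with a
#' generating panel: one sorted string per haplotype of `locus=entries` terms,
#' the whole set sorted. Two panels with identical signatures describe the
#' same haplotypes regardless of labelling.
#'
#' @param panel a `haplotype_panel`.
#' @export
panel_signature <- function(panel) {
  sig <- vapply(panel$rows, function(r) {
    terms <- vapply(sort(names(r)), function(loc) {
      e <- sort(vapply(strsplit(r[[loc]], "/", fixed = TRUE),
                       function(g) paste(sort(g), collapse = "/"), character(1)))
      paste0(loc, "=", paste(e, collapse = ";"))
    }, character(1))
    paste(terms, collapse = " ")
  }, character(1))
  sort(unname(sig))
}

#' Pairwise amino-acid identity between haplotypes
#'
#' Translates each haplotype's alleles over a region and computes, for every
#' pair of haplotypes, the proportion of identical amino-acid positions over
#' the loci present in both. A locus contributes only when both haplotypes
#' carry the same number of alleles there (otherwise the concatenated peptides
#' would misalign); alleles at a locus are concatenated in sorted-name order,
#' and the first member of an ambiguity group represents the group.
#'
#' @param panel a `haplotype_panel`.
#' @param db an `allele_db` resolving every panel allele.
#' @param region `c(start, end)` 1-based inclusive nucleotide interval applied
#'   to every allele sequence before translation (must be in frame), or NULL
#'   for the full sequence.
#' @param loci loci to include (default all).
#' @return symmetric matrix of identities in `[0, 1]` with unit diagonal;
#'   `NA` where two haplotypes share no comparable locus.
#' @export
aa_identity_matrix <- function(panel, db, region = NULL, loci = PANEL_LOCI) {
  labs <- names(panel$rows)
  peptide <- function(name) {
    s <- db_sequences(db, name)
    if (!is.null(region)) {
      if (region[2] > nchar(s)) stop("region beyond sequence end for ", name)
      s <- substr(s, region[1], region[2])
    }
    if (nchar(s) %% 3L != 0L) stop("region not in frame for ", name)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    stop_at <- regexpr("*", aa, fixed = TRUE)
    if (stop_at > 0 && stop_at < nchar(aa))
      stop("stop codon inside region for ", name, " at codon ", stop_at)
    aa
  }
  locus_pep <- function(h, loc) {
    e <- panel$rows[[h]][[loc]]
    if (is.null(e) || !length(e)) return(NULL)
    first <- vapply(strsplit(e, "/", fixed = TRUE), function(g) sort(g)[1], character(1))
    lapply(sort(first), peptide)
  }
  m <- matrix(NA_real_, length(labs), length(labs), dimnames = list(labs, labs))
  diag(m) <- 1
  if (length(labs) < 2L) return(m)
  for (i in seq_along(labs)) for (j in seq_len(i - 1L)) {
    same <- 0L; tot <- 0L
    for (loc in loci) {
      a <- locus_pep(labs[i], loc); b <- locus_pep(labs[j], loc)
      if (is.null(a) || is.null(b) || length(a) != length(b)) next
      for (k in seq_along(a)) {
        if (nchar(a[[k]]) != nchar(b[[k]])) next
        ca <- strsplit(a[[k]], "")[[1]]; cb <- strsplit(b[[k]], "")[[1]]
        same <- same + sum(ca == cb); tot <- tot + length(ca)
      }
    }
    m[i, j] <- m[j, i] <- if (tot > 0L) same / tot else NA_real_
  }
  m
}
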