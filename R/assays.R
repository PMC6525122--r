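# Assay profiles: which loci a primer pair amplifies, from which template,
# which alleles drop out, and which sub-region of the reference sequence the
# amplicon covers.  These encode the published amplification behaviour of the
# sheep class IIa genotyping assays: locus-specific DQA1 primers that yield
# no product on DQA1-null haplotypes, DQA2 primers that co-amplify DQA2 and
# DQA2-like, DQB primers with allele-dependent cross-amplification, and cDNA
# assays with allele-specific dropout.

#' Construct an assay profile
#'
#' @param name assay name.
#' @param loci loci amplified by this primer pair (non-empty).
#' @param template `"gDNA"` or `"cDNA"`.
#' @param dropout allele names that yield no product under this assay
#'   (primer-site polymorphism / expression failure on cDNA).
#' @param region amplified sub-region of each allele sequence: `NULL` for the
#'   full sequence, or `list(anchor = "3p", len = n)` for the 3'-terminal `n`
#'   bases (the truncated-forward-primer design that skips a length
#'   polymorphism in the 5' flank), or `list(anchor = "5p", start, end)`.
#' @param kmax largest allele set considered when deconvolving this assay's
#'   products (4 = two fully cross-amplifying loci in a diploid).
#' @export
assay_profile <- function(name, loci, template = "gDNA",
                          dropout = character(), region = NULL, kmax = 4L) {
  stopifnot(length(loci) >= 1L, template %in% c("gDNA", "cDNA"), kmax >= 1L)
  bad <- setdiff(loci, LOCI)
  if (length(bad)) stop("invalid locus: ", paste(bad, collapse = ", "))
  structure(list(name = name, loci = loci, template = template,
                 dropout = dropout, region = region, kmax = as.integer(kmax)),
            class = "assay_profile")
}

# region extraction for one allele sequence
assay_region_seq <- function(assay, sequence) {
  r <- assay$region
  if (is.null(r)) return(sequence)
  n <- nchar(sequence)
  if (identical(r$anchor, "3p")) {
    if (r$len > n) stop("assay region longer than allele sequence")
    substr(sequence, n - r$len + 1L, n)
  } else {
    if (r$end > n) stop("assay region beyond allele sequence end")
    substr(sequence, r$start, r$end)
  }
}

#' Default genotyping assay panel
#'
#' The five gDNA assays used for haplotype inference, mirroring the published
#' primer design:
#' * `DRB1` - locus-specific, truncated forward primer covering the
#'   3'-terminal 240 bases (full exon 2), immune to the 1-bp 5'-flank
#'   deletion carried by one allele;
#' * `DRB1_full` - the full-amplicon alternative that exposes that deletion
#'   as a length conflict in heterozygotes (not used for inference);
#' * `DQA1` - locus-specific; no product on DQA1-null haplotypes;
#' * `DQA2` - co-amplifies DQA2 and DQA2-like (up to four alleles per
#'   diploid);
#' * `DQB1`, `DQB2` - the two DQB reactions; `DQB2` co-amplifies DQB2-like.
#'
#' With `cdna = TRUE`, cDNA assays with allele-specific dropout are appended
#' (`DQA_cDNA`, `DQB_cDNA`, `DQB2like_cDNA`); by default the DQB2-like
#' alleles and the gDNA-only DQB2 allele of the three-DQB haplotype fail to
#' amplify from cDNA.
#'
#' @param cdna include the cDNA assays.
#' @param cross_amplification optional named list locus-assay extensions, e.g.
#'   `list(DQB1 = "DQB2")` to let the DQB1 reaction cross-amplify DQB2
#'   alleles as well.
#' @return named list of [assay_profile()] objects.
#' @export
default_assays <- function(cdna = FALSE, cross_amplification = NULL) {
  amp <- list(DRB1 = "DRB1", DQA1 = "DQA1", DQA2 = c("DQA2", "DQA2-like"),
              DQB1 = "DQB1", DQB2 = c("DQB2", "DQB2-like"))
  for (a in names(cross_amplification))
    amp[[a]] <- unique(c(amp[[a]], cross_amplification[[a]]))
  assays <- list(
    DRB1 = assay_profile("DRB1", amp$DRB1,
                         region = list(anchor = "3p", len = .FIXTURE_EXON)),
    DRB1_full = assay_profile("DRB1_full", amp$DRB1),
    DQA1 = assay_profile("DQA1", amp$DQA1),
    DQA2 = assay_profile("DQA2", amp$DQA2),
    DQB1 = assay_profile("DQB1", amp$DQB1),
    DQB2 = assay_profile("DQB2", amp$DQB2, kmax = 5L))
  if (cdna) {
    assays$DQA_cDNA <- assay_profile(
      "DQA_cDNA", c("DQA1", "DQA2"), template = "cDNA")
    assays$DQB_cDNA <- assay_profile(
      "DQB_cDNA", c("DQB1", "DQB2"), template = "cDNA",
      dropout = c("DQB2*09:01:01", "SoayB2-D", "SoayB2-F"))
    assays$DQB2like_cDNA <- assay_profile(
      "DQB2like_cDNA", "DQB2-like", template = "cDNA",
      dropout = c("DQB2-like*03:01:01", "DQB2-like*01:01:01"))
  }
  assays
}

#' Assays used for haplotype inference
#'
#' The locus-specific gDNA subset of [default_assays()] in inference order
#' (anchor first, then DQA, then DQB).
#' @export
inference_assays <- function() {
  default_assays()[c("DRB1", "DQA1", "DQA2", "DQB1", "DQB2")]
}
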