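# End-to-end orchestration: simulate (or load) genotype observations,
# deconvolve, infer haplotypes, validate, assign DQB loci phylogenetically,
# and run the selection analyses -- in the order of the underlying genotyping
# study, from one configuration object with a single master seed.

#' Pipeline configuration
#'
#' @param n number of simulated individuals (demo/simulation mode).
#' @param freqs named haplotype frequency vector; NULL = equal frequencies
#'   over the packaged panel.
#' @param seed master seed; all stage randomness derives from it.
#' @param stages stages to run, in order, from `"simulate"`, `"genotype"`,
#'   `"haplotype"`, `"validate"`, `"phylo"`, `"selection"`.
#' @param anchor_assay anchor assay (default `"DRB1"`).
#' @param min_support anchored-homozygote support threshold.
#' @param bootstrap_B bootstrap replicates for the phylogeny stage.
#' @param selection_models models fitted in the selection stage.
#' @param novel_allele_rate per-individual novel-allele injection rate.
#' @param observations optional externally supplied observations
#'   (individual -> assay -> consensus), replacing the simulate stage.
#' @param db,panel optional reference database/panel; default the packaged
#'   fixture.
#' @param output_dir optional directory; when set, stage outputs are written
#'   there as TSV/newick plus a manifest.
#' @export
pipeline_config <- function(n = 300L, freqs = NULL, seed = 1L,
                            stages = c("simulate", "genotype", "haplotype",
                                       "validate", "phylo", "selection"),
                            anchor_assay = "DRB1", min_support = 4L,
                            bootstrap_B = 100L,
                            selection_models = c("M1a", "M2a"),
                            novel_allele_rate = 0,
                            observations = NULL, db = NULL, panel = NULL,
                            output_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(n = n, freqs = freqs, seed = seed, stages = stages,
                 anchor_assay = anchor_assay, min_support = min_support,
                 bootstrap_B = bootstrap_B,
                 selection_models = selection_models,
                 novel_allele_rate = novel_allele_rate,
                 observations = observations, db = db, panel = panel,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order and returns a run report. In demo
#' mode (no external observations) a population is simulated from the
#' packaged haplotype panel, so no external files are needed.
#'
#' @param config a [pipeline_config()].
#' @return a `run_report`: list of per-stage results plus `summary`, a named
#'   list of headline numbers.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  ref <- list(db = config$db, panel = config$panel)
  if (is.null(ref$db) || is.null(ref$panel)) ref <- soay_fixture()
  assays <- inference_assays()
  report <- list(config = config, summary = list())
  outd <- config$output_dir
  if (!is.null(outd) && !dir.exists(outd)) dir.create(outd, recursive = TRUE)

  observations <- config$observations
  if ("simulate" %in% config$stages && is.null(observations)) {
    freqs <- config$freqs
    if (is.null(freqs)) {
      labs <- names(ref$panel$rows)
      freqs <- setNames(rep(1 / length(labs), length(labs)), labs)
    }
    sc <- sim_config(freqs, config$n, seed = config$seed,
                     novel_allele_rate = config$novel_allele_rate)
    population <- sample_population(ref$panel, sc)
    sim <- simulate_observations(population, ref$panel, ref$db, assays, sc)
    observations <- sim$observations
    report$population <- population
    report$novel_injected <- sim$novel
    report$summary$n_individuals <- nrow(population)
    if (!is.null(outd)) write_truth(population, file.path(outd, "truth.tsv"))
  }

  if ("genotype" %in% config$stages) {
    if (is.null(observations)) stop("stage 'genotype': no observations available")
    table <- genotype_population(observations, ref$db, assays)
    report$genotypes <- table
    st <- table(unlist(lapply(table, function(x)
      vapply(x, `[[`, "", "status"))))
    report$summary$call_status <- st
    if (!is.null(outd)) write_calls(table, file.path(outd, "calls.tsv"))
  }

  if ("haplotype" %in% config$stages) {
    if (is.null(report$genotypes)) stop("stage 'haplotype': genotype stage required")
    inf <- infer_haplotypes(report$genotypes, ref$db,
                            anchor_assay = config$anchor_assay,
                            min_support = config$min_support)
    report$inferred <- inf
    report$summary$n_haplotypes <- length(inf$panel$rows)
    if (!is.null(outd)) {
      write_panel(inf$panel, file.path(outd, "inferred_panel.tsv"))
      write.table(inf$info, file.path(outd, "inferred_info.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("validate" %in% config$stages) {
    if (is.null(report$inferred)) stop("stage 'validate': haplotype stage required")
    dev <- validate_haplotypes(observations, report$inferred$panel, assays,
                               ref$db)
    resolved <- resolve_individuals(observations, report$inferred$panel,
                                    assays, ref$db)
    freqs <- haplotype_frequencies(resolved, report$inferred$panel)
    report$deviations <- dev
    report$frequencies <- freqs
    report$summary$n_deviations <- nrow(dev)
    report$summary$homozygosity_anchor <- freqs$homozygosity_anchor
    report$summary$homozygosity_haplotype <- freqs$homozygosity_haplotype
    if (!is.null(outd))
      write.table(dev, file.path(outd, "deviations.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }

  if ("phylo" %in% config$stages) {
    # the three-DQB-haplotype scenario: hold the G alleles out as queries
    # against the remaining DQB references
    g_alleles <- haplotype_alleles(ref$panel, "G",
                                   loci = c("DQB1", "DQB2", "DQB2-like"))
    dqb <- ref$db[ref$db$locus %in% c("DQB1", "DQB2", "DQB2-like"), ]
    refs <- lapply(split(dqb$name, dqb$locus), function(nm)
      db_sequences(ref$db, nm))
    queries <- setNames(db_sequences(ref$db, g_alleles),
                        paste0("query_", seq_along(g_alleles)))
    asg <- assign_locus(queries, refs, B = config$bootstrap_B,
                        seed = child_seed(config$seed, 7L))
    asg$allele <- g_alleles
    report$locus_assignment <- asg
    tree <- bootstrap_support(unlist(refs), B = config$bootstrap_B,
                              seed = child_seed(config$seed, 8L))
    report$dqb_tree <- tree
    report$summary$g_dqb_loci <- table(asg$locus)
    if (!is.null(outd)) {
      ape::write.tree(tree, file.path(outd, "dqb_tree.nwk"))
      write.table(asg, file.path(outd, "locus_assignment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }

  if ("selection" %in% config$stages) {
    # site-model analysis of the DQB2 allele set (full-length alleles share
    # one aligned frame in the packaged reference)
    nm <- ref$db$name[ref$db$locus == "DQB2"]
    seqs <- db_sequences(ref$db, nm)
    seqs <- seqs[nchar(seqs) == max(nchar(seqs))]
    aln <- codon_alignment(seqs)
    tree <- nj_tree(k80_matrix(seqs))
    fits <- list()
    for (m in config$selection_models)
      fits[[m]] <- fit_site_model(aln, tree, m)
    report$selection <- list(fits = fits)
    if (all(c("M1a", "M2a") %in% names(fits))) {
      report$selection$lrt_m1a_m2a <- lrt(fits$M1a, fits$M2a)
      report$selection$neb <- neb_sites(fits$M2a, aln, tree)
      report$summary$lrt_p_m1a_m2a <- report$selection$lrt_m1a_m2a$p_value
    }
    if (all(c("M7", "M8") %in% names(fits)))
      report$selection$lrt_m7_m8 <- lrt(fits$M7, fits$M8)
    if (!is.null(outd)) {
      tab <- data.frame(
        model = names(fits),
        loglik = vapply(fits, `[[`, 0, "loglik"),
        params = vapply(fits, function(f)
          paste(sprintf("%s=%.4g", names(f$params), f$params),
                collapse = ";"), ""))
      write.table(tab, file.path(outd, "selection_fits.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }

  if (!is.null(outd)) {
    manifest <- c(sprintf("seed\t%s", config$seed),
                  sprintf("stages\t%s", paste(config$stages, collapse = ",")),
                  sprintf("generated\t%s", "ampliphase run"),
                  sprintf("files\t%s", paste(list.files(outd), collapse = ",")))
    writeLines(manifest, file.path(outd, "manifest.tsv"))
  }
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> stages: ", paste(x$config$stages, collapse = ", "), "\n",
      sep = "")
  for (nm in names(x$summary)) {
    cat("  ", nm, ": ", sep = "")
    v <- x$summary[[nm]]
    if (inherits(v, "table"))
      cat(paste(names(v), as.integer(v), sep = "=", collapse = " "), "\n")
    else cat(format(v), "\n")
  }
  invisible(x)
}
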