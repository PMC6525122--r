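ref <- soay_fixture()
eq_freqs <- setNames(rep(1 / 8, 8), names(ref$panel$rows))

test_that("population sampling is reproducible Hardy-Weinberg union", {
  expect_equal(nrow(sample_population(ref$panel,
                                      sim_config(eq_freqs, 0L))), 0L)
  p1 <- sample_population(ref$panel, sim_config(eq_freqs, 50L, seed = 3L))
  p2 <- sample_population(ref$panel, sim_config(eq_freqs, 50L, seed = 3L))
  expect_identical(p1, p2)
  # two haplotypes at 0.5/0.5: homozygote proportion within 3 binomial SE
  toy <- toy_reference()
  n <- 10000L
  pop <- sample_population(toy$panel,
                           sim_config(c(X = 0.5, Y = 0.5), n, seed = 9L))
  hom <- mean(pop$hap1 == pop$hap2)
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(hom - 0.5), 3 * se)
  expect_error(sample_population(ref$panel,
                                 sim_config(c(A = 1), 10L)), "match")
  expect_error(sim_config(c(A = 0.7, B = 0.2), 10L), "sum to 1")
})

test_that("assay simulation reproduces the published amplification behaviour", {
  assays <- default_assays()
  # DQA1-null homozygote: no product from the locus-specific DQA1 primers
  expect_true(is_no_product(simulate_assay(c("A", "A"), assays$DQA1,
                                           ref$panel, ref$db)))
  # same individual, DQA2 primers: DQA2 + DQA2-like co-amplify, so a single
  # product that is heterozygous in appearance
  o <- simulate_assay(c("A", "A"), assays$DQA2, ref$panel, ref$db)
  expect_s3_class(o, "mixed_sequence")
  expect_identical(o$codes, iupac_union(db_sequences(
    ref$db, c("DQA2*10:01:01", "DQA2-like*03:01:01")))$codes)
  expect_true(grepl("[^ACGT]", o$codes))
  # heterozygote with two DQA2 and two DQA2-like alleles: four-allele mixture
  o4 <- simulate_assay(c("A", "E"), assays$DQA2, ref$panel, ref$db)
  expect_identical(o4$codes, iupac_union(db_sequences(
    ref$db, c("DQA2*10:01:01", "DQA2-like*03:01:01",
              "DQA2*01:02:01", "DQA2-like*01:01:01")))$codes)
  # output length equals the assay region length
  expect_equal(nchar(o4$codes), 240L)
  drb <- simulate_assay(c("A", "B"), assays$DRB1, ref$panel, ref$db)
  expect_equal(nchar(drb$codes), 240L)
  # determinism: noise-free output is a function of the genotype
  expect_identical(simulate_assay(c("E", "A"), assays$DQA2, ref$panel,
                                  ref$db)$codes, o4$codes)
})

test_that("the full-exon assay exposes the 1-bp deletion as a length conflict", {
  assays <- default_assays()
  het <- simulate_assay(c("E", "B"), assays$DRB1_full, ref$panel, ref$db)
  expect_true(het$length_conflict)
  expect_equal(call_genotype(het, ref$db, assays$DRB1_full)$status,
               "uncallable_frameshift")
  # the truncated primer sits downstream of the deletion: callable again
  het2 <- simulate_assay(c("E", "B"), assays$DRB1, ref$panel, ref$db)
  expect_false(het2$length_conflict)
  call <- call_genotype(het2, ref$db, assays$DRB1)
  expect_equal(call$status, "called")
  expect_setequal(call$explanations[[1]], c("DRB1*13:01", "DRB1*01:02"))
  # the deletion homozygote is callable even from the full amplicon
  hom <- simulate_assay(c("E", "E"), assays$DRB1_full, ref$panel, ref$db)
  expect_equal(call_genotype(hom, ref$db, assays$DRB1_full)$status, "called")
})

test_that("cDNA dropout sets silence the configured alleles", {
  assays <- default_assays(cdna = TRUE)
  # DQB2-like cDNA primers amplify nothing from a DQB2-like carrier
  expect_true(is_no_product(simulate_assay(c("A", "A"),
                                           assays$DQB2like_cDNA,
                                           ref$panel, ref$db)))
  # with dropout disabled the product reappears
  o <- simulate_assay(c("A", "A"), assays$DQB2like_cDNA, ref$panel, ref$db,
                      dropout_enabled = FALSE)
  expect_s3_class(o, "mixed_sequence")
})

test_that("mutate_allele applies exactly the requested substitutions", {
  m0 <- mutate_allele(ref$db, "DQA2*10:01:01", 0L, seed = 4L)
  expect_identical(m0$sequence,
                   ref$db$sequence[ref$db$name == "DQA2*10:01:01"])
  expect_false(m0$name %in% ref$db$name)
  m2 <- mutate_allele(ref$db, "DQA2*10:01:01", 2L, seed = 4L)
  hd <- sum(strsplit(m2$sequence, "")[[1]] !=
              strsplit(ref$db$sequence[ref$db$name == "DQA2*10:01:01"], "")[[1]])
  expect_equal(hd, 2L)
  expect_identical(mutate_allele(ref$db, "DQA2*10:01:01", 2L, seed = 4L)$sequence,
                   m2$sequence)
  expect_error(mutate_allele(ref$db, "DQA2*10:01:01", -1L), "negative")
})

test_that("an injected novel allele surfaces as novel_suspected downstream", {
  assays <- inference_assays()
  nov <- mutate_allele(ref$db, "DQA2*10:01:01", 3L, seed = 5L)
  o <- simulate_assay(c("A", "A"), assays$DQA2, ref$panel, ref$db,
                      seq_override = setNames(nov$sequence, "DQA2*10:01:01"))
  call <- call_genotype(o, ref$db, assays$DQA2)
  expect_equal(call$status, "novel_suspected")
})

test_that("novel-allele injection is recorded and surfaces in the calls", {
  assays <- inference_assays()
  sc <- sim_config(eq_freqs, 20L, seed = 8L, novel_allele_rate = 1,
                   novel_divergence = 3L)
  pop <- sample_population(ref$panel, sc)
  sim <- simulate_observations(pop, ref$panel, ref$db, assays, sc)
  expect_equal(nrow(sim$novel), 20L)
  tbl <- genotype_population(sim$observations, ref$db, assays)
  statuses <- unlist(lapply(tbl, function(x) vapply(x, `[[`, "", "status")))
  expect_true(any(statuses == "novel_suspected"))
})

test_that("haplotype homozygosity never exceeds anchor-locus homozygosity", {
  for (s in 1:5) {
    pop <- sample_population(ref$panel, sim_config(eq_freqs, 200L, seed = s))
    hap_hom <- mean(pop$hap1 == pop$hap2)
    drb <- function(h) haplotype_alleles(ref$panel, h, loci = "DRB1")
    anchor_hom <- mean(mapply(function(a, b) identical(drb(a), drb(b)),
                              pop$hap1, pop$hap2))
    expect_lte(hap_hom, anchor_hom)
  }
})
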