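ref <- soay_fixture()
eq_freqs <- setNames(rep(1 / 8, 8), names(ref$panel$rows))
assays <- inference_assays()

test_that("anchor homozygotes are identified, rare alleles map to empty sets", {
  toy <- toy_reference()
  run <- simulate_and_call(toy$panel, toy$db, toy$assays,
                           c(X = 0.5, Y = 0.5), 1L, seed = 12L)
  pop <- run$population
  anchors <- find_anchor_homozygotes(run$table)
  if (pop$hap1 == pop$hap2) {
    a <- haplotype_alleles(toy$panel, pop$hap1, loci = "DRB1")
    expect_equal(anchors[[a]], pop$id)
  } else {
    expect_true(all(lengths(anchors) == 0L))
  }
  # HWE expectation for anchored counts: within 3 SE of sum(p_i^2) * n
  big <- simulate_and_call(ref$panel, ref$db, assays["DRB1"], eq_freqs, 120L,
                           seed = 13L)
  anchors <- find_anchor_homozygotes(big$table)
  # DRB1*01:01 is carried by two haplotypes (A, G), DRB1*22:01 by two (F, H)
  p_hom <- c(rep((2 / 8)^2, 2), rep((1 / 8)^2, 4))
  expected <- sum(p_hom) * 120
  se <- sqrt(sum(p_hom * (1 - p_hom)) * 120)
  expect_lt(abs(sum(lengths(anchors)) - expected), 3 * se)
})

test_that("shared anchor alleles split into their constituent haplotypes", {
  run <- simulate_and_call(ref$panel, ref$db, assays, eq_freqs, 300L,
                           seed = 14L)
  anchors <- find_anchor_homozygotes(run$table)
  ext <- extend_haplotypes("DRB1*01:01", anchors[["DRB1*01:01"]], run$table,
                           c("DQA1", "DQA2"), min_support = 4L)
  expect_equal(length(ext), 2L)  # haplotypes A and G under one DRB1 allele
  profs <- lapply(ext, function(h) sort(unlist(h$profile)))
  truth <- lapply(c("A", "G"), function(h)
    sort(haplotype_alleles(ref$panel, h, loci = c("DQA1", "DQA2", "DQA2-like"),
                           expand_groups = FALSE)))
  expect_setequal(lapply(profs, paste, collapse = "|"),
                  lapply(truth, paste, collapse = "|"))
  # an unshared anchor gives a single extension
  ext1 <- extend_haplotypes("DRB1*01:02", anchors[["DRB1*01:02"]], run$table,
                            c("DQA1", "DQA2"), min_support = 1L,
                            allow_low_support = TRUE)
  expect_equal(length(ext1), 1L)
  # deferral below min_support
  expect_error(extend_haplotypes("DRB1*01:02", character(), run$table,
                                 c("DQA1", "DQA2"), min_support = 4L),
               "defer")
})

test_that("heterozygote subtraction recovers a rare haplotype exactly", {
  # haplotype D rare at 2%: no homozygotes expected, recovered from
  # heterozygous carriers by subtracting the known partner haplotype
  freqs <- setNames(c(rep(0.14, 7), 0.02),
                    c("A", "B", "C", "E", "F", "G", "H", "D"))
  run <- simulate_and_call(ref$panel, ref$db, assays, freqs[names(eq_freqs)],
                           400L, seed = 15L)
  inf <- suppressWarnings(infer_haplotypes(run$table, ref$db))
  expect_identical(panel_signature(inf$panel), panel_signature(ref$panel))
  expect_true("DRB1*10:01" %in% inf$info$anchor)
})

test_that("validation is empty on data generated from the inferred set", {
  run <- simulate_and_call(ref$panel, ref$db, assays, eq_freqs, 100L,
                           seed = 16L)
  inf <- suppressWarnings(infer_haplotypes(run$table, ref$db))
  dev <- validate_haplotypes(run$observations, inf$panel, assays, ref$db)
  expect_equal(nrow(dev), 0L)
  # empty table: empty deviation list
  expect_equal(nrow(validate_haplotypes(list(), inf$panel, assays, ref$db)), 0L)
  # an injected novel allele is reported with its failing assay
  nov <- mutate_allele(ref$db, "DQA2*10:01:01", 3L, seed = 6L)
  obs_bad <- run$observations[1]
  obs_bad[[1]]$DQA2 <- simulate_assay(
    c("A", "A"), assays$DQA2, ref$panel, ref$db,
    seq_override = setNames(nov$sequence, "DQA2*10:01:01"))
  dev2 <- validate_haplotypes(obs_bad, inf$panel, assays, ref$db)
  expect_equal(nrow(dev2), 1L)
  expect_match(dev2$assay, "DQA2")
})

test_that("frequencies and homozygosity follow the stated arithmetic", {
  toy <- toy_reference()
  # two individuals (X,X) and (X,Y): freq(X)=0.75, freq(Y)=0.25, hom=0.5
  resolved <- list(i1 = rbind(c("X", "X")), i2 = rbind(c("X", "Y")))
  fr <- haplotype_frequencies(resolved, toy$panel)
  expect_equal(unname(fr$haplotype_freqs["X"]), 0.75)
  expect_equal(unname(fr$haplotype_freqs["Y"]), 0.25)
  expect_equal(fr$homozygosity_haplotype, 0.5)
  # single (X,X) individual
  fr1 <- haplotype_frequencies(list(i = rbind(c("X", "X"))), toy$panel)
  expect_equal(unname(fr1$haplotype_freqs["X"]), 1.0)
  expect_equal(fr1$homozygosity_haplotype, 1.0)
  # unresolved individuals are excluded and counted
  fr2 <- haplotype_frequencies(list(i = rbind(c("X", "X")),
                                    j = matrix(character(), 0, 2)), toy$panel)
  expect_equal(fr2$n_unresolved, 1L)
})

test_that("estimated frequencies track the generating values", {
  freqs <- setNames(c(0.3, 0.2, 0.1, 0.1, 0.1, 0.1, 0.05, 0.05),
                    names(ref$panel$rows))
  run <- simulate_and_call(ref$panel, ref$db, assays, freqs, 300L, seed = 17L)
  inf <- suppressWarnings(infer_haplotypes(run$table, ref$db))
  expect_identical(panel_signature(inf$panel), panel_signature(ref$panel))
  resolved <- resolve_individuals(run$observations, inf$panel, assays, ref$db)
  fr <- haplotype_frequencies(resolved, inf$panel)
  # map inferred labels back to generating labels via signatures
  sig_inf <- vapply(names(inf$panel$rows), function(h)
    paste(sort(haplotype_alleles(inf$panel, h, expand_groups = FALSE)),
          collapse = "|"), character(1))
  sig_true <- vapply(names(ref$panel$rows), function(h)
    paste(sort(haplotype_alleles(ref$panel, h, expand_groups = FALSE)),
          collapse = "|"), character(1))
  map <- names(sig_true)[match(sig_inf, sig_true)]
  est <- setNames(fr$haplotype_freqs, map)[names(freqs)]
  # multinomial: each estimate within 3 SE (2n draws) of its truth
  se <- sqrt(freqs * (1 - freqs) / (2 * 300))
  expect_true(all(abs(est - freqs) < 3 * se + 1e-9))
  # haplotype homozygosity never exceeds anchor homozygosity
  expect_lte(fr$homozygosity_haplotype, fr$homozygosity_anchor)
})

test_that("anchor splitting bounds the number of inferred haplotypes", {
  run <- simulate_and_call(ref$panel, ref$db, assays, eq_freqs, 300L,
                           seed = 18L)
  inf <- suppressWarnings(infer_haplotypes(run$table, ref$db))
  anchors <- find_anchor_homozygotes(run$table)
  expect_gte(length(inf$panel$rows), length(anchors))
  expect_equal(length(inf$panel$rows), 8L)  # two anchors are shared
})
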