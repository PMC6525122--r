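ref <- soay_fixture()

test_that("explain_mixture finds exact minimal explanations", {
  with_seed(10L, {
    cand <- setNames(rand_seqs(5, 12), paste0("a", 1:5))
    # an allele's own sequence: unique size-1 explanation
    ex <- explain_mixture(mixed_sequence(cand[["a2"]]), cand)
    expect_equal(ex, list("a2"))
    # union of alleles 1 and 3: equals brute-force enumeration over 2^5 subsets
    obs <- iupac_union(cand[c("a1", "a3")])
    ex <- explain_mixture(obs, cand)
    oracle <- oracle_explain(obs$codes, cand)
    expect_setequal(lapply(ex, sort), oracle)
    # a base present in no candidate: empty result (novel suspected)
    codes <- obs$codes
    expect_equal(explain_mixture(mixed_sequence(paste0("N", substr(codes, 2, 12))),
                                 cand), explain_mixture(obs, cand))
  })
  expect_error(explain_mixture(mixed_sequence("ACGT"), c(x = "ACGT"),
                               kmax = 0L), "kmax")
})

test_that("deconvolution equals brute-force subset enumeration on random instances", {
  with_seed(77L, {
    for (rep in 1:30) {
      n_cand <- sample(3:8, 1)
      len <- 10L
      cand <- setNames(rand_seqs(n_cand, len), paste0("c", seq_len(n_cand)))
      k_true <- sample(1:min(4, n_cand), 1)
      members <- sample(names(cand), k_true)
      obs <- iupac_union(cand[members])
      ex <- explain_mixture(obs, cand, kmax = 4L)
      oracle <- oracle_explain(obs$codes, cand, kmax = 4L)
      expect_setequal(lapply(ex, function(x) paste(sort(x), collapse = "+")),
                      lapply(oracle, function(x) paste(x, collapse = "+")))
      # soundness: the generating subset appears among explanations of its
      # own union whenever no smaller subset shares that union
      if (length(ex) && length(ex[[1]]) == k_true)
        expect_true(paste(sort(members), collapse = "+") %in%
                      vapply(ex, function(x) paste(sort(x), collapse = "+"), ""))
    }
  })
})

test_that("a mixture with an unexplained base yields no explanation", {
  with_seed(11L, {
    cand <- setNames(rand_seqs(4, 10), paste0("c", 1:4))
    obs <- iupac_union(cand[1:2])$codes
    # inject a base absent from every candidate at position 1
    present <- unique(substr(unname(cand), 1, 1))
    missing_base <- setdiff(c("A", "C", "G", "T"), present)
    if (length(missing_base)) {
      b1 <- unique(substr(unname(cand[1:2]), 1, 1))
      codes <- paste0(oracle_code_of_set(c(b1, missing_base[1])),
                      substr(obs, 2, 10))
      # rebuild the first code from the union plus the missing base
      expect_length(explain_mixture(mixed_sequence(codes), cand), 0L)
    }
  })
})

test_that("indistinguishable alleles collapse into a called ambiguity group", {
  assays <- inference_assays()
  # a DQB1*07 homozygote: the two exon-identical alleles report as one group
  o <- simulate_assay(c("D", "D"), assays$DQB1, ref$panel, ref$db)
  call <- call_genotype(o, ref$db, assays$DQB1)
  expect_equal(call$status, "called")
  expect_equal(call$explanations[[1]], "DQB1*07:01:01/DQB1*07:02:01")
  # collapsing never changes the number of minimal explanations
  cand_raw <- setNames(
    vapply(db_sequences(ref$db, db_locus_names(ref$db, "DQB1")), identity, ""),
    db_locus_names(ref$db, "DQB1"))
  ex_raw <- explain_mixture(o, cand_raw)
  ex_grp <- explain_mixture(o, assay_candidates(ref$db, assays$DQB1))
  expect_equal(length(ex_grp), 1L)
  expect_equal(length(ex_raw), 2L)  # 07:01 and 07:02 variants, same cardinality
  expect_true(all(lengths(ex_raw) == lengths(ex_grp)[1]))
})

test_that("four co-amplified alleles are called exactly", {
  assays <- inference_assays()
  o <- simulate_assay(c("A", "E"), assays$DQA2, ref$panel, ref$db)
  call <- call_genotype(o, ref$db, assays$DQA2)
  expect_equal(call$status, "called")
  expect_setequal(call$explanations[[1]],
                  c("DQA2*10:01:01", "DQA2-like*03:01:01",
                    "DQA2*01:02:01", "DQA2-like*01:01:01"))
})

test_that("noise-free simulated observations never look novel", {
  assays <- inference_assays()
  labs <- names(ref$panel$rows)
  run <- simulate_and_call(ref$panel, ref$db, assays,
                           setNames(rep(1 / 8, 8), labs), 40L, seed = 21L)
  statuses <- unlist(lapply(run$table, function(x)
    vapply(x, `[[`, "", "status")))
  expect_false(any(statuses == "novel_suspected"))
  expect_true(all(statuses %in% c("called", "no_product")))
})

test_that("observation FASTA round-trips through calls", {
  assays <- inference_assays()
  labs <- names(ref$panel$rows)
  run <- simulate_and_call(ref$panel, ref$db, assays,
                           setNames(rep(1 / 8, 8), labs), 5L, seed = 2L)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_observations_fasta(run$observations, path)
  obs2 <- read_observations_fasta(path)
  t2 <- genotype_population(obs2, ref$db, assays)
  expect_identical(calls_as_data_frame(run$table), calls_as_data_frame(t2))
})
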