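test_that("FASTA round trip is the identity and malformed records are rejected", {
  db <- allele_db(name = c("DRB1*01:01", "DQA1*02:01"),
                  locus = c("DRB1", "DQA1"),
                  sequence = c("ACGTACGTA", "TTTTCCCCA"),
                  status = c("official", "official"),
                  accession = c(NA, "LR000001"),
                  full_length = c(TRUE, FALSE))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_allele_fasta(db, path)
  db2 <- read_allele_fasta(path)
  expect_identical(as.data.frame(db), as.data.frame(db2))
  # a second write is byte-identical
  path2 <- withr::local_tempfile(fileext = ".fasta")
  write_allele_fasta(db2, path2)
  expect_identical(readLines(path), readLines(path2))

  expect_error(allele_db(name = c("a", "a"), locus = c("DRB1", "DRB1"),
                         sequence = c("AC", "AC")), "duplicate")
  expect_error(allele_db(name = "x", locus = "DQB9", sequence = "AC"),
               "DQB9")
  expect_error(allele_db(name = "x", locus = "DQB1", sequence = "ACRT"),
               "ambiguity")
})

test_that("the packaged panel fixture has the published structure", {
  ref <- soay_fixture()
  expect_equal(nrow(ref$db), 35L)              # distinct allele names
  expect_equal(length(ref$panel$rows), 8L)     # haplotypes A-H
  # distinct panel entries, the exon-2-identical DQB1 pair counted once
  expect_equal(length(panel_allele_names(ref$panel, expand_groups = FALSE)),
               34L)
  drb1 <- unique(unlist(lapply(names(ref$panel$rows), function(h)
    haplotype_alleles(ref$panel, h, loci = "DRB1"))))
  expect_equal(length(drb1), 6L)
  dqa1_null <- names(ref$panel$rows)[vapply(names(ref$panel$rows), function(h)
    length(haplotype_alleles(ref$panel, h, loci = "DQA1")) == 0L, logical(1))]
  expect_setequal(dqa1_null, c("A", "E", "G"))
  g_dqb <- haplotype_alleles(ref$panel, "G",
                             loci = c("DQB1", "DQB2", "DQB2-like"))
  expect_equal(length(g_dqb), 3L)
  # regeneration from code reproduces the frozen files
  regen <- synthetic_reference()
  expect_identical(as.data.frame(regen$db), as.data.frame(ref$db))
  expect_identical(panel_signature(regen$panel), panel_signature(ref$panel))
})

test_that("panel loading preserves absences and rejects bad rows", {
  ref <- soay_fixture()
  expect_length(haplotype_alleles(ref$panel, "A", loci = "DQA1"), 0L)
  expect_length(haplotype_alleles(ref$panel, "A", loci = "DQB1"), 0L)
  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_length(load_panel(empty)$rows, 0L)
  expect_error(haplotype_panel(list(Z = list(
    "DQA2" = c("a", "b", "c")))), "more than 2")
  expect_error(haplotype_panel(list(Z = list("DQA2" = "nonexistent")),
                               db = ref$db), "absent from database")
})

test_that("match_sequence ranks by ungapped best-offset identity", {
  ref <- soay_fixture()
  a <- ref$db$sequence[ref$db$name == "DQA2*10:01:01"]
  hit <- match_sequence(a, ref$db)
  expect_equal(hit$name[1], "DQA2*10:01:01")
  expect_equal(hit$identity[1], 1.0)
  # every allele matches itself at identity 1
  for (i in seq_len(nrow(ref$db))) {
    h <- match_sequence(ref$db$sequence[i], ref$db,
                        locus_filter = ref$db$locus[i])
    expect_true(ref$db$name[i] %in% h$name[h$identity == 1])
  }
  # two substitutions over 240 bases: identity = 238/240 by direct count
  q <- a
  substr(q, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(a, 5, 5))[1]
  substr(q, 100, 100) <- setdiff(c("A", "C", "G", "T"), substr(a, 100, 100))[1]
  mism <- sum(strsplit(q, "")[[1]] != strsplit(a, "")[[1]])
  expect_equal(mism, 2L)
  h <- match_sequence(q, ref$db, locus_filter = "DQA2", min_identity = 0.9)
  expect_equal(h$identity[h$name == "DQA2*10:01:01"], 238 / 240)
  # nothing at full identity: novel candidate contract
  expect_equal(nrow(match_sequence(q, ref$db, min_identity = 1.0)), 0L)
  expect_error(match_sequence("", ref$db), "empty")
  expect_error(match_sequence("ACGT", ref$db, locus_filter = "unassigned"),
               "no alleles")
})

test_that("register_novel applies the temporary-nomenclature priority rules", {
  ref <- soay_fixture()
  novel_seq <- with_seed(1L, rand_seqs(1, 240))
  # fragment with an archive match: locus*accession
  r1 <- register_novel(ref$db, novel_seq, "DQA1", "C",
                       full_length = FALSE, genbank_match = "Z28420x")
  expect_equal(r1$name, "DQA1*Z28420x")
  expect_equal(r1$db$status[r1$db$name == r1$name], "temporary_accession")
  # fragment without a match: locus-haplotype
  r2 <- register_novel(ref$db, novel_seq, "DQB2", "F", full_length = FALSE)
  expect_equal(r2$name, "DQB2-F")
  expect_equal(r2$db$status[r2$db$name == r2$name], "temporary_haplotype")
  # full-length: flagged for nomenclature submission
  r3 <- register_novel(ref$db, novel_seq, "DQB2", "F", full_length = TRUE)
  expect_equal(r3$db$status[r3$db$name == r3$name], "novel_unnamed")
  # re-registration errors naming the first registration
  expect_error(register_novel(r2$db, novel_seq, "DQB2", "F"), "DQB2-F")
  # naming is a pure function of its inputs
  r2b <- register_novel(ref$db, novel_seq, "DQB2", "F", full_length = FALSE)
  expect_equal(r2b$name, r2$name)
})

test_that("amino-acid identity is 1 on the diagonal and counts codon changes", {
  ref <- soay_fixture()
  m2 <- aa_identity_matrix(ref$panel, ref$db,
                           loci = c("DQA2", "DQA2-like", "DQB2"))
  expect_true(all(diag(m2) == 1))
  expect_true(all(m2[!is.na(m2)] >= 0 & m2[!is.na(m2)] <= 1))
  expect_true(isSymmetric(m2))

  # hand-counted toy: two haplotypes sharing one locus, 3 of 12 codons differ
  seq1 <- "ATGGCTGCAGCTTTTGCAGCTGCAGCTGCAGCTTTT"  # 12 codons
  seq2 <- seq1
  substr(seq2, 4, 6) <- "CCT"; substr(seq2, 7, 9) <- "GGT"
  substr(seq2, 13, 15) <- "CAT"
  db <- allele_db(name = c("DQA2*01:01", "DQA2*02:01"),
                  locus = c("DQA2", "DQA2"), sequence = c(seq1, seq2))
  pan <- haplotype_panel(list(P = list("DQA2" = "DQA2*01:01"),
                              Q = list("DQA2" = "DQA2*02:01")), db = db)
  mm <- aa_identity_matrix(pan, db, loci = "DQA2")
  expect_equal(mm["P", "Q"], 9 / 12)
  # an internal stop codon in the region is rejected with its position
  seq3 <- seq1
  substr(seq3, 10, 12) <- "TAA"
  db3 <- allele_db(name = "DQA2*03:01", locus = "DQA2", sequence = seq3)
  expect_error(aa_identity_matrix(
    haplotype_panel(list(R = list("DQA2" = "DQA2*03:01"),
                         S = list("DQA2" = "DQA2*03:01")), db = db3),
    db3, loci = "DQA2"), "stop codon")
  # identical haplotypes: identity exactly 1
  pan2 <- haplotype_panel(list(P = list("DQA2" = "DQA2*01:01"),
                               Q = list("DQA2" = "DQA2*01:01")), db = db)
  expect_equal(aa_identity_matrix(pan2, db, loci = "DQA2")["P", "Q"], 1)
})
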