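test_that("K80 distance reproduces the closed form and its domain", {
  r <- k80_distance("ACGTACGT", "ACGTACGT")
  expect_equal(r$d, 0); expect_equal(r$P, 0); expect_equal(r$Q, 0)
  # 20 bases, exactly 2 transitions and 1 transversion:
  s1 <- "AAAAACCCCCGGGGGTTTTT"
  s2 <- "GAAAATCCCCGGGGGTTTTA"   # A->G (ts), C->T (ts), T->A (tv)
  r <- k80_distance(s1, s2)
  expect_equal(r$P, 0.10)
  expect_equal(r$Q, 0.05)
  expect_equal(r$d, 0.5 * log(1 / 0.75) + 0.25 * log(1 / 0.9))
  # saturation: P = 0.5, Q = 0
  expect_error(k80_distance(paste(rep("A", 10), collapse = ""),
                            paste(c(rep("G", 5), rep("A", 5)), collapse = "")),
               "saturat")
  # symmetry + zero iff identical over included sites
  r2 <- k80_distance(s2, s1)
  expect_equal(r2$d, r$d)
  # gap/N positions excluded pairwise
  r3 <- k80_distance("ACGT-CGT", "ACGTACGA")
  expect_equal(r3$n_sites, 7L)
})

test_that("K80 distances agree with an independent implementation", {
  with_seed(30L, {
    anc <- rand_seqs(1, 300)
    seqs <- c(a = anc,
              b = ampliphase:::mutate_string(anc, 12L),
              c = ampliphase:::mutate_string(anc, 25L))
    m <- k80_matrix(seqs)
    bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
    m2 <- as.matrix(ape::dist.dna(bin, model = "K80",
                                  pairwise.deletion = TRUE))
    expect_equal(unname(m), unname(m2[names(seqs), names(seqs)]),
                 tolerance = 1e-10)
  })
})

test_that("neighbour joining recovers an additive tree exactly", {
  # hand-built additive matrix from tree ((a:2,b:3):1,(c:4,d:5)) with the
  # internal edge of length 1
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m["a", "b"] <- m["b", "a"] <- 5
  m["a", "c"] <- m["c", "a"] <- 7
  m["a", "d"] <- m["d", "a"] <- 8
  m["b", "c"] <- m["c", "b"] <- 8
  m["b", "d"] <- m["d", "b"] <- 9
  m["c", "d"] <- m["d", "c"] <- 9
  tr <- nj_tree(m)
  # topology: ab | cd
  expect_true(ape::is.monophyletic(ape::root(tr, "d"), c("a", "b")))
  # additive matrices are reproduced exactly by pairwise path lengths
  path <- ape::cophenetic.phylo(tr)[rownames(m), colnames(m)]
  expect_equal(path, m, tolerance = 1e-12)
  # 3 taxa: closed-form three-point branch lengths
  m3 <- m[1:3, 1:3]
  tr3 <- nj_tree(m3)
  bl <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])], tr3$tip.label)
  expect_equal(unname(bl["a"]), (5 + 7 - 8) / 2)
  expect_equal(unname(bl["b"]), (5 + 8 - 7) / 2)
  expect_equal(unname(bl["c"]), (7 + 8 - 5) / 2)
  expect_error(nj_tree(m[1:2, 1:2]), "3 taxa")
  # identical rows join first at distance 0
  m4 <- m
  m4["a", "b"] <- m4["b", "a"] <- 0
  m4["b", "c"] <- m4["c", "b"] <- 7; m4["b", "d"] <- m4["d", "b"] <- 8
  tr4 <- nj_tree(m4)
  cp <- ape::cophenetic.phylo(tr4)
  expect_equal(cp["a", "b"], 0)
  expect_true(all(tr4$edge.length >= 0))
})

test_that("bootstrap supports are reproducible and bounded", {
  with_seed(31L, {
    anc1 <- rand_seqs(1, 200); anc2 <- ampliphase:::mutate_string(anc1, 60L)
    aln <- c(a1 = anc1, a2 = ampliphase:::mutate_string(anc1, 3L),
             a3 = ampliphase:::mutate_string(anc1, 4L),
             b1 = anc2, b2 = ampliphase:::mutate_string(anc2, 3L),
             b3 = ampliphase:::mutate_string(anc2, 4L))
  })
  t1 <- bootstrap_support(aln, B = 50L, seed = 5L)
  t2 <- bootstrap_support(aln, B = 50L, seed = 5L)
  expect_identical(t1$node.label, t2$node.label)
  # two clearly separated clusters: the between-cluster split is near-certain
  expect_gte(max(t1$node.label, na.rm = TRUE), 0.95)
  # B = 1: supports are 0 or 1
  t3 <- bootstrap_support(aln, B = 1L, seed = 5L)
  expect_true(all(t3$node.label %in% c(0, 1) | is.na(t3$node.label)))
  expect_error(bootstrap_support(aln, B = 0L), "B must be")
})

test_that("locus assignment places queries with their reference clusters", {
  ref <- soay_fixture()
  dqb <- ref$db[ref$db$locus %in% c("DQB1", "DQB2", "DQB2-like"), ]
  refs <- lapply(split(dqb$name, dqb$locus), function(nm)
    db_sequences(ref$db, nm))
  # query identical to a DQB2 reference
  q1 <- setNames(refs$DQB2[["DQB2*04:01:01"]], "q_same")
  a1 <- assign_locus(q1, refs, B = 50L, seed = 6L)
  expect_equal(a1$locus, "DQB2")
  expect_equal(a1$support, 1.0)
  # query derived from a DQB2-like reference by 2 substitutions
  q2 <- setNames(ampliphase:::with_seed(8L, ampliphase:::mutate_string(
    refs[["DQB2-like"]][[1]], 2L)), "q_mut")
  a2 <- assign_locus(q2, refs, B = 50L, seed = 6L)
  expect_equal(a2$locus, "DQB2-like")
  expect_gte(a2$support, 0.9)
  expect_error(assign_locus(q1, list(DQB1 = refs$DQB1[1]), B = 5L),
               "at least 2")
})

test_that("the three-DQB haplotype resolves to two DQB2 loci plus DQB2-like", {
  ref <- soay_fixture()
  g <- haplotype_alleles(ref$panel, "G", loci = c("DQB1", "DQB2", "DQB2-like"))
  dqb <- ref$db[ref$db$locus %in% c("DQB1", "DQB2", "DQB2-like"), ]
  refs <- lapply(split(dqb$name, dqb$locus), function(nm)
    db_sequences(ref$db, nm))
  queries <- setNames(db_sequences(ref$db, g), paste0("q", seq_along(g)))
  asg <- assign_locus(queries, refs, B = 50L, seed = 7L)
  expect_setequal(asg$locus, c("DQB2", "DQB2", "DQB2-like"))
})
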