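test_that("subset duplicates are removed, unique evidence is kept", {
  # step-4 pattern: two true alleles with their own unique reads, a
  # third whose reads are all shared with them
  a01 <- mkCand("A*01:01", c("r1", "r2", "r3", "u1"))
  a04 <- mkCand("A*04:01", c("r1", "r2", "r3", "u2"))
  a06 <- mkCand("A*06:01", c("r1", "r2", "r3"))
  kept <- removeSubsetDuplicates(list(a01, a04, a06))
  expect_setequal(vapply(kept, `[[`, character(1), "allele"),
                  c("A*01:01", "A*04:01"))

  # single candidate unchanged
  expect_length(removeSubsetDuplicates(list(a06)), 1L)

  # pairwise-disjoint read sets: nothing removed
  disj <- list(mkCand("A*01:01", c("a", "b")),
               mkCand("A*02:01", c("c")),
               mkCand("A*03:01", c("d", "e")))
  expect_length(removeSubsetDuplicates(disj), 3L)

  # identical read sets are not proper subsets: both kept
  same <- list(mkCand("A*01:01", c("a", "b")),
               mkCand("A*02:01", c("a", "b")))
  expect_length(removeSubsetDuplicates(same), 2L)
})

test_that("duplicate removal is idempotent and order-invariant", {
  set.seed(41)
  pool <- paste0("r", 1:12)
  for (rep in 1:20) {
    cands <- lapply(1:5, function(i)
      mkCand(sprintf("A*%02d:01", i),
             sample(pool, sample(2:8, 1))))
    once <- removeSubsetDuplicates(cands)
    expect_equal(removeSubsetDuplicates(once), once)
    perm <- sample(length(cands))
    again <- removeSubsetDuplicates(cands[perm])
    expect_setequal(vapply(again, `[[`, character(1), "allele"),
                    vapply(once, `[[`, character(1), "allele"))
  }
})

test_that("unique reads are counted against all other candidates", {
  expect_equal(countUniqueReads(c("r1", "r2", "r3"),
                                list(c("r2"), c("r3"))), 1L)
  expect_equal(countUniqueReads(c("r1", "r2"), list()), 2L)
  expect_equal(countUniqueReads(character(0), list(c("r1"))), 0L)
})

test_that("genotype calls follow the unique-read het/hom rule", {
  # both top candidates hold unique reads: het
  cl <- callGenotype(list(mkCand("A*01:01", c("s1", "s2", "u1")),
                          mkCand("A*04:01", c("s1", "s2", "u2", "u3"))),
                     "A")
  expect_equal(cl@zygosity, "het")
  expect_setequal(cl@alleles, c("A*01:01", "A*04:01"))
  expect_equal(unname(cl@uniqueReadCounts[cl@alleles]),
               ifelse(cl@alleles == "A*04:01", 2L, 1L))

  # only one candidate: hom
  cl <- callGenotype(list(mkCand("B*07:02", c("r1", "r2"))), "B")
  expect_equal(cl@zygosity, "hom")
  expect_equal(cl@alleles, "B*07:02")

  # second candidate with zero unique reads: hom on the first
  cl <- callGenotype(list(mkCand("A*01:01", c("r1", "r2", "u1")),
                          mkCand("A*02:01", c("r1", "r2"))), "A")
  expect_equal(cl@zygosity, "hom")
  expect_equal(cl@alleles, "A*01:01")

  # no unique reads anywhere: flagged low-confidence hom on the
  # best-covered candidate
  cl <- callGenotype(list(mkCand("A*01:01", c("r1", "r2")),
                          mkCand("A*02:01", c("r1", "r2"))), "A")
  expect_equal(cl@zygosity, "hom")
  expect_true("low_confidence_no_unique_reads" %in% cl@flags)

  # empty candidate set: no-call, not an error
  cl <- callGenotype(list(), "A")
  expect_equal(cl@zygosity, "none")
  expect_length(cl@alleles, 0L)
  expect_equal(cl@resolution, 0L)
})

test_that("ties break deterministically by totals, score, then name", {
  a <- mkCand("A*02:01", c("x", "u1"), score = 5)
  b <- mkCand("A*01:01", c("x", "u2"), score = 5)
  cl <- callGenotype(list(a, b), "A")
  # equal unique counts and totals and scores: lexicographic order
  expect_equal(cl@alleles, c("A*01:01", "A*02:01"))
})

test_that("error-free diploid reads at 90x recover the true het pair", {
  cfg <- simConfig(seed = 52L)
  sim <- simulateAlleleDb(cfg)
  truth <- c("A*03:01", "A*05:01")
  reads <- simulateDiploidReads(sim$db, "A", truth, cfg, seed = 53)
  cl <- typeGene(reads, sim$db, "A")
  expect_equal(cl@zygosity, "het")
  expect_setequal(cl@alleles, truth)
  # het alleles never share a typing sequence (distinct groups)
  expect_length(unique(cl@alleles), 2L)
})

test_that("fallback exons resolve alleles identical over the primary exon", {
  set.seed(54)
  e2 <- randSeq(250)
  e3 <- randSeq(250)
  db <- mkDb(list(
    mkRecord("DQB1*05:01", c(`2` = e2, `3` = e3)),
    mkRecord("DQB1*05:02", c(`2` = e2, `3` = flipBase(e3, 125)))))
  cfg <- simConfig(genes = "DQB1", readLength = 60L, depth = 80)
  reads <- simulateDiploidReads(db, "DQB1",
                                c("DQB1*05:01", "DQB1*05:02"), cfg,
                                seed = 55)
  # primary pass alone cannot split the exon-2-identical pair
  noFb <- typeGene(reads, db, "DQB1", fallback = FALSE)
  expect_equal(noFb@zygosity, "hom")
  expect_equal(noFb@alleles, "DQB1*05")
  # the fallback cascade types over exons 2+3 and resolves the het
  cl <- typeGene(reads, db, "DQB1")
  expect_equal(cl@zygosity, "het")
  expect_setequal(cl@alleles, c("DQB1*05:01", "DQB1*05:02"))
  expect_true(3L %in% cl@exonsUsed)
  expect_true("fallback_exons" %in% cl@flags)
})

test_that("a decisive primary pass never engages the fallback exons", {
  cfg <- simConfig(seed = 56L)
  sim <- simulateAlleleDb(cfg)
  truth <- c("A*05:01", "A*06:01")
  reads <- simulateDiploidReads(sim$db, "A", truth, cfg, seed = 57)
  cl <- typeGene(reads, sim$db, "A")
  expect_setequal(cl@alleles, truth)
  expect_equal(cl@exonsUsed, c(2L, 3L))      # primary exons only
  expect_false("fallback_exons" %in% cl@flags)
})

test_that("reads covering a single-base difference decide the call", {
  cfg <- simConfig(seed = 58L)
  sim <- simulateAlleleDb(cfg)
  nd <- sim$info$nearDuplicates
  row <- nd[nd$gene == "B", ]
  for (truthAllele in c(row$allele1, row$allele2)) {
    reads <- simulateDiploidReads(sim$db, "B",
                                  c(truthAllele, truthAllele), cfg,
                                  seed = 59)
    cl <- typeGene(reads, sim$db, "B")
    expect_equal(cl@zygosity, "hom")
    expect_equal(cl@alleles, truthAllele)
  }
})

test_that("calls flatten into a stable genotype table", {
  cl <- callGenotype(list(mkCand("A*01:01:01", c("s", "u1")),
                          mkCand("A*04:01", c("s", "u2"))), "A",
                     exonsUsed = c(2L, 3L))
  tab <- genotypeTable(list(cl), sample = "S1")
  expect_equal(tab$sample, "S1")
  expect_equal(tab$zygosity, "het")
  expect_equal(tab$exons_used, "2,3")
  tab4 <- genotypeTable(list(cl), digits = 4)
  expect_true(all(tab4$allele1 %in% c("A*01:01", "A*04:01")))

  # hom repeats the allele in both slots; no-call leaves NA
  hom <- callGenotype(list(mkCand("B*07:02", c("r", "u"))), "B")
  expect_equal(genotypeTable(hom)$allele2, "B*07:02")
  expect_true(is.na(genotypeTable(callGenotype(list(), "C"))$allele1))
})
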