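test_that("equal seeds give identical databases and read sets", {
  cfg <- simConfig(seed = 61L)
  a <- simulateAlleleDb(cfg)
  b <- simulateAlleleDb(cfg)
  expect_equal(alleleNames(a$db), alleleNames(b$db))
  expect_equal(lapply(a$db@records, slot, "exons"),
               lapply(b$db@records, slot, "exons"))
  truth <- c("A*03:01", "A*04:01")
  r1 <- simulateDiploidReads(a$db, "A", truth, cfg, seed = 62)
  r2 <- simulateDiploidReads(b$db, "A", truth, cfg, seed = 62)
  expect_equal(as.character(r1), as.character(r2))
})

test_that("the engineered near-duplicate pair is the only Hamming-1 pair", {
  cfg <- simConfig(seed = 63L)
  sim <- simulateAlleleDb(cfg)
  for (g in c("A", "DRB1")) {
    recs <- Filter(function(r) r@name@gene == g, sim$db@records)
    nms <- vapply(recs, function(r) renderAlleleName(r@name), character(1))
    concat <- vapply(recs, function(r)
      paste(r@exons[order(as.integer(names(r@exons)))], collapse = ""),
      character(1))
    ham <- function(x, y)
      sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    onePairs <- list()
    for (i in seq_along(recs)[-length(recs)])
      for (j in seq(i + 1, length(recs)))
        if (ham(concat[i], concat[j]) == 1L)
          onePairs[[length(onePairs) + 1L]] <- sort(c(nms[i], nms[j]))
    expected <- sim$info$nearDuplicates
    expected <- expected[expected$gene == g, ]
    expect_length(onePairs, 1L)
    expect_equal(onePairs[[1L]],
                 sort(c(expected$allele1, expected$allele2)))
  }
})

test_that("zero substitution rate collapses all alleles into one group", {
  cfg <- simConfig(genes = "A", nAlleles = 4L, substitutionRate = 0,
                   nearDuplicatePairs = 0L, identicalQuartets = 0L,
                   seed = 64L)
  sim <- simulateAlleleDb(cfg)
  groups <- buildRepresentativeGroups(sim$db, "A")
  expect_length(groups, 1L)
  expect_length(groups[[1L]]@members, 4L)
})

test_that("the identical-exon quartet collapses to its 6-digit representative", {
  cfg <- simConfig(seed = 65L)
  sim <- simulateAlleleDb(cfg)
  groups <- buildRepresentativeGroups(sim$db, "A")
  sizes <- lengths(lapply(groups, slot, "members"))
  quart <- groups[[which(sizes == 4L)]]
  expect_equal(renderAlleleName(quart@representative), "A*01:01:01")
})

test_that("read counts realize the requested depth", {
  # depth 30x over a 270 bp region with 150 bp reads: 2 x 27 reads
  cfg <- simConfig(genes = "X", nAlleles = 2L, nearDuplicatePairs = 0L,
                   identicalQuartets = 0L, depth = 30,
                   classTable = c(X = "I"),
                   exonLengths = list(I = c(`2` = 270L)), seed = 66L)
  sim <- simulateAlleleDb(cfg)
  nms <- alleleNames(sim$db)
  reads <- simulateDiploidReads(sim$db, "X", nms[1:2], cfg, seed = 67)
  expect_equal(length(reads), 54L)
})

test_that("error-free reads place exactly on their source haplotype", {
  cfg <- simConfig(seed = 68L)
  sim <- simulateAlleleDb(cfg)
  truth <- c("C*05:01", "C*05:01")
  reads <- simulateDiploidReads(sim$db, "C", truth, cfg, seed = 69)
  rec <- sim$db@records[[match(truth[1L], alleleNames(sim$db))]]
  full <- paste(rec@exons[order(as.integer(names(rec@exons)))],
                collapse = "")
  pl <- placeReads(reads, full)
  expect_setequal(unique(pl$read_id), names(reads))
})

test_that("error-bearing reads are imperfect copies at roughly the set rate", {
  cfg <- simConfig(genes = "A", errorRate = 0.01, seed = 70L)
  sim <- simulateAlleleDb(cfg)
  reads <- simulateDiploidReads(sim$db, "A", c("A*03:01", "A*03:01"),
                                cfg, seed = 71)
  rec <- sim$db@records[[match("A*03:01", alleleNames(sim$db))]]
  full <- paste(rec@exons[order(as.integer(names(rec@exons)))],
                collapse = "")
  pl <- placeReads(reads, full)
  fracPlaced <- length(unique(pl$read_id)) / length(reads)
  # P(150 error-free bases) ~ 0.99^150 ~ 0.22; allow a wide band
  expect_gt(fracPlaced, 0.08)
  expect_lt(fracPlaced, 0.5)
})

test_that("downsampling keeps the requested fraction", {
  reads <- readsAt(randSeq(300), rep(0:99, 10), 50)
  expect_length(downsampleReads(reads, 0.05, seed = 72), 50L)
  expect_length(downsampleReads(reads, 1), length(reads))
})

test_that("truth sets draw valid diploid genotypes", {
  cfg <- simConfig(seed = 73L)
  sim <- simulateAlleleDb(cfg)
  truth <- sampleTruthSet(sim$db, 4, seed = 74)
  expect_equal(nrow(truth), 4L * 5L)
  expect_true(all(truth$allele1 %in% alleleNames(sim$db)))
  expect_true(all(truth$allele2 %in% alleleNames(sim$db)))
})
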