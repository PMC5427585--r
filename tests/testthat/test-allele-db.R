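test_that("allele names parse, render and round-trip", {
  nm <- parseAlleleName("A*02:01:01:01")
  expect_s4_class(nm, "AlleleName")
  expect_equal(nm@gene, "A")
  expect_equal(nm@fields, c("02", "01", "01", "01"))
  expect_equal(renderAlleleName(nm), "A*02:01:01:01")

  # leading zeros are text, not numbers
  expect_false(renderAlleleName(parseAlleleName("A*2:01")) ==
                 renderAlleleName(parseAlleleName("A*02:01")))

  # expression suffix round-trips, HLA- prefix is stripped
  expect_equal(renderAlleleName(parseAlleleName("A*02:01:01:02L")),
               "A*02:01:01:02L")
  expect_equal(parseAlleleName("HLA-DQB1*05:02")@gene, "DQB1")

  expect_null(parseAlleleName("notaname"))
  expect_null(parseAlleleName("A*"))
})

test_that("name truncation keeps digits/2 fields and drops the suffix", {
  a <- parseAlleleName("A*02:01:01:01")
  expect_equal(renderAlleleName(truncateAlleleName(a, 4)), "A*02:01")
  expect_equal(renderAlleleName(truncateAlleleName(a, 2)), "A*02")
  # fewer fields than requested: unchanged
  expect_equal(truncateAlleleName("B*55:02:01", 8), "B*55:02:01")
  expect_equal(truncateAlleleName("A*02", 2), "A*02")
  # suffix dropped unless all fields retained
  expect_equal(truncateAlleleName("A*02:01:01:02L", 8), "A*02:01:01:02L")
  expect_equal(truncateAlleleName("A*02:01:01:02L", 6), "A*02:01:01")
})

test_that("truncation is idempotent and monotone over digit levels", {
  set.seed(1)
  names <- c("A*02:01:01:01", "B*55:02:01", "DRB1*07:01", "C*01",
             "A*02:01:01:02L")
  for (nm in names) {
    for (d in c(2, 4, 6, 8)) {
      once <- truncateAlleleName(nm, d)
      expect_equal(truncateAlleleName(once, d), once)
    }
    via4 <- truncateAlleleName(truncateAlleleName(nm, 4), 2)
    expect_equal(via4, truncateAlleleName(nm, 2))
    via6 <- truncateAlleleName(truncateAlleleName(nm, 6), 4)
    expect_equal(via6, truncateAlleleName(nm, 4))
  }
})

test_that("FASTA parsing builds records, skips junk, rejects duplicates", {
  fa <- tempfile(fileext = ".fasta")

  # single record, no exon map: whole sequence becomes exon 2
  writeLines(c(">X*01:01", "ACGT"), fa)
  db <- parseAlleleFasta(fa)
  expect_equal(length(db@records), 1L)
  expect_equal(db@records[[1L]]@exons, c(`2` = "ACGT"))

  # IMGT-style header: allele token is found among other tokens
  writeLines(c(">HLA:HLA00005 A*02:01:01:01 1098 bp", "ACGTACGT"), fa)
  db <- parseAlleleFasta(fa)
  expect_equal(alleleNames(db), "A*02:01:01:01")
  expect_equal(db@records[[1L]]@sourceId, "HLA:HLA00005")

  # unparseable headers are skipped and counted
  writeLines(c(">garbage header", "AAAA", ">B*07:02", "CCCC"), fa)
  db <- parseAlleleFasta(fa)
  expect_equal(alleleNames(db), "B*07:02")
  expect_equal(dbMetadata(db)$nSkipped, 1L)

  # duplicate rendered names error, naming the duplicate
  writeLines(c(">A*01:01", "AAAA", ">A*01:01", "CCCC"), fa)
  expect_error(parseAlleleFasta(fa), "A\\*01:01")

  # empty input errors
  writeLines(character(0), fa)
  expect_error(parseAlleleFasta(fa))
})

test_that("an exon-boundary table splits records into exons", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">A*01:01", "AAACCCGGGTTT"), fa)
  em <- data.frame(allele = c("A*01:01", "A*01:01"), exon = c(2L, 3L),
                   start = c(1L, 7L), end = c(6L, 12L))
  db <- parseAlleleFasta(fa, exonMap = em)
  expect_equal(db@records[[1L]]@exons, c(`2` = "AAACCC", `3` = "GGGTTT"))

  # same table read from TSV
  tsv <- tempfile(fileext = ".tsv")
  write.table(em, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  db2 <- parseAlleleFasta(fa, exonMap = tsv)
  expect_equal(db2@records[[1L]]@exons, db@records[[1L]]@exons)
})

test_that("identical-exon alleles collapse to a shared-prefix representative", {
  set.seed(7)
  e2 <- randSeq(60); e3 <- randSeq(60)
  quartet <- lapply(sprintf("A*02:01:01:%02d", 1:4), mkRecord,
                    exons = c(`2` = e2, `3` = e3))
  db <- mkDb(quartet)
  groups <- buildRepresentativeGroups(db, "A", exons = c(2, 3))
  expect_length(groups, 1L)
  expect_equal(renderAlleleName(groups[[1L]]@representative), "A*02:01:01")
  expect_length(groups[[1L]]@members, 4L)
  expect_equal(groups[[1L]]@typingSequence, paste0(e2, e3))
  expect_equal(groups[[1L]]@exonsUsed, c(2L, 3L))
})

test_that("a single-base difference separates groups; prefixes shorten as needed", {
  set.seed(8)
  e2 <- randSeq(80)
  db <- mkDb(list(mkRecord("A*01:01", c(`2` = e2)),
                  mkRecord("A*02:01", c(`2` = flipBase(e2, 40)))))
  groups <- buildRepresentativeGroups(db, "A", exons = 2)
  expect_length(groups, 2L)
  expect_true(all(lengths(lapply(groups, slot, "members")) == 1L))

  # shared prefix shorter than full names
  db2 <- mkDb(list(mkRecord("A*01:01:01", c(`2` = e2)),
                   mkRecord("A*01:01:02", c(`2` = e2))))
  g2 <- buildRepresentativeGroups(db2, "A", exons = 2)
  expect_length(g2, 1L)
  expect_equal(renderAlleleName(g2[[1L]]@representative), "A*01:01")

  expect_error(buildRepresentativeGroups(db, "ZZ", exons = 2),
               "not in database")
})

test_that("grouping partitions the gene and ignores record order", {
  set.seed(9)
  seqs <- replicate(3, randSeq(50))
  recs <- c(
    lapply(sprintf("B*01:01:%02d", 1:3), mkRecord, exons = c(`2` = seqs[1])),
    list(mkRecord("B*02:01", c(`2` = seqs[2])),
         mkRecord("B*03:01", c(`2` = seqs[3]))))
  db <- mkDb(recs)
  groups <- buildRepresentativeGroups(db, "B", exons = 2)
  members <- unlist(lapply(groups, function(g)
    vapply(g@members, renderAlleleName, character(1))))
  expect_setequal(members, alleleNames(db))       # partition: all present
  expect_equal(sum(lengths(lapply(groups, slot, "members"))),
               length(recs))                      # ... exactly once

  for (perm in list(c(5, 1, 3, 2, 4), rev(seq_along(recs)))) {
    g2 <- buildRepresentativeGroups(mkDb(recs[perm]), "B", exons = 2)
    expect_equal(names(g2), names(groups))
    expect_equal(lapply(g2, slot, "typingSequence"),
                 lapply(groups, slot, "typingSequence"))
  }
})

test_that("records missing a requested exon group among their own kind", {
  set.seed(10)
  e2 <- randSeq(40); e3 <- randSeq(40)
  db <- mkDb(list(
    mkRecord("A*01:01", c(`2` = e2, `3` = e3)),
    mkRecord("A*01:02", c(`2` = e2)),            # exon 3 never deposited
    mkRecord("A*01:03", c(`2` = e2))))
  groups <- buildRepresentativeGroups(db, "A", exons = c(2, 3))
  expect_length(groups, 2L)
  used <- lapply(groups, slot, "exonsUsed")
  expect_setequal(vapply(used, paste, character(1), collapse = ","),
                  c("2,3", "2"))
})

test_that("groups export as JSON with members and exons used", {
  set.seed(11)
  e2 <- randSeq(30)
  db <- mkDb(list(mkRecord("A*01:01:01", c(`2` = e2)),
                  mkRecord("A*01:01:02", c(`2` = e2))))
  groups <- buildRepresentativeGroups(db, "A", exons = 2)
  js <- jsonlite::fromJSON(groupsToJson(groups), simplifyVector = FALSE)
  expect_length(js, 1L)
  expect_equal(js[[1L]]$representative, "A*01:01")
  expect_length(js[[1L]]$members, 2L)
})
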