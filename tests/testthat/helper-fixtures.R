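## Small in-code fixture builders shared across the suite.

randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mkRecord <- function(name, exons, src = "TEST") {
  new("AlleleRecord", name = parseAlleleName(name),
      exons = exons, sourceId = src)
}

mkDb <- function(records, policy = NULL) {
  genes <- unique(vapply(records, function(r) r@name@gene, character(1)))
  if (is.null(policy)) policy <- defaultGeneExonPolicy(genes)
  new("AlleleDatabase", records = records, geneExonPolicy = policy)
}

## error-free fixed-length reads tiled over a sequence at given starts
## (0-based)
readsAt <- function(seq, starts, len, prefix = "r") {
  rds <- substring(seq, starts + 1L, starts + len)
  names(rds) <- sprintf("%s%03d", prefix, seq_along(rds))
  Biostrings::DNAStringSet(rds)
}

## hand-built candidate (the structure produced by buildCandidates)
mkCand <- function(allele, readIds, score = 1, group = NULL) {
  list(allele = allele, score = score, distances = numeric(0),
       nReads = length(readIds), nPlacements = length(readIds),
       readIds = readIds, group = group)
}

## substitute one base (1-based pos) with a different one,
## deterministically
flipBase <- function(seq, pos) {
  old <- substr(seq, pos, pos)
  new <- setdiff(c("A", "C", "G", "T"), old)[1L]
  substr(seq, pos, pos) <- new
  seq
}
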