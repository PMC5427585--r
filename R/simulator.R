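#' Construct a simulation configuration
#'
#' Defaults describe the regime the pipeline targets: a five-gene HLA
#' panel, 150 bp reads, 90x total depth, error-free reads. Exon lengths
#' follow typical class I (exons 2--5 of 270/276/276/117 bp) and class II
#' (exons 2--4 of 270/282/111 bp) exon sizes; alleles differ from a
#' gene's ancestral sequence by sparse substitutions at 2% per base,
#' giving inter-allele distances of a few dozen bases over the typing
#' exons, in line with the polymorphism the score function must tolerate.
#'
#' @param genes,nAlleles,substitutionRate,nearDuplicatePairs,identicalQuartets,readLength,depth,errorRate,classTable,exonLengths,seed
#'   see [SimConfig-class].
#' @return a [SimConfig-class].
#' @export
simConfig <- function(genes = c("A", "B", "C", "DQB1", "DRB1"),
                      nAlleles = 8L,
                      substitutionRate = 0.02,
                      nearDuplicatePairs = 1L,
                      identicalQuartets = 1L,
                      readLength = 150L,
                      depth = 90,
                      errorRate = 0,
                      classTable = c(A = "I", B = "I", C = "I",
                                     DQB1 = "II", DRB1 = "II"),
                      exonLengths = list(
                        I = c(`2` = 270L, `3` = 276L, `4` = 276L,
                              `5` = 117L),
                        II = c(`2` = 270L, `3` = 282L, `4` = 111L)),
                      seed = 1L) {
  classTable <- unlist(classTable)   # tolerate YAML-born lists
  new("SimConfig", genes = genes, nAlleles = as.integer(nAlleles),
      substitutionRate = substitutionRate,
      nearDuplicatePairs = as.integer(nearDuplicatePairs),
      identicalQuartets = as.integer(identicalQuartets),
      readLength = as.integer(readLength), depth = depth,
      errorRate = errorRate, classTable = classTable,
      exonLengths = lapply(exonLengths, function(x)
        stats::setNames(as.integer(x), names(x))),
      seed = as.integer(seed))
}

#' @describeIn SimConfig-class compact display
#' @param object a `SimConfig`
#' @export
setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d gene(s), %d alleles/gene, sub rate %g, %d bp reads at %gx, error %g, seed %d\n",
    length(object@genes), object@nAlleles, object@substitutionRate,
    object@readLength, object@depth, object@errorRate, object@seed))
})

.BASES <- c("A", "C", "G", "T")

.randomSeq <- function(len) {
  paste(sample(.BASES, len, replace = TRUE), collapse = "")
}

## substitute each base independently with probability `rate`, always to
## a different base
.mutateSeq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit)
    ch[i] <- sample(setdiff(.BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

.substituteAt <- function(seq, pos, newBase = NULL) {
  old <- substr(seq, pos, pos)
  if (is.null(newBase)) newBase <- sample(setdiff(.BASES, old), 1L)
  substr(seq, pos, pos) <- newBase
  seq
}

.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Simulate an allele reference database
#'
#' Per gene, an ancestral exon set is drawn at random and mutated into
#' `nAlleles` variant sequences at the configured substitution rate. The
#' catalogue then emulates the two structures that make real allele
#' databases hard: (i) `identicalQuartets` quartets of alleles whose
#' exons are base-for-base identical, distinguished only at the deepest
#' name field (these must collapse to a representative allele); and (ii)
#' `nearDuplicatePairs` pairs of alleles differing at exactly one base of
#' exon 2 (the hardest single-variant discrimination case). When
#' `substitutionRate > 0`, a deterministic repair step guarantees that no
#' unintended allele pair sits within Hamming distance 2, so the
#' requested near-duplicate count is exact.
#'
#' All randomness is fixed by `cfg@seed`: equal configurations give
#' byte-identical databases.
#'
#' @param cfg a [SimConfig-class].
#' @return list with elements `db` (an [AlleleDatabase-class]) and `info`
#'   (data.frames `nearDuplicates` -- gene, allele1, allele2, exon,
#'   position -- and `quartets` -- gene, representative prefix, members).
#' @export
simulateAlleleDb <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  nStructured <- cfg@identicalQuartets + cfg@nearDuplicatePairs
  if (cfg@nAlleles < nStructured)
    stop("'nAlleles' must cover the requested quartets and pairs")
  set.seed(cfg@seed)
  records <- list()
  ndRows <- list()
  qRows <- list()
  for (gene in cfg@genes) {
    cls <- cfg@classTable[[gene]]
    exl <- cfg@exonLengths[[cls]]
    if (any(exl < 1L)) stop("exon length too short")
    ancestral <- vapply(exl, .randomSeq, character(1))
    names(ancestral) <- names(exl)
    variants <- lapply(seq_len(cfg@nAlleles), function(i)
      vapply(ancestral, .mutateSeq, character(1),
             rate = cfg@substitutionRate))
    ## deterministic repair: unintended pairs must be >= 3 apart so the
    ## engineered Hamming-1 pair stays the only pair within distance 1
    if (cfg@substitutionRate > 0) {
      concat <- vapply(variants, paste0, character(1), collapse = "")
      attempt <- 0L
      repeat {
        fixed <- TRUE
        for (i in seq_len(max(0L, cfg@nAlleles - 1L))) {
          for (j in seq(i + 1L, cfg@nAlleles)) {
            if (.hamming(concat[i], concat[j]) < 3L) {
              attempt <- attempt + 1L
              pos <- ((i * 131L + j * 37L + attempt * 61L) %%
                        nchar(variants[[j]][1L])) + 1L
              variants[[j]][1L] <- .substituteAt(variants[[j]][1L], pos)
              concat[j] <- paste0(variants[[j]], collapse = "")
              fixed <- FALSE
            }
          }
        }
        if (fixed || attempt > 1000L) break
      }
    }
    addRecord <- function(fields, exons) {
      nm <- new("AlleleName", gene = gene, fields = fields, suffix = "")
      records[[length(records) + 1L]] <<-
        new("AlleleRecord", name = nm, exons = exons,
            sourceId = paste0("SIM:", renderAlleleName(nm)))
      renderAlleleName(nm)
    }
    idx <- 0L
    for (q in seq_len(cfg@identicalQuartets)) {
      idx <- idx + 1L
      members <- vapply(1:4, function(k)
        addRecord(c(sprintf("%02d", idx), "01", "01", sprintf("%02d", k)),
                  variants[[idx]]), character(1))
      qRows[[length(qRows) + 1L]] <- data.frame(
        gene = gene,
        representative = paste0(gene, "*", sprintf("%02d", idx),
                                ":01:01"),
        members = paste(members, collapse = ","),
        stringsAsFactors = FALSE)
    }
    for (p in seq_len(cfg@nearDuplicatePairs)) {
      idx <- idx + 1L
      base <- variants[[idx]]
      a1 <- addRecord(c(sprintf("%02d", idx), "01"), base)
      pos <- sample.int(nchar(base[["2"]]), 1L)
      twin <- base
      twin[["2"]] <- .substituteAt(twin[["2"]], pos)
      a2 <- addRecord(c(sprintf("%02d", idx), "02"), twin)
      ndRows[[length(ndRows) + 1L]] <- data.frame(
        gene = gene, allele1 = a1, allele2 = a2, exon = 2L,
        position = pos, stringsAsFactors = FALSE)
    }
    while (idx < cfg@nAlleles) {
      idx <- idx + 1L
      addRecord(c(sprintf("%02d", idx), "01"), variants[[idx]])
    }
  }
  pol <- defaultGeneExonPolicy(cfg@genes, cfg@classTable)
  db <- new("AlleleDatabase", records = records, geneExonPolicy = pol,
            metadata = list(simulated = TRUE, seed = cfg@seed))
  info <- list(
    nearDuplicates = if (length(ndRows)) do.call(rbind, ndRows)
                     else data.frame(),
    quartets = if (length(qRows)) do.call(rbind, qRows)
               else data.frame())
  list(db = db, info = info)
}

.recordByName <- function(db, name) {
  i <- match(name, alleleNames(db))
  if (is.na(i)) stop("allele not in database: ", name)
  db@records[[i]]
}

.fullSequence <- function(rec) {
  ord <- order(as.integer(names(rec@exons)))
  paste(rec@exons[ord], collapse = "")
}

#' Simulate diploid reads for one gene
#'
#' Draws error-bearing fixed-length reads from the two haplotypes of a
#' diploid genotype. Read start positions are uniform over each
#' haplotype's concatenated exon sequence; each haplotype receives
#' `depth * L / (2 * readLength)` reads so the two together realize the
#' configured total depth; reads are reverse-complemented with
#' probability 1/2; sequencing errors are independent per-base
#' substitutions at `cfg@errorRate`.
#'
#' @param db an [AlleleDatabase-class].
#' @param gene gene symbol.
#' @param alleles character(2), the two true allele names (identical for
#'   a homozygote).
#' @param cfg a [SimConfig-class] (readLength, depth, errorRate used).
#' @param seed optional integer; when given, fixes this call's
#'   randomness.
#' @return a named [Biostrings::DNAStringSet] (FASTQ-writable with
#'   [writeReadsFastq()]).
#' @export
simulateDiploidReads <- function(db, gene, alleles, cfg, seed = NULL) {
  stopifnot(length(alleles) == 2L)
  if (!is.null(seed)) set.seed(seed)
  out <- character(0)
  for (hap in 1:2) {
    rec <- .recordByName(db, alleles[hap])
    seqc <- .fullSequence(rec)
    L <- nchar(seqc)
    if (L < cfg@readLength)
      stop("haplotype region (", L, " bp) shorter than read length")
    n <- max(0L, as.integer(round(cfg@depth * L / (2 * cfg@readLength))))
    if (n == 0L) next
    starts <- sample.int(L - cfg@readLength + 1L, n, replace = TRUE)
    rds <- substring(seqc, starts, starts + cfg@readLength - 1L)
    if (cfg@errorRate > 0)
      rds <- vapply(rds, .mutateSeq, character(1), rate = cfg@errorRate,
                    USE.NAMES = FALSE)
    flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (any(flip))
      rds[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(rds[flip])))
    names(rds) <- sprintf("sim_%s_h%d_r%04d", gene, hap, seq_len(n))
    out <- c(out, rds)
  }
  Biostrings::DNAStringSet(out)
}

#' Simulate the full read set of one diploid sample
#'
#' @param db an [AlleleDatabase-class].
#' @param truth data.frame with columns `gene`, `allele1`, `allele2`
#'   (one row per gene).
#' @param cfg a [SimConfig-class].
#' @param seed optional integer fixing this sample's randomness.
#' @return a named [Biostrings::DNAStringSet] over all genes.
#' @export
simulateSample <- function(db, truth, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  parts <- lapply(seq_len(nrow(truth)), function(i)
    simulateDiploidReads(db, truth$gene[i],
                         c(truth$allele1[i], truth$allele2[i]), cfg))
  do.call(c, parts)
}

#' Draw random diploid truth genotypes from a database
#'
#' @param db an [AlleleDatabase-class].
#' @param nSamples number of samples.
#' @param genes gene symbols; defaults to all in `db`.
#' @param homFraction probability that a genotype is homozygous.
#' @param seed optional integer.
#' @return data.frame with columns `sample`, `gene`, `allele1`,
#'   `allele2`.
#' @export
sampleTruthSet <- function(db, nSamples, genes = hlaGenes(db),
                           homFraction = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nms <- alleleNames(db)
  geneOf <- vapply(db@records, function(r) r@name@gene, character(1))
  rows <- list()
  for (s in seq_len(nSamples)) {
    for (g in genes) {
      pool <- nms[geneOf == g]
      a1 <- sample(pool, 1L)
      a2 <- if (stats::runif(1) < homFraction || length(pool) == 1L) a1
            else sample(setdiff(pool, a1), 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sprintf("S%03d", s), gene = g, allele1 = a1,
        allele2 = a2, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Randomly downsample a read set
#'
#' Keeps `round(length(reads) * fraction)` reads drawn without
#' replacement, emulating the random read-selection used to probe
#' performance at reduced depth.
#'
#' @param reads a [Biostrings::DNAStringSet].
#' @param fraction in (0, 1].
#' @param seed optional integer.
#' @return the downsampled [Biostrings::DNAStringSet].
#' @export
downsampleReads <- function(reads, fraction, seed = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- round(length(reads) * fraction)
  reads[sort(sample.int(length(reads), k))]
}

#' Write reads as FASTQ
#'
#' @param reads a named [Biostrings::DNAStringSet].
#' @param file output path (".gz" suffix compresses).
#' @export
writeReadsFastq <- function(reads, file) {
  quals <- Biostrings::BStringSet(vapply(
    BiocGenerics::width(reads),
    function(w) paste(rep("I", w), collapse = ""), character(1)))
  Biostrings::writeXStringSet(reads, file, format = "fastq",
                              qualities = quals,
                              compress = endsWith(file, ".gz"))
  invisible(file)
}

#' Write an allele database as FASTA (+ exon-boundary TSV)
#'
#' Each record's exons are concatenated into one FASTA record whose
#' header carries the allele name; the companion exon map records the
#' 1-based inclusive boundaries of each exon within the record, so
#' [parseAlleleFasta()] round-trips the database.
#'
#' @param db an [AlleleDatabase-class].
#' @param file FASTA output path.
#' @param exonMapFile optional TSV output path for the exon boundaries.
#' @export
writeAlleleFasta <- function(db, file, exonMapFile = NULL) {
  seqs <- character(length(db@records))
  headers <- character(length(db@records))
  maps <- list()
  for (i in seq_along(db@records)) {
    rec <- db@records[[i]]
    ord <- order(as.integer(names(rec@exons)))
    ex <- rec@exons[ord]
    seqs[i] <- paste(ex, collapse = "")
    nm <- renderAlleleName(rec@name)
    headers[i] <- sprintf("%s %s %d bp", rec@sourceId, nm,
                          nchar(seqs[i]))
    ends <- cumsum(nchar(ex))
    maps[[i]] <- data.frame(allele = nm,
                            exon = as.integer(names(ex)),
                            start = c(1L, utils::head(ends, -1L) + 1L),
                            end = ends, stringsAsFactors = FALSE)
  }
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- headers
  Biostrings::writeXStringSet(dss, file)
  if (!is.null(exonMapFile))
    utils::write.table(do.call(rbind, maps), exonMapFile, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(file)
}
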