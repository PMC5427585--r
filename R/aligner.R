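#' Read short reads from FASTQ
#'
#' Thin wrapper over Biostrings FASTQ input: sequences are kept, quality
#' strings are parsed but unused (placement is exact-match, so base
#' qualities carry no extra information). Read ids are the header up to
#' the first whitespace.
#'
#' @param file path to a FASTQ file (plain or gzip).
#' @return a named [Biostrings::DNAStringSet].
#' @export
readReadsFastq <- function(file) {
  reads <- Biostrings::readDNAStringSet(file, format = "fastq")
  names(reads) <- sub("[[:space:]].*$", "", names(reads))
  reads
}

## Precompiled exact matcher: reads indexed once (both strands, split by
## width) into hash maps sequence -> read ids, reusable against many
## typing sequences. A full-length exact match of a w-mer read is a hit
## of its sequence among the subject's w-mers, so lookup per subject is
## one vectorized hashed match() per width and strand. Reads containing
## any non-ACGT letter (N included) can never match under the
## 100%-identity rule and are dropped up front.
.exactMatcher <- function(reads) {
  stopifnot(is(reads, "DNAStringSet"))
  if (length(reads) == 0L) return(list(groups = list()))
  if (is.null(names(reads)))
    names(reads) <- paste0("read", seq_along(reads))
  seqs <- as.character(reads)
  ok <- grepl("^[ACGT]+$", seqs)
  seqs <- seqs[ok]
  if (length(seqs) == 0L) return(list(groups = list()))
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  ids <- names(reads)[ok]
  byw <- split(seq_along(seqs), nchar(seqs))
  groups <- lapply(byw, function(idx) list(
    w = nchar(seqs[idx[1L]]),
    fwd = split(ids[idx], seqs[idx]),
    rev = split(ids[idx], rev[idx])))
  list(groups = groups)
}

## Match a precompiled matcher against one typing sequence (character).
## Returns the placement data.frame: 0-based inclusive coordinates,
## duplicate placements of one read at one locus collapsed ("+" wins for
## palindromic reads).
.matchAgainst <- function(matcher, typingSequence) {
  L <- nchar(typingSequence)
  parts <- list()
  for (g in matcher$groups) {
    if (g$w > L) next
    n <- L - g$w + 1L
    kmers <- substring(typingSequence, seq_len(n), seq_len(n) + g$w - 1L)
    for (strand in c("+", "-")) {
      map <- if (strand == "+") g$fwd else g$rev
      m <- match(kmers, names(map))
      pos <- which(!is.na(m))
      if (length(pos) == 0L) next
      idlist <- map[m[pos]]
      nper <- lengths(idlist)
      parts[[length(parts) + 1L]] <- data.frame(
        read_id = unlist(idlist, use.names = FALSE),
        start = rep(pos - 1L, nper),
        end = rep(pos + g$w - 2L, nper),
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (length(parts) == 0L)
    return(data.frame(read_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, parts)
  df <- df[order(match(df$strand, c("+", "-"))), , drop = FALSE]  # "+" wins
  df <- df[!duplicated(df[, c("read_id", "start", "end")]), , drop = FALSE]
  df <- df[order(df$start, df$end, df$read_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Place reads on a typing sequence by exact full-length match
#'
#' Reports every position where a read, or its reverse complement,
#' matches the typing sequence with 100% identity over its full length;
#' reads with any mismatch are discarded entirely, and reads containing N
#' never match. A palindromic read matching one locus on both strands is
#' reported once (plus strand). A read matching several loci contributes
#' all of them.
#'
#' @param reads a named [Biostrings::DNAStringSet] (or a single character
#'   string for one read).
#' @param typingSequence character(1) nucleotide sequence.
#' @return data.frame with columns `read_id`, `start`, `end` (0-based
#'   inclusive), `strand`; zero rows when nothing matches.
#' @examples
#' placeReads(Biostrings::DNAStringSet(c(r1 = "ACGT")), "TTACGTTT")
#' @export
placeReads <- function(reads, typingSequence) {
  if (is.character(reads))
    reads <- Biostrings::DNAStringSet(stats::setNames(reads, "read1"))
  .matchAgainst(.exactMatcher(reads), typingSequence)
}

#' Center coordinate of a placement, in doubled units
#'
#' The center of a read placed at 0-based inclusive `[start, end]` is
#' `(start + end) / 2`, which is a half-integer for even read lengths.
#' To keep all downstream distance arithmetic exact, centers are carried
#' as `start + end` (twice the base-pair coordinate); divide by 2 to
#' convert to bp.
#'
#' @param start,end 0-based inclusive placement coordinates (vectorized).
#' @return numeric vector of doubled center coordinates.
#' @examples
#' readCenter(0, 149)   # 149, i.e. center 74.5 bp
#' @export
readCenter <- function(start, end) {
  as.numeric(start) + as.numeric(end)
}

#' Build per-allele alignment profiles
#'
#' Places a read set on every representative group's typing sequence and
#' derives the sorted read-center coordinates. A read may contribute to
#' many alleles; per allele, duplicate placements of one read at one
#' locus are collapsed. Profiles are independent of read input order.
#'
#' @param reads a named [Biostrings::DNAStringSet].
#' @param groups list of [RepresentativeGroup-class].
#' @return named list of [AlignmentProfile-class], one per representative.
#' @export
buildProfiles <- function(reads, groups) {
  stopifnot(length(groups) > 0L)
  matcher <- .exactMatcher(reads)
  profs <- lapply(groups, function(g) {
    pl <- .matchAgainst(matcher, g@typingSequence)
    new("AlignmentProfile",
        allele = renderAlleleName(g@representative),
        placements = pl,
        centers = sort(readCenter(pl$start, pl$end)),
        regionLength = nchar(g@typingSequence))
  })
  names(profs) <- vapply(groups, function(g)
    renderAlleleName(g@representative), character(1))
  profs
}

#' Export placements as TSV
#'
#' @param placements placement data.frame (see [placeReads()]), or an
#'   [AlignmentProfile-class].
#' @param file output path.
#' @param allele optional allele name column value when `placements` is a
#'   bare data.frame.
#' @export
writePlacementsTsv <- function(placements, file, allele = NA_character_) {
  if (is(placements, "AlignmentProfile")) {
    allele <- placements@allele
    placements <- placements@placements
  }
  out <- data.frame(read_id = placements$read_id,
                    allele = rep(allele, nrow(placements)),
                    placements[, c("start", "end", "strand"),
                               drop = FALSE],
                    stringsAsFactors = FALSE)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @describeIn AlignmentProfile-class summary display
#' @param object an `AlignmentProfile`
#' @export
setMethod("show", "AlignmentProfile", function(object) {
  cat(sprintf("AlignmentProfile for %s: %d placement(s) on %d bp\n",
              object@allele, nrow(object@placements),
              object@regionLength))
})
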