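#' Default per-gene exon policy
#'
#' Class I genes (A, B, C by default) are typed primarily on exons 2 and
#' 3, with exons 4 and 5 as fallback; class II genes (DQB1, DRB1) on exon
#' 2 with exons 3 and 4 as fallback. These exons encode the peptide
#' binding groove and carry almost all typing-relevant polymorphism; many
#' catalogued alleles have only them deposited.
#'
#' @param genes character vector of gene symbols.
#' @param classTable named character vector mapping gene to `"I"`/`"II"`.
#' @return named list: gene -> `list(primary =, fallback =)` integer
#'   exon indices.
#' @export
defaultGeneExonPolicy <- function(genes = names(classTable),
                                  classTable = c(A = "I", B = "I", C = "I",
                                                 DQB1 = "II", DRB1 = "II")) {
  pol <- lapply(genes, function(g) {
    cls <- if (g %in% names(classTable)) classTable[[g]] else "I"
    if (cls == "I")
      list(primary = c(2L, 3L), fallback = c(4L, 5L))
    else
      list(primary = 2L, fallback = c(3L, 4L))
  })
  names(pol) <- genes
  pol
}

## Pick the allele-name token out of a FASTA header line.
.nameFromHeader <- function(header) {
  tokens <- strsplit(trimws(header), "[[:space:]]+")[[1]]
  for (tok in tokens) {
    nm <- parseAlleleName(tok)
    if (!is.null(nm)) return(nm)
  }
  NULL
}

#' Read an allele reference database from FASTA
#'
#' Each FASTA record must carry an allele-name token in its header (e.g.
#' `>HLA:HLA00005 A*01:01:01:01 1098 bp`). Without an exon-boundary
#' table each record's whole sequence is treated as a single typing exon
#' with index 2; with one, per-exon sequences are cut out of the record.
#' Records whose header contains no parseable allele name are skipped and
#' counted in `metadata(db)$skipped`.
#'
#' @param file path to a FASTA file (plain or gzip).
#' @param exonMap optional exon-boundary table: a data.frame (or path to
#'   a TSV with header) with columns `allele`, `exon`, `start`, `end`;
#'   coordinates 1-based inclusive within the FASTA record.
#' @param geneExonPolicy per-gene typing exon policy; see
#'   [defaultGeneExonPolicy()]. Genes found in the file but absent from
#'   the policy get the class I default.
#' @return an [AlleleDatabase-class].
#' @export
parseAlleleFasta <- function(file, exonMap = NULL,
                             geneExonPolicy = defaultGeneExonPolicy()) {
  seqs <- Biostrings::readDNAStringSet(file)
  if (length(seqs) == 0L) stop("no FASTA records in ", file)
  if (is.character(exonMap) && length(exonMap) == 1L)
    exonMap <- utils::read.delim(exonMap, stringsAsFactors = FALSE)
  if (!is.null(exonMap))
    stopifnot(all(c("allele", "exon", "start", "end") %in% colnames(exonMap)))
  records <- list()
  skipped <- character(0)
  for (i in seq_along(seqs)) {
    header <- names(seqs)[i]
    nm <- .nameFromHeader(header)
    if (is.null(nm)) {
      skipped <- c(skipped, header)
      next
    }
    full <- toupper(as.character(seqs[[i]]))
    rendered <- renderAlleleName(nm)
    if (!is.null(exonMap) && rendered %in% exonMap$allele) {
      rows <- exonMap[exonMap$allele == rendered, , drop = FALSE]
      exons <- vapply(seq_len(nrow(rows)), function(j)
        substr(full, rows$start[j], rows$end[j]), character(1))
      names(exons) <- as.character(rows$exon)
    } else {
      exons <- c(`2` = full)
    }
    rec <- new("AlleleRecord", name = nm, exons = exons,
               sourceId = sub("[[:space:]].*$", "", header))
    dup <- vapply(records, function(r) renderAlleleName(r@name),
                  character(1))
    if (rendered %in% dup)
      stop("duplicate allele name in FASTA: ", rendered)
    records[[length(records) + 1L]] <- rec
  }
  if (length(records) == 0L)
    stop("no FASTA record had a parseable allele name")
  genesSeen <- unique(vapply(records, function(r) r@name@gene, character(1)))
  missing <- setdiff(genesSeen, names(geneExonPolicy))
  if (length(missing))
    geneExonPolicy <- c(geneExonPolicy, defaultGeneExonPolicy(missing))
  new("AlleleDatabase", records = records,
      geneExonPolicy = geneExonPolicy,
      metadata = list(skipped = skipped, nSkipped = length(skipped)))
}

#' @rdname AlleleDatabase-class
#' @param db an [AlleleDatabase-class]
#' @return `alleleNames()`: rendered names of all records.
#' @export
alleleNames <- function(db) {
  vapply(db@records, function(r) renderAlleleName(r@name), character(1))
}

#' @rdname AlleleDatabase-class
#' @return `hlaGenes()`: gene symbols present in the database.
#' @export
hlaGenes <- function(db) {
  unique(vapply(db@records, function(r) r@name@gene, character(1)))
}

#' @rdname AlleleDatabase-class
#' @param gene gene symbol
#' @return `exonPolicy()`: `list(primary =, fallback =)` for `gene`.
#' @export
exonPolicy <- function(db, gene) {
  pol <- db@geneExonPolicy[[gene]]
  if (is.null(pol)) pol <- defaultGeneExonPolicy(gene)[[1L]]
  pol
}

#' @rdname AlleleDatabase-class
#' @return `dbMetadata()`: the metadata list.
#' @export
dbMetadata <- function(db) db@metadata

#' @rdname AlleleDatabase-class
#' @param names rendered allele names to keep
#' @return `subsetDatabase()`: a database restricted to `names`.
#' @export
subsetDatabase <- function(db, names) {
  keep <- alleleNames(db) %in% names
  new("AlleleDatabase", records = db@records[keep],
      geneExonPolicy = db@geneExonPolicy, metadata = db@metadata)
}

#' @describeIn AlleleDatabase-class summary display
#' @param object an `AlleleDatabase`
#' @export
setMethod("show", "AlleleDatabase", function(object) {
  gs <- vapply(object@records, function(r) r@name@gene, character(1))
  cat("AlleleDatabase with", length(object@records), "alleles\n")
  tab <- table(gs)
  cat(paste0("  ", names(tab), ": ", as.integer(tab), collapse = "\n"), "\n")
})

#' Collapse alleles with identical typing exons into groups
#'
#' Alleles of `gene` are partitioned by exact equality of their
#' concatenated typing-exon sequences. A read placed on one member is
#' placed identically on all, so each group is carried forward under a
#' representative name: the longest leading run of name fields shared by
#' all members (e.g. four eight-digit alleles `02:01:01:01`--`:04` with
#' identical exons collapse to representative `02:01:01`). Records
#' missing some requested exon are grouped among records with the same
#' available subset, and the exons actually used are recorded per group.
#'
#' @param db an [AlleleDatabase-class].
#' @param gene gene symbol present in `db`.
#' @param exons integer vector of requested exon indices; defaults to the
#'   gene's primary policy exons.
#' @return list of [RepresentativeGroup-class], ordered by representative
#'   name. The partition property holds: every record of the gene appears
#'   in exactly one group.
#' @export
buildRepresentativeGroups <- function(db, gene,
                                      exons = exonPolicy(db, gene)$primary) {
  recs <- Filter(function(r) r@name@gene == gene, db@records)
  if (length(recs) == 0L) stop("gene not in database: ", gene)
  exons <- sort(as.integer(exons))
  keys <- vapply(recs, function(r) {
    have <- intersect(as.character(exons), names(r@exons))
    paste0(paste(have, collapse = ","), "|",
           paste(r@exons[have], collapse = "-"))
  }, character(1))
  groups <- split(recs, keys)
  out <- lapply(groups, function(members) {
    nms <- lapply(members, slot, "name")
    have <- intersect(as.character(exons), names(members[[1L]]@exons))
    if (length(have) == 0L)
      stop("allele ", renderAlleleName(nms[[1L]]),
           " has none of the requested exons (",
           paste(exons, collapse = ","), ")")
    tseq <- paste(members[[1L]]@exons[have], collapse = "")
    shared <- .sharedFieldPrefix(nms)
    flagged <- FALSE
    if (shared == 0L && length(nms) > 1L) {
      rendered <- vapply(nms, renderAlleleName, character(1))
      rep <- nms[[order(rendered)[1L]]]
      flagged <- TRUE
    } else if (length(nms) == 1L) {
      rep <- nms[[1L]]
    } else {
      rep <- new("AlleleName", gene = gene,
                 fields = nms[[1L]]@fields[seq_len(shared)], suffix = "")
    }
    new("RepresentativeGroup", representative = rep, members = nms,
        typingSequence = tseq, exonsUsed = as.integer(have),
        flagged = flagged)
  })
  ## representative names must be unique across groups; a computed prefix
  ## can in principle coincide with another group's name -- fall back to
  ## the smallest member name for the colliders
  repNames <- vapply(out, function(g) renderAlleleName(g@representative),
                     character(1))
  clash <- repNames %in% repNames[duplicated(repNames)]
  if (any(clash)) {
    out[clash] <- lapply(out[clash], function(g) {
      rendered <- vapply(g@members, renderAlleleName, character(1))
      g@representative <- g@members[[order(rendered)[1L]]]
      g@flagged <- TRUE
      g
    })
    repNames <- vapply(out, function(g) renderAlleleName(g@representative),
                       character(1))
  }
  out <- out[order(repNames)]
  names(out) <- sort(repNames)
  out
}

#' Export representative groups as JSON
#'
#' @param groups list of [RepresentativeGroup-class].
#' @param file optional path; when given, JSON is written there.
#' @return the JSON string, invisibly when written to file.
#' @export
groupsToJson <- function(groups, file = NULL) {
  x <- lapply(groups, function(g) list(
    representative = renderAlleleName(g@representative),
    members = vapply(g@members, renderAlleleName, character(1)),
    exons_used = g@exonsUsed,
    flagged = g@flagged))
  names(x) <- NULL
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}

#' @describeIn RepresentativeGroup-class compact display
#' @param object a `RepresentativeGroup`
#' @export
setMethod("show", "RepresentativeGroup", function(object) {
  cat("RepresentativeGroup", renderAlleleName(object@representative),
      sprintf("(%d member%s, exons %s, %d bp)\n", length(object@members),
              if (length(object@members) == 1L) "" else "s",
              paste(object@exonsUsed, collapse = ","),
              nchar(object@typingSequence)))
})
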