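#' @import methods
NULL

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Structured HLA allele name
#'
#' Represents one allele name in colon-delimited field notation, e.g.
#' `A*02:01:01:01` or `DQB1*05:02`: a short gene symbol, one to four numeric
#' name fields, and an optional trailing expression-suffix letter (N, L, S,
#' C, A or Q). Name fields are kept as text so that leading zeros survive
#' (`"02"` is not the same field as `"2"`).
#'
#' @slot gene character(1), gene symbol (e.g. `"A"`, `"DQB1"`).
#' @slot fields character vector of 1--4 numeric name fields, in order.
#' @slot suffix character(1), expression suffix letter or `""`.
#'
#' @seealso [parseAlleleName()], [renderAlleleName()], [truncateAlleleName()]
#' @export
setClass("AlleleName",
         slots = c(gene = "character", fields = "character",
                   suffix = "character"),
         prototype = prototype(suffix = ""))

setValidity("AlleleName", function(object) {
  msg <- character(0)
  if (length(object@gene) != 1L || !nzchar(object@gene))
    msg <- c(msg, "'gene' must be a single non-empty string")
  if (length(object@fields) < 1L)
    msg <- c(msg, "at least one name field is required")
  if (!all(grepl("^[0-9]+$", object@fields)))
    msg <- c(msg, "name fields must be numeric strings")
  if (length(object@suffix) != 1L || !grepl("^[A-Z]?$", object@suffix))
    msg <- c(msg, "'suffix' must be \"\" or a single capital letter")
  if (length(msg)) msg else TRUE
})

#' One allele reference record
#'
#' One named allele together with its deposited exon sequences, keyed by
#' exon index. Real allele catalogues deposit different exon subsets for
#' different alleles, so the exon map is allowed to be sparse.
#'
#' @slot name an [AlleleName-class].
#' @slot exons named character vector of nucleotide sequences; names are
#'   exon indices (as characters of integers >= 1).
#' @slot sourceId character(1), free-text accession from the FASTA header.
#' @export
setClass("AlleleRecord",
         slots = c(name = "AlleleName", exons = "character",
                   sourceId = "character"))

setValidity("AlleleRecord", function(object) {
  msg <- character(0)
  ex <- object@exons
  if (length(ex) < 1L)
    msg <- c(msg, "a record needs at least one exon sequence")
  if (is.null(names(ex)) || anyDuplicated(names(ex)) ||
      !all(grepl("^[0-9]+$", names(ex))) ||
      any(as.integer(names(ex)) < 1L))
    msg <- c(msg, "exon indices must be unique integers >= 1")
  if (any(!nzchar(ex)))
    msg <- c(msg, "exon sequences must be non-empty")
  if (!all(grepl("^[ACGTN]*$", ex)))
    msg <- c(msg, "exon sequences must be over {A,C,G,T,N}")
  if (length(object@sourceId) != 1L)
    msg <- c(msg, "'sourceId' must be a single string")
  if (length(msg)) msg else TRUE
})

#' Allele reference database
#'
#' A collection of [AlleleRecord-class] objects plus the per-gene exon
#' policy used for typing: which exons are matched first (primary) and
#' which are consulted when the primary exons do not separate the
#' remaining candidates (fallback). The defaults follow the usual
#' class I / class II convention: class I genes type on exons 2 and 3
#' with exons 4 and 5 in reserve; class II genes type on exon 2 with
#' exons 3 and 4 in reserve.
#'
#' @slot records list of [AlleleRecord-class].
#' @slot geneExonPolicy named list, gene -> `list(primary =, fallback =)`
#'   integer vectors of exon indices.
#' @slot metadata free-form list (parser statistics, simulation truth, ...).
#'
#' @seealso [parseAlleleFasta()], [buildRepresentativeGroups()]
#' @export
setClass("AlleleDatabase",
         slots = c(records = "list", geneExonPolicy = "list",
                   metadata = "list"),
         prototype = prototype(metadata = list()))

setValidity("AlleleDatabase", function(object) {
  msg <- character(0)
  if (!all(vapply(object@records, is, logical(1), "AlleleRecord")))
    msg <- c(msg, "'records' must all be AlleleRecord objects")
  else {
    nms <- vapply(object@records,
                  function(r) renderAlleleName(r@name), character(1))
    if (anyDuplicated(nms))
      msg <- c(msg, paste0("duplicate allele name(s): ",
                           paste(unique(nms[duplicated(nms)]),
                                 collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Group of alleles with identical typing exons
#'
#' Alleles whose typing-exon sequences are base-for-base identical cannot
#' be separated by any read and are collapsed into one group, carried
#' forward under a representative name: the longest shared leading field
#' prefix of the member names. All downstream placement, scoring and
#' calling operate on representatives.
#'
#' @slot representative an [AlleleName-class], truncated to the shared
#'   prefix of the members.
#' @slot members list of member [AlleleName-class]s.
#' @slot typingSequence character(1), concatenated shared typing exons.
#' @slot exonsUsed integer vector of exon indices actually concatenated.
#' @slot flagged logical(1), `TRUE` when the members shared no field
#'   prefix and the representative fell back to the smallest member name.
#' @export
setClass("RepresentativeGroup",
         slots = c(representative = "AlleleName", members = "list",
                   typingSequence = "character", exonsUsed = "integer",
                   flagged = "logical"),
         prototype = prototype(flagged = FALSE))

setValidity("RepresentativeGroup", function(object) {
  msg <- character(0)
  if (length(object@members) < 1L)
    msg <- c(msg, "a group needs at least one member")
  if (length(object@typingSequence) != 1L || !nzchar(object@typingSequence))
    msg <- c(msg, "'typingSequence' must be one non-empty string")
  if (length(msg)) msg else TRUE
})

#' Parameters of the read-distribution score
#'
#' The score of a candidate allele is \eqn{\sum_j (D_j / c)^e} over the
#' distances \eqn{D_j} between centers of consecutive placed reads;
#' alleles scoring above `cutoff` are discarded. `c` rescales distances to
#' the spacing expected from even coverage (30 bp for 150 bp reads), and
#' the cubic exponent makes a single uncovered read-length stretch
#' (D = 150) score exactly the default cutoff of 125.
#'
#' @slot c positive scale constant, in bp.
#' @slot exponent positive exponent (integer-valued).
#' @slot cutoff positive score cutoff; candidates scoring above it are
#'   discarded, a score equal to the cutoff is retained.
#' @slot includeBoundaries logical(1); when `TRUE` (default) the distances
#'   from the region start to the first center and from the last center to
#'   the region end are also penalized, so an allele covered only in its
#'   middle does not get a free pass.
#'
#' @seealso [scoreParams()], [scoreDistances()], [filterByScore()]
#' @export
setClass("ScoreParams",
         slots = c(c = "numeric", exponent = "numeric", cutoff = "numeric",
                   includeBoundaries = "logical"))

setValidity("ScoreParams", function(object) {
  msg <- character(0)
  if (length(object@c) != 1L || !is.finite(object@c) || object@c <= 0)
    msg <- c(msg, "'c' must be a single positive number")
  if (length(object@exponent) != 1L || object@exponent < 1)
    msg <- c(msg, "'exponent' must be >= 1")
  if (length(object@cutoff) != 1L || object@cutoff <= 0)
    msg <- c(msg, "'cutoff' must be positive")
  if (length(object@includeBoundaries) != 1L)
    msg <- c(msg, "'includeBoundaries' must be a single logical")
  if (length(msg)) msg else TRUE
})

#' Read placements on one allele
#'
#' All exact full-length placements of a read set on one representative
#' allele's typing sequence, plus the derived read-center coordinates.
#' Centers are stored in doubled-integer units (`start + end`, 0-based
#' inclusive coordinates) so half-integer centers stay exact; divide by 2
#' to get base-pair positions.
#'
#' @slot allele character(1), rendered representative allele name.
#' @slot placements data.frame with columns `read_id`, `start`, `end`
#'   (0-based inclusive), `strand` (`"+"`/`"-"`).
#' @slot centers numeric vector, sorted ascending, doubled units.
#' @slot regionLength integer(1), length of the typing sequence in bp.
#' @export
setClass("AlignmentProfile",
         slots = c(allele = "character", placements = "data.frame",
                   centers = "numeric", regionLength = "integer"))

setValidity("AlignmentProfile", function(object) {
  msg <- character(0)
  if (nrow(object@placements) != length(object@centers))
    msg <- c(msg, "one center per placement is required")
  if (is.unsorted(object@centers))
    msg <- c(msg, "'centers' must be sorted ascending")
  if (length(object@regionLength) != 1L || object@regionLength < 1L)
    msg <- c(msg, "'regionLength' must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration
#'
#' Parameters of the synthetic allele database and diploid read sets.
#' Defaults emulate a five-gene HLA panel typed from 150 bp reads at 90x
#' total depth with error-free reads; per gene the simulated catalogue
#' contains a quartet of alleles with identical exons (exercising
#' representative grouping) and one pair of alleles differing at exactly
#' one base of a typing exon (the hardest discrimination case).
#'
#' @slot genes character vector of gene symbols.
#' @slot nAlleles integer(1), distinct allele sequences per gene (the
#'   quartet members share one of these sequences).
#' @slot substitutionRate numeric(1), per-base substitution probability
#'   applied when deriving each allele from the gene's ancestral sequence.
#' @slot nearDuplicatePairs integer(1), number of allele pairs per gene at
#'   Hamming distance exactly 1.
#' @slot identicalQuartets integer(1), number of identical-exon quartets
#'   per gene.
#' @slot readLength integer(1), bp.
#' @slot depth numeric(1), total target depth (x) across both haplotypes.
#' @slot errorRate numeric(1), per-base sequencing error probability.
#' @slot classTable named character vector, gene -> `"I"` or `"II"`.
#' @slot exonLengths list with elements `I` and `II`: named integer
#'   vectors of exon lengths (names are exon indices).
#' @slot seed integer(1); fixes all randomness of database generation.
#'
#' @seealso [simConfig()], [simulateAlleleDb()], [simulateDiploidReads()]
#' @export
setClass("SimConfig",
         slots = c(genes = "character", nAlleles = "integer",
                   substitutionRate = "numeric",
                   nearDuplicatePairs = "integer",
                   identicalQuartets = "integer",
                   readLength = "integer", depth = "numeric",
                   errorRate = "numeric", classTable = "character",
                   exonLengths = "list", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@nAlleles < 1L) msg <- c(msg, "'nAlleles' must be >= 1")
  if (object@nearDuplicatePairs < 0L || object@identicalQuartets < 0L)
    msg <- c(msg, "pair/quartet counts must be >= 0")
  if (object@depth <= 0) msg <- c(msg, "'depth' must be positive")
  if (object@readLength < 1L) msg <- c(msg, "'readLength' must be >= 1")
  if (object@substitutionRate < 0 || object@substitutionRate > 1 ||
      object@errorRate < 0 || object@errorRate > 1)
    msg <- c(msg, "rates must be in [0, 1]")
  if (!all(object@genes %in% names(object@classTable)))
    msg <- c(msg, "every gene needs a class in 'classTable'")
  if (!all(unique(object@classTable) %in% names(object@exonLengths)))
    msg <- c(msg, "every class needs exon lengths")
  if (length(msg)) msg else TRUE
})

#' Final genotype call for one gene
#'
#' The one- or two-allele call emitted after score filtering, duplicate
#' removal and unique-read phasing. A heterozygote call carries two
#' representative alleles, each supported by at least one uniquely aligned
#' read; a homozygote call carries one. When no candidate has unique reads
#' (all survivors mutually redundant) a homozygote call on the
#' best-covered candidate is emitted and flagged low-confidence.
#'
#' @slot gene character(1).
#' @slot alleles character vector of 0 (no-call), 1 (hom) or 2 (het)
#'   rendered representative allele names.
#' @slot zygosity `"het"`, `"hom"` or `"none"`.
#' @slot uniqueReadCounts named integer, unique supporting reads per
#'   called allele.
#' @slot totalReads named integer, all placed reads per called allele.
#' @slot scores named numeric, read-distribution score per called allele.
#' @slot resolution integer(1), digits resolved (2 x fields of the least
#'   resolved called name; 0 for a no-call).
#' @slot exonsUsed integer vector of exon indices the call was typed on.
#' @slot flags character vector of diagnostic flags.
#' @export
setClass("GenotypeCall",
         slots = c(gene = "character", alleles = "character",
                   zygosity = "character", uniqueReadCounts = "integer",
                   totalReads = "integer", scores = "numeric",
                   resolution = "integer", exonsUsed = "integer",
                   flags = "character"))

setValidity("GenotypeCall", function(object) {
  msg <- character(0)
  z <- object@zygosity
  if (length(z) != 1L || !z %in% c("het", "hom", "none"))
    msg <- c(msg, "'zygosity' must be het, hom or none")
  else {
    n <- length(object@alleles)
    if (z == "het" && n != 2L) msg <- c(msg, "het calls carry two alleles")
    if (z == "hom" && n != 1L) msg <- c(msg, "hom calls carry one allele")
    if (z == "none" && n != 0L) msg <- c(msg, "no-calls carry no allele")
  }
  if (length(msg)) msg else TRUE
})
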