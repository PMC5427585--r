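#' Construct score parameters
#'
#' @param c positive scale constant in bp; 30 matches 150 bp reads (see
#'   [suggestedScoreConstant()]).
#' @param exponent exponent of the penalty; the default cube gives the
#'   best separation between evenly and unevenly covered alleles.
#' @param cutoff score cutoff; candidates scoring above it are discarded.
#'   With c = 30 and the cubic exponent, 125 is the score of a single
#'   uncovered read-length (150 bp) stretch.
#' @param includeBoundaries also penalize the uncovered distance from the
#'   region start to the first read center and from the last center to
#'   the region end.
#' @return a [ScoreParams-class].
#' @examples
#' scoreDistances(150, scoreParams())   # 125
#' @export
scoreParams <- function(c = 30, exponent = 3, cutoff = 125,
                        includeBoundaries = TRUE) {
  new("ScoreParams", c = as.numeric(c), exponent = as.numeric(exponent),
      cutoff = as.numeric(cutoff),
      includeBoundaries = isTRUE(includeBoundaries))
}

#' @describeIn ScoreParams-class compact display
#' @param object a `ScoreParams`
#' @export
setMethod("show", "ScoreParams", function(object) {
  cat(sprintf("ScoreParams: c = %g bp, exponent = %g, cutoff = %g, boundaries %s\n",
              object@c, object@exponent, object@cutoff,
              if (object@includeBoundaries) "on" else "off"))
})

#' Scale constant suggested for a read length
#'
#' The default c = 30 assumes 150 bp reads, i.e. each position covered on
#' average five times at the reference depth, so adjacent read centers sit
#' about read_length/5 apart under even coverage. For other read lengths
#' the same reasoning gives c = read_length / 5.
#'
#' @param readLength read length in bp.
#' @return suggested c, in bp.
#' @export
suggestedScoreConstant <- function(readLength) {
  stopifnot(readLength > 0)
  readLength / 5
}

#' Distances between consecutive read centers
#'
#' Converts a profile's sorted center coordinates (doubled units, see
#' [readCenter()]) into the inter-center distances D_j in bp:
#' `D_j = (center_{j+1} - center_j) / 2`. With `includeBoundaries` on,
#' two extra distances are appended: from the region start (position 0)
#' to the first center, and from the last center to the region end
#' (position `regionLength`); an empty profile then yields the single
#' distance `regionLength`, the maximal possible gap.
#'
#' @param centers numeric vector of center coordinates in doubled units,
#'   sorted ascending.
#' @param regionLength length of the typing sequence in bp.
#' @param includeBoundaries logical; see above.
#' @return numeric vector of distances in bp (possibly half-integers).
#' @examples
#' interCenterDistances(c(200, 500), 600, includeBoundaries = FALSE) # 150
#' @export
interCenterDistances <- function(centers, regionLength,
                                 includeBoundaries = TRUE) {
  stopifnot(!is.unsorted(centers))
  if (length(centers) == 0L)
    return(if (includeBoundaries) as.numeric(regionLength) else numeric(0))
  d <- diff(centers) / 2
  if (includeBoundaries)
    d <- c(centers[1L] / 2, d,
           regionLength - centers[length(centers)] / 2)
  as.numeric(d)
}

#' Read-distribution score
#'
#' `Score = sum_j (D_j / c) ^ exponent` over the inter-center distances of
#' a candidate allele. Evenly tiled reads keep every D_j near c/|spacing|
#' scale and the score small; a single uncovered stretch of one read
#' length (150 bp at the defaults) alone contributes the default cutoff
#' of 125.
#'
#' @param distances numeric vector of D_j in bp (all >= 0); an empty
#'   vector scores 0.
#' @param params a [ScoreParams-class].
#' @return the score, a non-negative number.
#' @examples
#' scoreDistances(c(60, 90), scoreParams())   # 8 + 27 = 35
#' @export
scoreDistances <- function(distances, params = scoreParams()) {
  if (length(distances) == 0L) return(0)
  if (any(distances < 0)) stop("negative inter-center distance")
  sum((distances / params@c) ^ params@exponent)
}

#' Score one alignment profile
#'
#' @param profile an [AlignmentProfile-class].
#' @param params a [ScoreParams-class].
#' @return list with `allele`, `score`, `distances`, `nReads` (distinct
#'   read ids), `nPlacements`.
#' @export
scoreProfile <- function(profile, params = scoreParams()) {
  d <- interCenterDistances(profile@centers, profile@regionLength,
                            params@includeBoundaries)
  list(allele = profile@allele,
       score = scoreDistances(d, params),
       distances = d,
       nReads = length(unique(profile@placements$read_id)),
       nPlacements = nrow(profile@placements))
}

#' Build scored candidates from profiles
#'
#' One candidate per profile, carrying the read-id set needed by
#' duplicate removal and phasing downstream.
#'
#' @param profiles named list of [AlignmentProfile-class] (from
#'   [buildProfiles()]); names are representative allele names.
#' @param params a [ScoreParams-class].
#' @param groups optional matching list of [RepresentativeGroup-class];
#'   when given, each candidate keeps a reference to its group (needed by
#'   the fallback cascade).
#' @return list of candidate lists with elements `allele`, `readIds`,
#'   `nReads`, `nPlacements`, `score`, `distances`, `group`.
#' @export
buildCandidates <- function(profiles, params = scoreParams(),
                            groups = NULL) {
  out <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    s <- scoreProfile(p, params)
    c(s, list(readIds = unique(p@placements$read_id),
              group = if (is.null(groups)) NULL else groups[[i]]))
  })
  names(out) <- names(profiles)
  out
}

#' Filter candidates by the score cutoff
#'
#' Retains candidates whose score does not exceed the cutoff (a score
#' exactly at the cutoff survives; only scores strictly above it are
#' discarded). Candidates with zero placed reads are always discarded.
#'
#' @param candidates list of candidates from [buildCandidates()].
#' @param params a [ScoreParams-class].
#' @return the retained subset, same structure.
#' @export
filterByScore <- function(candidates, params = scoreParams()) {
  Filter(function(cand)
    cand$nReads >= 1L && cand$score <= params@cutoff, candidates)
}

#' Candidate score table
#'
#' @param candidates list of candidates from [buildCandidates()].
#' @param params a [ScoreParams-class] (for the retained flag).
#' @param file optional TSV output path.
#' @return data.frame with `allele`, `n_reads`, `score`, `retained`.
#' @export
scoreTable <- function(candidates, params = scoreParams(), file = NULL) {
  df <- data.frame(
    allele = vapply(candidates, `[[`, character(1), "allele"),
    n_reads = vapply(candidates, `[[`, integer(1), "nReads"),
    score = vapply(candidates, `[[`, numeric(1), "score"),
    stringsAsFactors = FALSE)
  df$retained <- df$n_reads >= 1L & df$score <= params@cutoff
  rownames(df) <- NULL
  if (!is.null(file))
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  df
}
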