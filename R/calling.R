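#' Remove duplicated (subset) candidate alleles
#'
#' A candidate whose placed reads form a proper subset of another
#' candidate's reads carries no read of its own that could distinguish it
#' (every read it holds is also explained by the superset allele), so it
#' is removed; candidates with unique sequence evidence are retained by
#' construction, since holding any read absent from the superset breaks
#' the subset relation. Removal is computed against the original
#' candidate set in one pass, which makes it idempotent and invariant to
#' input order.
#'
#' @param candidates list of candidates (see [buildCandidates()]), each
#'   with a `readIds` element.
#' @return the retained subset, same structure and relative order.
#' @export
removeSubsetDuplicates <- function(candidates) {
  n <- length(candidates)
  if (n <= 1L) return(candidates)
  sets <- lapply(candidates, `[[`, "readIds")
  drop <- vapply(seq_len(n), function(i) {
    si <- sets[[i]]
    for (j in seq_len(n)) {
      if (j == i) next
      sj <- sets[[j]]
      if (length(si) < length(sj) && all(si %in% sj)) return(TRUE)
    }
    FALSE
  }, logical(1))
  candidates[!drop]
}

#' Count reads unique to one candidate
#'
#' Number of read ids placed on `readIds`'s candidate and on no candidate
#' in `others`. Unique reads are the evidence unit for the final call:
#' true alleles are more likely to carry them than false alleles, and the
#' count must be recomputed after duplicate removal because false
#' candidates absorb uniqueness.
#'
#' @param readIds character vector of the candidate's read ids.
#' @param others list of character vectors: the other candidates' read
#'   ids.
#' @return integer count.
#' @export
countUniqueReads <- function(readIds, others) {
  sum(!readIds %in% unique(unlist(others)))
}

## Ranking table used by callGenotype and the fallback trigger: unique
## read count desc, then total reads desc, then score asc, then name.
.phaseCandidates <- function(candidates) {
  n <- length(candidates)
  uniq <- vapply(seq_len(n), function(i)
    countUniqueReads(candidates[[i]]$readIds,
                     lapply(candidates[-i], `[[`, "readIds")), integer(1))
  df <- data.frame(
    allele = vapply(candidates, `[[`, character(1), "allele"),
    unique_reads = uniq,
    n_reads = vapply(candidates, `[[`, integer(1), "nReads"),
    score = vapply(candidates, `[[`, numeric(1), "score"),
    stringsAsFactors = FALSE)
  df$idx <- seq_len(n)
  df[order(-df$unique_reads, -df$n_reads, df$score, df$allele), ,
     drop = FALSE]
}

.noCall <- function(gene, exonsUsed = integer(0), flags = "no_call") {
  new("GenotypeCall", gene = gene, alleles = character(0),
      zygosity = "none", uniqueReadCounts = integer(0),
      totalReads = integer(0), scores = numeric(0), resolution = 0L,
      exonsUsed = as.integer(exonsUsed), flags = flags)
}

#' Call the genotype from phased candidates
#'
#' Candidates (already score-filtered and subset-deduplicated) are ranked
#' by unique read count; ties break by total placed reads, then lower
#' score, then name, so the call is deterministic. If the top two
#' candidates both hold uniquely aligned reads the call is heterozygous
#' with both; if only the top one does, homozygous. When no candidate has
#' any unique read (all survivors mutually redundant) a homozygous call
#' on the best-covered candidate is emitted with a low-confidence flag.
#' An empty candidate set yields a no-call, not an error.
#'
#' @param candidates list of candidates (see [buildCandidates()]).
#' @param gene gene symbol for the call.
#' @param exonsUsed integer vector recorded in the call.
#' @return a [GenotypeCall-class].
#' @export
callGenotype <- function(candidates, gene, exonsUsed = integer(0)) {
  if (length(candidates) == 0L) return(.noCall(gene, exonsUsed))
  ranked <- .phaseCandidates(candidates)
  flags <- character(0)
  if (nrow(ranked) >= 2L && ranked$unique_reads[1L] >= 1L &&
      ranked$unique_reads[2L] >= 1L) {
    pick <- ranked[1:2, ]
    zyg <- "het"
    flags <- c(flags, sprintf("unique_support=%d/%d",
                              pick$unique_reads[1L],
                              pick$unique_reads[2L]))
  } else if (ranked$unique_reads[1L] >= 1L) {
    pick <- ranked[1L, ]
    zyg <- "hom"
  } else {
    ranked <- ranked[order(-ranked$n_reads, ranked$score, ranked$allele), ,
                     drop = FALSE]
    pick <- ranked[1L, ]
    zyg <- "hom"
    flags <- c(flags, "low_confidence_no_unique_reads")
  }
  fieldsOf <- function(a) length(parseAlleleName(a)@fields)
  new("GenotypeCall", gene = gene, alleles = pick$allele,
      zygosity = zyg,
      uniqueReadCounts = stats::setNames(as.integer(pick$unique_reads),
                                         pick$allele),
      totalReads = stats::setNames(as.integer(pick$n_reads), pick$allele),
      scores = stats::setNames(pick$score, pick$allele),
      resolution = 2L * min(vapply(pick$allele, fieldsOf, integer(1))),
      exonsUsed = as.integer(exonsUsed), flags = flags)
}

## One grouping -> profiling -> scoring -> dedup -> call pass over a
## fixed exon set. Returns the call plus per-stage candidate counts and
## the surviving candidates (for the fallback trigger).
.typePass <- function(reads, db, gene, params, exons) {
  groups <- buildRepresentativeGroups(db, gene, exons)
  profiles <- buildProfiles(reads, groups)
  cands <- buildCandidates(profiles, params, groups)
  passed <- filterByScore(cands, params)
  dedup <- removeSubsetDuplicates(passed)
  call <- callGenotype(dedup, gene,
                       exonsUsed = sort(unique(unlist(
                         lapply(dedup, function(cd) cd$group@exonsUsed),
                         use.names = FALSE))))
  if (length(call@exonsUsed) == 0L)
    call@exonsUsed <- sort(as.integer(exons))
  list(call = call, candidates = dedup,
       stages = data.frame(stage = c("groups", "score_pass", "dedup",
                                     "called"),
                           n = c(length(groups), length(passed),
                                 length(dedup), length(call@alleles))))
}

## Fallback trigger: either more than two candidates tie at the top of
## the unique-read ranking (the pair is not determined), or a finalist
## group hides members that differ over the fallback exons (deeper
## resolution is possible).
.needsFallback <- function(pass, db, gene, primary, fallback) {
  cands <- pass$candidates
  if (length(cands) == 0L || length(fallback) == 0L) return(FALSE)
  ranked <- .phaseCandidates(cands)
  if (nrow(ranked) > 2L && ranked$unique_reads[3L] == ranked$unique_reads[2L])
    return(TRUE)
  allExons <- union(primary, fallback)
  for (a in pass$call@alleles) {
    i <- match(a, vapply(cands, `[[`, character(1), "allele"))
    grp <- cands[[i]]$group
    if (length(grp@members) < 2L) next
    sub <- subsetDatabase(db, vapply(grp@members, renderAlleleName,
                                     character(1)))
    if (length(buildRepresentativeGroups(sub, gene, allExons)) > 1L)
      return(TRUE)
  }
  FALSE
}

## Full per-gene cascade with optional fallback-exon rerun.
.typeGene <- function(reads, db, gene, params = scoreParams(),
                      fallback = TRUE) {
  pol <- exonPolicy(db, gene)
  pass1 <- .typePass(reads, db, gene, params, pol$primary)
  stages <- cbind(pass = "primary", pass1$stages)
  result <- pass1
  usedFallback <- FALSE
  if (fallback && .needsFallback(pass1, db, gene, pol$primary,
                                 pol$fallback)) {
    contention <- unique(unlist(lapply(pass1$candidates, function(cd)
      vapply(cd$group@members, renderAlleleName, character(1)))))
    sub <- subsetDatabase(db, contention)
    pass2 <- .typePass(reads, sub, gene, params,
                       union(pol$primary, pol$fallback))
    stages <- rbind(stages, cbind(pass = "fallback", pass2$stages))
    if (pass2$call@zygosity != "none") {
      result <- pass2
      usedFallback <- TRUE
    }
  }
  call <- result$call
  if (usedFallback)
    call@flags <- c(call@flags, "fallback_exons")
  list(call = call, stages = stages, candidates = result$candidates)
}

#' Type one gene
#'
#' Runs the full per-gene cascade: representative grouping over the
#' primary typing exons, exact-match read placement, read-distribution
#' scoring and cutoff filtering, subset-duplicate removal, and the
#' unique-read genotype call. If the primary exons leave the top of the
#' ranking ambiguous (more than two tied candidates) or a finalist group
#' can still be split by the fallback exons, the cascade is rerun over
#' primary plus fallback exons restricted to the alleles still in
#' contention, and the more resolved call is returned; `exonsUsed` in the
#' call records which exons decided it.
#'
#' @param reads a named [Biostrings::DNAStringSet].
#' @param db an [AlleleDatabase-class].
#' @param gene gene symbol.
#' @param params a [ScoreParams-class].
#' @param fallback logical; rerun with fallback exons when needed.
#' @return a [GenotypeCall-class].
#' @export
typeGene <- function(reads, db, gene, params = scoreParams(),
                     fallback = TRUE) {
  .typeGene(reads, db, gene, params, fallback)$call
}

#' Type all genes of a sample
#'
#' @param reads a named [Biostrings::DNAStringSet].
#' @param db an [AlleleDatabase-class].
#' @param genes gene symbols to type; defaults to all genes in `db`.
#' @param params a [ScoreParams-class].
#' @param fallback logical; see [typeGene()].
#' @return named list of [GenotypeCall-class], one per gene.
#' @export
typeHLA <- function(reads, db, genes = hlaGenes(db),
                    params = scoreParams(), fallback = TRUE) {
  calls <- lapply(genes, function(g)
    typeGene(reads, db, g, params, fallback))
  names(calls) <- genes
  calls
}

#' Tabulate genotype calls
#'
#' Flattens calls into one row per gene. Homozygous calls repeat the
#' allele in both columns (the genotype has two slots); no-calls leave
#' both `NA`. With `digits`, reported names are truncated to that
#' resolution.
#'
#' @param calls a [GenotypeCall-class], or a (possibly named) list of
#'   them.
#' @param sample optional sample id column value.
#' @param digits optional 2/4/6/8 truncation of reported names.
#' @return data.frame with columns `sample` (if given), `gene`,
#'   `allele1`, `allele2`, `zygosity`, `unique1`, `unique2`, `score1`,
#'   `score2`, `resolution`, `exons_used`, `flags`.
#' @export
genotypeTable <- function(calls, sample = NULL, digits = NULL) {
  if (is(calls, "GenotypeCall")) calls <- list(calls)
  rows <- lapply(calls, function(cl) {
    al <- cl@alleles
    if (!is.null(digits) && length(al))
      al <- vapply(al, truncateAlleleName, character(1), digits = digits)
    a1 <- if (length(al) >= 1L) al[1L] else NA_character_
    a2 <- if (length(al) >= 2L) al[2L] else a1
    get2 <- function(v, miss) c(v, rep(miss, 2L))[1:2]
    u <- get2(unname(cl@uniqueReadCounts), NA_integer_)
    s <- get2(unname(cl@scores), NA_real_)
    if (cl@zygosity == "hom") { u[2L] <- u[1L]; s[2L] <- s[1L] }
    data.frame(gene = cl@gene, allele1 = a1, allele2 = a2,
               zygosity = cl@zygosity, unique1 = u[1L], unique2 = u[2L],
               score1 = s[1L], score2 = s[2L],
               resolution = cl@resolution,
               exons_used = paste(cl@exonsUsed, collapse = ","),
               flags = paste(cl@flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (!is.null(sample)) df <- cbind(sample = sample, df)
  df
}

#' @describeIn GenotypeCall-class compact display
#' @param object a `GenotypeCall`
#' @export
setMethod("show", "GenotypeCall", function(object) {
  al <- if (length(object@alleles)) paste(object@alleles, collapse = " / ")
        else "no call"
  cat(sprintf("GenotypeCall %s: %s [%s]", object@gene, al,
              object@zygosity))
  if (length(object@uniqueReadCounts))
    cat(sprintf(", unique reads %s",
                paste(object@uniqueReadCounts, collapse = "/")))
  if (length(object@exonsUsed))
    cat(sprintf(", exons %s", paste(object@exonsUsed, collapse = ",")))
  if (length(object@flags))
    cat(sprintf(" (%s)", paste(object@flags, collapse = "; ")))
  cat("\n")
})
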