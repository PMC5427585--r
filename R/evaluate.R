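## Does a called allele name match a truth allele name at the requested
## resolution? Both are truncated to `digits`; a match is field-wise
## prefix agreement in either direction, so a representative-level call
## (e.g. 02:01:01) matches any of its members (02:01:01:01 ...).
.alleleMatches <- function(called, truth, digits = 8) {
  if (is.na(called) || is.na(truth)) return(FALSE)
  a <- parseAlleleName(called)
  b <- parseAlleleName(truth)
  if (is.null(a) || is.null(b) || a@gene != b@gene) return(FALSE)
  a <- truncateAlleleName(a, digits)
  b <- truncateAlleleName(b, digits)
  .isFieldPrefix(a, b) || .isFieldPrefix(b, a)
}

## correct/missing/wrong for one genotype: called and truth are
## character(2) slots (hom = allele repeated, no-call = NA). The two
## slots are matched as an unordered pair: the pairing maximizing the
## number of matches wins.
.matchGenotype <- function(called, truth, digits) {
  missing <- sum(is.na(called))
  m <- function(i, j) .alleleMatches(called[i], truth[j], digits)
  straight <- sum(m(1, 1), m(2, 2))
  crossed <- sum(m(1, 2), m(2, 1))
  correct <- max(straight, crossed)
  c(correct = correct, missing = missing,
    wrong = 2L - correct - missing)
}

#' Score genotype calls against a truth set
#'
#' Each diploid genotype contributes two allele slots, matched against
#' the truth as an unordered pair at the requested digit resolution
#' (representative-level calls match any member of their group). Slots
#' are classified as correct, missing (no-call) or wrong; the three
#' always sum to two per genotype.
#'
#' @param calls data.frame with columns `sample`, `gene`, `allele1`,
#'   `allele2` (see [genotypeTable()]; no-calls have `NA` alleles).
#' @param truth data.frame with the same columns.
#' @param digits resolution of the comparison (2/4/6/8).
#' @return data.frame with one row per gene plus an `"overall"` row:
#'   `gene`, `n_slots`, `correct`, `missing`, `wrong`, `accuracy`.
#' @export
evaluateCalls <- function(calls, truth, digits = 4) {
  key <- function(df) paste(df$sample, df$gene)
  if (!setequal(key(calls), key(truth)) ||
      nrow(calls) != nrow(truth))
    stop("calls and truth must cover the same samples and genes")
  calls <- calls[match(key(truth), key(calls)), , drop = FALSE]
  tallies <- vapply(seq_len(nrow(truth)), function(i) {
    .matchGenotype(c(calls$allele1[i], calls$allele2[i]),
                   c(truth$allele1[i], truth$allele2[i]), digits)
  }, numeric(3))
  per <- data.frame(gene = truth$gene, t(tallies),
                    stringsAsFactors = FALSE)
  agg <- stats::aggregate(cbind(correct, missing, wrong) ~ gene,
                          data = per, FUN = sum)
  agg <- agg[order(agg$gene), , drop = FALSE]
  total <- data.frame(gene = "overall",
                      correct = sum(agg$correct),
                      missing = sum(agg$missing),
                      wrong = sum(agg$wrong))
  out <- rbind(agg, total)
  out$n_slots <- out$correct + out$missing + out$wrong
  out$accuracy <- out$correct / out$n_slots
  rownames(out) <- NULL
  out[, c("gene", "n_slots", "correct", "missing", "wrong", "accuracy")]
}

#' Sensitivity/specificity sweep over depth and score cutoff
#'
#' For every (depth, cutoff) cell the full pipeline is rerun on
#' simulated reads and scored at the allele-call level against the
#' gene's representative panel: sensitivity is the fraction of true
#' alleles called, specificity the fraction of non-true panel alleles
#' not called. Replicates are paired across depths: each sample's reads
#' are simulated once at the highest depth and nested random subsets
#' realize the lower depths, so depth comparisons are not confounded by
#' sampling noise. All randomness derives from `cfg@seed`.
#'
#' @param db an [AlleleDatabase-class].
#' @param truth truth set data.frame (`sample`, `gene`, `allele1`,
#'   `allele2`), e.g. from [sampleTruthSet()].
#' @param depths numeric vector of total depths (x) to test.
#' @param cutoffs numeric vector of score cutoffs to test.
#' @param cfg a [SimConfig-class] (readLength, errorRate, seed used).
#' @param params base [ScoreParams-class]; the cutoff is overridden per
#'   cell.
#' @param file optional TSV output path.
#' @return data.frame with columns `depth`, `cutoff`, `tp`, `fn`, `fp`,
#'   `tn`, `sensitivity`, `specificity`.
#' @export
depthSweep <- function(db, truth, depths, cutoffs = 125, cfg = simConfig(),
                       params = scoreParams(), file = NULL) {
  stopifnot(length(depths) >= 1L, length(cutoffs) >= 1L)
  maxDepth <- max(depths)
  genes <- unique(truth$gene)
  panelSize <- vapply(genes, function(g)
    length(buildRepresentativeGroups(db, g)), integer(1))
  names(panelSize) <- genes
  samples <- unique(truth$sample)
  acc <- array(0L, dim = c(length(depths), length(cutoffs), 4L),
               dimnames = list(NULL, NULL, c("tp", "fn", "fp", "tn")))
  cfgMax <- cfg
  cfgMax@depth <- maxDepth
  for (si in seq_along(samples)) {
    rows <- truth[truth$sample == samples[si], , drop = FALSE]
    seedS <- as.integer((abs(cfg@seed) * 7919 + si * 104729) %%
                          .Machine$integer.max)
    set.seed(seedS)
    for (gi in seq_len(nrow(rows))) {
      g <- rows$gene[gi]
      truthAlleles <- unique(c(rows$allele1[gi], rows$allele2[gi]))
      reads <- simulateDiploidReads(db, g,
                                    c(rows$allele1[gi], rows$allele2[gi]),
                                    cfgMax)
      perm <- sample.int(length(reads))
      for (di in seq_along(depths)) {
        k <- round(length(reads) * depths[di] / maxDepth)
        sub <- reads[sort(utils::head(perm, k))]
        for (ci in seq_along(cutoffs)) {
          p <- params
          p@cutoff <- as.numeric(cutoffs[ci])
          call <- typeGene(sub, db, g, p)
          called <- call@alleles
          tp <- sum(vapply(truthAlleles, function(t)
            any(vapply(called, .alleleMatches, logical(1), truth = t)),
            logical(1)))
          fp <- sum(vapply(called, function(a)
            !any(vapply(truthAlleles, .alleleMatches, logical(1),
                        called = a)), logical(1)))
          fn <- length(truthAlleles) - tp
          tn <- panelSize[[g]] - length(truthAlleles) - fp
          acc[di, ci, ] <- acc[di, ci, ] +
            c(tp = tp, fn = fn, fp = fp, tn = max(0L, tn))
        }
      }
    }
  }
  grid <- expand.grid(di = seq_along(depths), ci = seq_along(cutoffs))
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(r) {
    di <- grid$di[r]; ci <- grid$ci[r]
    v <- acc[di, ci, ]
    data.frame(depth = depths[di], cutoff = cutoffs[ci],
               tp = v[["tp"]], fn = v[["fn"]], fp = v[["fp"]],
               tn = v[["tn"]],
               sensitivity = v[["tp"]] / (v[["tp"]] + v[["fn"]]),
               specificity = v[["tn"]] / (v[["tn"]] + v[["fp"]]))
  }))
  rownames(out) <- NULL
  if (!is.null(file))
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
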