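#' Parse an allele name from text
#'
#' Accepts the colon-delimited field notation `gene*f1:f2[:f3[:f4]][X]`
#' where each `f` is a numeric field (leading zeros significant) and `X`
#' an optional expression-suffix letter; an optional `HLA-` prefix on the
#' gene symbol is stripped. Rendering the result with
#' [renderAlleleName()] round-trips through this parser.
#'
#' @param x character(1), e.g. `"A*02:01:01:01"` or `"HLA-DQB1*05:02"`.
#' @return an [AlleleName-class], or `NULL` if `x` does not parse.
#' @examples
#' nm <- parseAlleleName("A*02:01:01:01")
#' renderAlleleName(nm)
#' @export
parseAlleleName <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- regexec("^(?:HLA-)?([A-Za-z][A-Za-z0-9-]*)\\*([0-9]+(?::[0-9]+)*)\\s?([A-Z]?)$",
               x)
  g <- regmatches(x, m)[[1]]
  if (length(g) == 0L) return(NULL)
  fields <- strsplit(g[3], ":", fixed = TRUE)[[1]]
  if (length(fields) < 1L || length(fields) > 4L) return(NULL)
  new("AlleleName", gene = g[2], fields = fields, suffix = g[4])
}

#' Render an allele name as text
#'
#' @param name an [AlleleName-class] (a character string is passed
#'   through unchanged, which lets rendered names be used interchangeably).
#' @return character(1) in `gene*f1:f2...` notation, suffix appended.
#' @export
renderAlleleName <- function(name) {
  if (is.character(name)) return(name)
  stopifnot(is(name, "AlleleName"))
  paste0(name@gene, "*", paste(name@fields, collapse = ":"), name@suffix)
}

#' Truncate an allele name to a digit resolution
#'
#' Allele names are reported at two-digit (first field, antigen group),
#' four-digit (two fields, protein), six- or eight-digit resolution. A
#' request for `digits` keeps the first `digits/2` fields; the expression
#' suffix is dropped unless every field is retained. Names with fewer
#' fields than requested are returned unchanged. Truncation is idempotent
#' and monotone: truncating to 4 then 2 digits equals truncating to 2.
#'
#' @param name an [AlleleName-class] or a parseable character(1).
#' @param digits 2, 4, 6 or 8.
#' @return an [AlleleName-class] (or character(1) when `name` was
#'   character).
#' @examples
#' renderAlleleName(truncateAlleleName(parseAlleleName("A*02:01:01:01"), 4))
#' @export
truncateAlleleName <- function(name, digits) {
  stopifnot(digits %in% c(2, 4, 6, 8))
  asChar <- is.character(name)
  if (asChar) {
    parsed <- parseAlleleName(name)
    if (is.null(parsed)) stop("cannot parse allele name: ", name)
    name <- parsed
  }
  keep <- min(length(name@fields), digits / 2)
  out <- new("AlleleName", gene = name@gene,
             fields = name@fields[seq_len(keep)],
             suffix = if (keep == length(name@fields)) name@suffix else "")
  if (asChar) renderAlleleName(out) else out
}

## Longest shared leading field prefix of a set of AlleleNames (same gene).
## Returns integer >= 0 (number of shared fields).
.sharedFieldPrefix <- function(names) {
  fl <- lapply(names, slot, "fields")
  k <- min(lengths(fl))
  shared <- 0L
  for (i in seq_len(k)) {
    fi <- vapply(fl, `[`, character(1), i)
    if (length(unique(fi)) == 1L) shared <- i else break
  }
  shared
}

## field-wise "is prefix of" (same gene, fields of a lead those of b)
.isFieldPrefix <- function(a, b) {
  if (a@gene != b@gene) return(FALSE)
  na <- length(a@fields)
  na <= length(b@fields) && all(a@fields == b@fields[seq_len(na)])
}

#' @describeIn AlleleName-class compact display
#' @param object an `AlleleName`
#' @export
setMethod("show", "AlleleName", function(object) {
  cat("AlleleName:", renderAlleleName(object), "\n")
})
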