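## Internal helpers shared across modules.

.datatable.aware <- TRUE

METH_CONTEXTS <- c("CG", "CHG", "CHH")
CONTROL_CHROM <- "lambda_control"

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## round() in R is round-half-even; reported percentages use half-up
## as conventionally printed.
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

## All randomness descends from one user seed; each pipeline stage draws
## from its own substream so stages are independently reproducible.
substreamSeed <- function(seed, offset) {
  s <- (as.numeric(seed) * 97L + offset) %% 2147483647
  as.integer(s)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

checkContext <- function(context) {
  bad <- setdiff(unique(as.character(context)), METH_CONTEXTS)
  if (length(bad) > 0) {
    stop("unknown methylation context value(s): ", paste(bad, collapse = ", "),
         " (expected CG, CHG or CHH)")
  }
  invisible(TRUE)
}

## seqlengths for a set of reports, falling back to observed maxima when
## the objects carry no Seqinfo.
inferSeqlengths <- function(...) {
  grs <- list(...)
  sl <- GenomeInfoDb::seqlengths(grs[[1]])
  if (all(!is.na(sl)) && length(sl) > 0) return(sl)
  pos <- lapply(grs, function(g) {
    tapply(BiocGenerics::end(g), as.character(GenomicRanges::seqnames(g)), max)
  })
  chroms <- unique(unlist(lapply(pos, names)))
  out <- vapply(chroms, function(ch) {
    max(vapply(pos, function(p) if (ch %in% names(p)) p[[ch]] else 0, 0))
  }, 0)
  out
}
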