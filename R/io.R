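#' Derive the sequence context of every cytosine in a reference
#'
#' Scans both strands of a reference sequence and classifies every cytosine
#' as CG, CHG or CHH (H = A, T or C) from the two bases immediately 3' of
#' it on its own strand. On the plus strand a C at position `i` is
#' classified by bases `i+1, i+2`; a minus-strand cytosine appears as a G
#' at `i` on the plus strand and is classified by the reverse complement of
#' bases `i-1, i-2`. A cytosine whose two-base window contains an N or runs
#' off the chromosome end is omitted, since its context is undefined.
#'
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @return A [CytosineReport] skeleton: `GRanges` of width-1 cytosine
#'   positions with `context`, and zero counts (fill in counts from an
#'   experiment or simulation).
#' @examples
#' genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTACAGTACTTT"))
#' extractContexts(genome)
#' @export
#' @importFrom Biostrings DNAStringSet readDNAStringSet
extractContexts <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("reference sequences must carry unique names")
  names(genome) <- sub("\\s.*$", "", names(genome))
  parts <- lapply(seq_along(genome), function(i) {
    chars <- strsplit(as.character(genome[[i]]), "", fixed = TRUE)[[1]]
    if (length(bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))) > 0)
      stop("invalid characters in sequence '", names(genome)[i], "': ",
           paste(bad, collapse = ", "))
    L <- length(chars)
    if (L == 0) return(NULL)
    valid <- chars %in% c("A", "C", "G", "T")
    b1 <- c(chars[-1], "N")            # base at i+1
    b2 <- c(chars[-(1:2)], "N", "N")   # base at i+2
    v1 <- c(valid[-1], FALSE)
    v2 <- c(valid[-(1:2)], FALSE, FALSE)
    ## plus strand: C with two valid downstream bases
    pPos <- which(chars == "C" & v1 & v2)
    pCtx <- ifelse(b1[pPos] == "G", "CG",
                   ifelse(b2[pPos] == "G", "CHG", "CHH"))
    ## minus strand: G on plus strand; its 3' neighbours are i-1, i-2
    ## (complemented), so CG iff base i-1 is C, CHG iff base i-2 is C
    a1 <- c("N", chars[-L])            # base at i-1
    a2 <- c("N", "N", chars[-((L - 1):L)])
    u1 <- c(FALSE, valid[-L])
    u2 <- c(FALSE, FALSE, valid[-((L - 1):L)])
    mPos <- which(chars == "G" & u1 & u2)
    mCtx <- ifelse(a1[mPos] == "C", "CG",
                   ifelse(a2[mPos] == "C", "CHG", "CHH"))
    if (length(pPos) + length(mPos) == 0) return(NULL)
    data.frame(
      chrom = names(genome)[i],
      pos = c(pPos, mPos),
      strand = rep(c("+", "-"), c(length(pPos), length(mPos))),
      context = c(pCtx, mCtx),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, parts)
  sl <- stats::setNames(Biostrings::width(genome), names(genome))
  if (is.null(df) || nrow(df) == 0) {
    return(CytosineReport(character(), integer(), character(), character(),
                          integer(), integer(), seqlengths = sl))
  }
  o <- order(match(df$chrom, names(genome)), df$pos)
  df <- df[o, ]
  CytosineReport(df$chrom, df$pos, df$strand, df$context,
                 0L, 0L, seqlengths = sl)
}

METHRATIO_HEADER <- c("chrom", "pos", "strand", "context",
                      "ratio", "eff_CT_count", "C_count")

#' Read a methratio-style per-cytosine methylation table
#'
#' The dialect is tab-separated with header
#' `chrom pos strand context ratio eff_CT_count C_count`; `pos` is 1-based,
#' `context` is CG/CHG/CHH, `C_count` the methylated reads and
#' `eff_CT_count` the total covering reads. Gzip-compressed files are
#' accepted. Rows violating the record invariants are rejected with their
#' line numbers.
#'
#' @param path Path to the (optionally gzipped) TSV.
#' @return A [CytosineReport].
#' @export
#' @importFrom data.table fread
readMethylome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path)
    on.exit(try(close(con), silent = TRUE), add = TRUE)
    dt <- utils::read.delim(con, check.names = FALSE, colClasses = c(
      "character", "integer", "character", "character", "numeric",
      "integer", "integer"))
  } else {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = c(1, 3, 4)),
                            showProgress = FALSE)
  }
  if (!identical(colnames(dt), METHRATIO_HEADER))
    stop("unexpected methylome header in ", path, ": ",
         paste(colnames(dt), collapse = ", "))
  if (nrow(dt) == 0) {
    return(CytosineReport(character(), integer(), character(), character(),
                          integer(), integer()))
  }
  ## +1 for the header line, so messages give file line numbers
  lineNo <- seq_len(nrow(dt)) + 1L
  fail <- function(mask, what) {
    if (any(mask)) {
      stop("invalid methylome rows (", what, ") at line(s) ",
           paste(utils::head(lineNo[mask], 10), collapse = ", "),
           if (sum(mask) > 10) " ..." else "", " in ", path)
    }
  }
  fail(is.na(dt$pos) | dt$pos < 1, "pos must be >= 1")
  fail(!(dt$strand %in% c("+", "-")), "strand must be + or -")
  fail(!(dt$context %in% METH_CONTEXTS), "unknown context")
  fail(is.na(dt$C_count) | is.na(dt$eff_CT_count) | dt$C_count < 0 |
         dt$eff_CT_count < 0 | dt$C_count > dt$eff_CT_count,
       "need 0 <= C_count <= eff_CT_count")
  CytosineReport(dt$chrom, dt$pos, dt$strand, dt$context,
                 dt$C_count, dt$eff_CT_count)
}

#' Write a CytosineReport as a methratio-style table
#'
#' @param x A [CytosineReport].
#' @param path Output path; a `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
#' @importFrom data.table fwrite data.table
writeMethylome <- function(x, path) {
  stopifnot(is(x, "CytosineReport"))
  n <- totalCount(x)
  cc <- cCount(x)
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(x)),
    pos = BiocGenerics::start(x),
    strand = as.character(BiocGenerics::strand(x)),
    context = context(x),
    ratio = ifelse(n > 0, cc / n, 0),
    eff_CT_count = n,
    C_count = cc
  )
  data.table::fwrite(dt, path, sep = "\t", compress = "auto")
  invisible(path)
}

#' Read gene or transposon annotations
#'
#' Accepts GFF3 (1-based inclusive; `gene`-type records are kept, or all
#' records when none are typed `gene`) or BED (0-based half-open).
#' Coordinate-dialect conversion is handled by the importer, so a GFF3 gene
#' `1..100` and a BED line `chr1 0 100` produce the same internal interval.
#' Unstranded features are treated as plus-strand.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file (optionally gzipped).
#' @param featureClass `"gene"` or `"TE"`; defaults by format (GFF3 = gene,
#'   BED = TE).
#' @return A `GRanges` with metadata columns `id` and `featureClass`.
#' @export
#' @importFrom rtracklayer import
#' @importFrom BiocGenerics strand<-
readAnnotations <- function(path, featureClass = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  base <- sub("\\.(gz|bgz)$", "", path)
  ext <- tolower(tools::file_ext(base))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    if ("type" %in% colnames(S4Vectors::mcols(gr)) &&
        any(S4Vectors::mcols(gr)$type == "gene")) {
      gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    }
    mc <- S4Vectors::mcols(gr)
    id <- if ("ID" %in% colnames(mc)) as.character(mc$ID)
          else if ("Name" %in% colnames(mc)) as.character(mc$Name)
          else paste0("feature_", seq_along(gr))
    featureClass <- featureClass %||% "gene"
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    mc <- S4Vectors::mcols(gr)
    id <- if ("name" %in% colnames(mc) && !any(is.na(mc$name)))
      as.character(mc$name) else paste0("feature_", seq_along(gr))
    featureClass <- featureClass %||% "TE"
  } else {
    stop("unrecognized annotation format: ", path,
         " (expected .gff3/.gff or .bed)")
  }
  if (length(gr) > 0 && any(BiocGenerics::width(gr) < 1))
    stop("annotation intervals with start >= end after normalization in ", path)
  strand(gr)[as.character(strand(gr)) == "*"] <- "+"
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    id = id, featureClass = featureClass)
  if (anyDuplicated(id)) stop("duplicate feature ids in ", path)
  out
}
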