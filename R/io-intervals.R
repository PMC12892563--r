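#' Read genomic intervals from BED6 or GFF3
#'
#' Thin wrappers around [rtracklayer::import()] that return a `GRanges` with
#' two metadata columns used throughout the package: `feature_id` (unique
#' within the collection) and `feature_class` (gene, exon, TE, lncRNA,
#' siRNA_cluster, ACR, ...). Coordinates follow the Bioconductor convention
#' (1-based, closed); the 0-based half-open BED convention is converted at
#' the file boundary by rtracklayer, so a BED line `chr1 100 200` becomes
#' `[101, 200]` internally and round-trips unchanged.
#'
#' For BED6 the name column supplies `feature_id` and `feature_class` is
#' taken from the `feature_class` argument. For GFF3 the `type` column
#' supplies `feature_class` and the `ID` attribute supplies `feature_id`;
#' exon records carry a `Parent` column linking them to their gene.
#'
#' @param path file to read or write.
#' @param format `"bed"` or `"gff3"`.
#' @param feature_class class label assigned to BED records (BED has no type
#'   column).
#' @return `GRanges` with `feature_id` and `feature_class` metadata columns.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200),
#'   strand = "+", feature_id = "x1", feature_class = "gene")
#' f <- tempfile(fileext = ".bed")
#' write_intervals(gr, f, format = "bed")
#' read_intervals(f, format = "bed", feature_class = "gene")
#' @export
read_intervals <- function(path, format = c("bed", "gff3"),
                           feature_class = "region") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3"),
    error = function(e) stop("failed to parse ", path, " as ", toupper(format),
                             ": ", conditionMessage(e), call. = FALSE)
  )
  if (length(gr) == 0) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out)$feature_id <- character(0)
    S4Vectors::mcols(out)$feature_class <- character(0)
    return(out)
  }
  if (any(GenomicRanges::width(gr) < 1)) {
    bad <- which(GenomicRanges::width(gr) < 1)[1]
    stop("interval ", bad, " in ", path, " has start >= end")
  }
  if (format == "bed") {
    id <- S4Vectors::mcols(gr)$name
    if (is.null(id)) id <- paste0("feat", seq_along(gr))
    out <- GenomicRanges::granges(gr)
    S4Vectors::mcols(out)$feature_id <- as.character(id)
    S4Vectors::mcols(out)$feature_class <- rep(feature_class, length(gr))
  } else {
    mc <- S4Vectors::mcols(gr)
    id <- if (!is.null(mc$ID)) as.character(mc$ID) else paste0("feat", seq_along(gr))
    cls <- as.character(mc$type)
    out <- GenomicRanges::granges(gr)
    S4Vectors::mcols(out)$feature_id <- id
    S4Vectors::mcols(out)$feature_class <- cls
    if (!is.null(mc$Parent)) {
      par <- vapply(mc$Parent, function(p)
        if (length(p)) as.character(p[1]) else NA_character_, character(1))
      S4Vectors::mcols(out)$parent_id <- par
    }
  }
  validate_intervals(out)
  out
}

#' @rdname read_intervals
#' @param x `GRanges` with `feature_id` and `feature_class` columns.
#' @param source source tag written to GFF3 column 2.
#' @export
write_intervals <- function(x, path, format = c("bed", "gff3"),
                            source = "triadNC") {
  format <- match.arg(format)
  validate_intervals(x)
  if (format == "bed") {
    out <- GenomicRanges::granges(x)
    if (length(x)) {
      S4Vectors::mcols(out)$name <- S4Vectors::mcols(x)$feature_id
      S4Vectors::mcols(out)$score <- 0L
    }
    rtracklayer::export(out, path, format = "BED")
  } else {
    out <- GenomicRanges::granges(x)
    if (length(x)) {
      S4Vectors::mcols(out)$source <- source
      S4Vectors::mcols(out)$type <- S4Vectors::mcols(x)$feature_class
      S4Vectors::mcols(out)$ID <- S4Vectors::mcols(x)$feature_id
      pid <- S4Vectors::mcols(x)$parent_id
      if (!is.null(pid)) S4Vectors::mcols(out)$Parent <- ifelse(is.na(pid), "", pid)
    }
    rtracklayer::export(out, path, format = "GFF3")
  }
  invisible(path)
}

validate_intervals <- function(x) {
  stopifnot(methods::is(x, "GRanges"))
  if (length(x) == 0) return(invisible(x))
  mc <- S4Vectors::mcols(x)
  if (is.null(mc$feature_id) || is.null(mc$feature_class))
    stop("interval collection must carry feature_id and feature_class")
  if (anyDuplicated(mc$feature_id))
    stop("duplicated feature_id: ",
         paste(unique(mc$feature_id[duplicated(mc$feature_id)]), collapse = ", "))
  invisible(x)
}

# exons of each gene must be disjoint and contained in the gene body
validate_gene_models <- function(genes, exons) {
  validate_intervals(genes)
  if (length(exons) == 0) return(invisible(TRUE))
  pid <- S4Vectors::mcols(exons)$parent_id
  if (is.null(pid)) stop("exons must carry a parent_id column")
  ok <- pid %in% S4Vectors::mcols(genes)$feature_id
  if (!all(ok)) stop("exon with unknown parent gene: ",
                     S4Vectors::mcols(exons)$feature_id[!ok][1])
  idx <- match(pid, S4Vectors::mcols(genes)$feature_id)
  within <- GenomicRanges::start(exons) >= GenomicRanges::start(genes)[idx] &
    GenomicRanges::end(exons) <= GenomicRanges::end(genes)[idx]
  if (!all(within)) stop("exon outside its gene body: ",
                         S4Vectors::mcols(exons)$feature_id[!within][1])
  for (g in unique(pid)) {
    e <- exons[pid == g]
    if (length(e) > 1) {
      red <- GenomicRanges::reduce(GenomicRanges::granges(e))
      if (length(red) != length(e))
        stop("overlapping exons in gene ", g)
    }
  }
  invisible(TRUE)
}
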