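#' Read / write per-cytosine methylation tables
#'
#' The on-disk dialect is a Bismark-style CX report: one row per cytosine
#' with columns `chrom`, `pos` (1-based), `strand`, `context` (CG/CHG/CHH),
#' `meth` (methylated read count) and `unmeth` (unmethylated read count),
#' optionally a `sample` column. Counts rather than ratios are required
#' because the differential test and the weighted level both operate on raw
#' reads.
#'
#' @param path TSV file with a header line.
#' @return `data.table` with the columns above plus `total = meth + unmeth`.
#' @export
read_methylation <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("chrom", "pos", "strand", "context", "meth", "unmeth")
  if (!all(need %in% names(dt)))
    stop("methylation table needs columns: ", paste(need, collapse = ", "))
  validate_methylation(dt)
  dt[, total := meth + unmeth]
  dt[]
}

#' @rdname read_methylation
#' @param dt methylation `data.table`.
#' @export
write_methylation <- function(dt, path) {
  validate_methylation(dt)
  out <- data.table::as.data.table(dt)
  out <- out[, intersect(c("chrom", "pos", "strand", "context", "meth",
                           "unmeth", "sample"), names(out)), with = FALSE]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

validate_methylation <- function(dt) {
  if (any(dt$meth < 0) || any(dt$unmeth < 0))
    stop("negative methylation counts")
  if (!all(dt$context %in% c("CG", "CHG", "CHH")))
    stop("unknown context: ",
         paste(setdiff(unique(dt$context), c("CG", "CHG", "CHH")), collapse = ", "))
  if (!all(dt$strand %in% c("+", "-")))
    stop("methylation strand must be + or -")
  invisible(dt)
}
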