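#' Expression matrices with generation/replicate metadata
#'
#' `expression_matrix()` bundles a feature-by-sample abundance matrix with
#' ordered sample metadata (generation, replicate) and optional per-feature
#' metadata (subgenome of origin), the shape every downstream classifier
#' consumes. Values must be non-negative and complete; the unit tag records
#' whether entries are TPM, RPM or raw counts.
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param samples data.frame with columns `sample`, `generation` (one of
#'   maternal/paternal/hybrid/insilico) and `replicate`; row order defines
#'   sample order and must match `colnames(values)`.
#' @param unit `"TPM"`, `"RPM"` or `"count"`.
#' @param features optional data.frame with columns `feature_id` and
#'   `subgenome` (`"A"`, `"C"` or `"unknown"`).
#' @return an object of class `"expression_matrix"`.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' em <- expression_matrix(m, data.frame(
#'   sample = c("s1", "s2", "s3"),
#'   generation = c("maternal", "paternal", "hybrid"),
#'   replicate = 1L), unit = "count")
#' dim(em$values)
#' @export
expression_matrix <- function(values, samples, unit = c("TPM", "RPM", "count"),
                              features = NULL) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have feature rownames")
  if (is.null(colnames(values))) stop("values must have sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature id: ",
         rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values))) stop("duplicated sample id")
  if (anyNA(values)) stop("missing values are not allowed (no imputation)")
  if (any(values < 0)) stop("negative expression value at feature ",
                            rownames(values)[which(values < 0, arr.ind = TRUE)[1, 1]])
  samples <- as.data.frame(samples)
  need <- c("sample", "generation", "replicate")
  if (!all(need %in% names(samples)))
    stop("samples needs columns: ", paste(need, collapse = ", "))
  if (!identical(as.character(samples$sample), colnames(values)))
    stop("sample metadata order must match matrix columns")
  ok_gen <- c("maternal", "paternal", "hybrid", "insilico")
  if (!all(samples$generation %in% ok_gen))
    stop("unknown generation label: ",
         paste(setdiff(samples$generation, ok_gen), collapse = ", "))
  if (!is.null(features)) {
    features <- as.data.frame(features)
    if (!all(c("feature_id", "subgenome") %in% names(features)))
      stop("features needs columns feature_id, subgenome")
    if (!setequal(features$feature_id, rownames(values)))
      stop("features$feature_id must match matrix rownames")
    features <- features[match(rownames(values), features$feature_id), ,
                         drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(values = values, samples = samples, unit = unit,
                 features = features),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  cat("  generations:",
      paste(sprintf("%s(%d)", names(table(x$samples$generation)),
                    table(x$samples$generation)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read / write an expression table with its sample sidecar
#'
#' The on-disk form is a pair of TSVs: the value table (first column
#' `feature_id`, one column per sample, optional trailing `subgenome`
#' column) and a metadata sidecar with columns `sample`, `generation`,
#' `replicate`. `write_expression()` inverts `read_expression()` exactly.
#'
#' @param path value TSV.
#' @param meta_path sample-metadata TSV sidecar.
#' @param unit unit tag (not stored in the TSV).
#' @return [expression_matrix()] object.
#' @export
read_expression <- function(path, meta_path, unit = c("TPM", "RPM", "count")) {
  unit <- match.arg(unit)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"feature_id" %in% names(tab)) stop("first column must be feature_id")
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  features <- NULL
  if ("subgenome" %in% names(tab)) {
    features <- data.frame(feature_id = tab$feature_id,
                           subgenome = tab$subgenome,
                           stringsAsFactors = FALSE)
    tab$subgenome <- NULL
  }
  vals <- as.matrix(tab[, setdiff(names(tab), "feature_id"), drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression values in ", path)
  rownames(vals) <- tab$feature_id
  expression_matrix(vals, meta, unit = unit, features = features)
}

#' @rdname read_expression
#' @param em [expression_matrix()] object.
#' @export
write_expression <- function(em, path, meta_path) {
  stopifnot(inherits(em, "expression_matrix"))
  tab <- data.frame(feature_id = rownames(em$values),
                    em$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(em$features)) tab$subgenome <- em$features$subgenome
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(em$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Subset an expression matrix by sample or feature
#'
#' @param em [expression_matrix()] object.
#' @param samples sample ids to keep (default all).
#' @param features feature ids to keep (default all).
#' @return a new `expression_matrix`.
#' @export
subset_expression <- function(em, samples = NULL, features = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  v <- em$values
  smeta <- em$samples
  fmeta <- em$features
  if (!is.null(samples)) {
    keep <- match(samples, colnames(v))
    if (anyNA(keep)) stop("unknown sample: ", samples[is.na(keep)][1])
    v <- v[, keep, drop = FALSE]
    smeta <- smeta[keep, , drop = FALSE]
    rownames(smeta) <- NULL
  }
  if (!is.null(features)) {
    keep <- match(features, rownames(v))
    if (anyNA(keep)) stop("unknown feature: ", features[is.na(keep)][1])
    v <- v[keep, , drop = FALSE]
    if (!is.null(fmeta)) fmeta <- fmeta[keep, , drop = FALSE]
  }
  expression_matrix(v, smeta, unit = em$unit, features = fmeta)
}

#' Samples belonging to one generation
#'
#' @param em [expression_matrix()] object.
#' @param generation generation label.
#' @return character vector of sample ids.
#' @export
generation_samples <- function(em, generation) {
  stopifnot(inherits(em, "expression_matrix"))
  as.character(em$samples$sample[em$samples$generation == generation])
}

#' Counts-per-million normalization
#'
#' Divides each column by its sum and scales to one million. Already
#' depth-normalized units (TPM/RPM) are returned unchanged.
#'
#' @param em [expression_matrix()] object.
#' @return an `expression_matrix` with unit `"RPM"` (or the input unchanged).
#' @export
normalize_cpm <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$unit != "count") return(em)
  libs <- colSums(em$values)
  if (any(libs == 0)) stop("sample with zero total counts: ",
                           colnames(em$values)[libs == 0][1])
  v <- sweep(em$values, 2, libs, "/") * 1e6
  expression_matrix(v, em$samples, unit = "RPM", features = em$features)
}
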