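#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment (via [stats::p.adjust()]) with input
#' validation. The adjusted values are monotone non-decreasing in the rank
#' of the raw p-values and capped at 1. Note that the step-up map is not
#' idempotent: re-adjusting an adjusted vector multiplies by n/rank again.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] and be non-missing")
  stats::p.adjust(p, method = "BH")
}

#' Correlate one feature's expression with a subgenome dosage vector
#'
#' Pearson product-moment correlation between expression values and the
#' relative dosage, with the two-sided t-test on n - 2 degrees of freedom.
#' Expression with zero variance has no defined correlation and is
#' reported unclassifiable (`r = NA`).
#'
#' @param values numeric expression values, parallel to `dosage`.
#' @param dosage relative dosage vector (at least 3 points).
#' @return list `r`, `r_squared`, `p`, `n`, and two-decimal truncations
#'   `r_trunc2`, `r_squared_trunc2` (truncation, not rounding, is what
#'   reproduces the printed two-decimal values of the reference worked
#'   example).
#' @examples
#' correlate_dosage(c(1.36, 1.76, 5.78), c(1/2, 2/3, 1))
#' @export
correlate_dosage <- function(values, dosage) {
  if (length(values) != length(dosage))
    stop("values and dosage lengths differ")
  if (length(values) < 3) stop("need at least 3 points")
  if (stats::sd(values) == 0 || stats::sd(dosage) == 0)
    return(list(r = NA_real_, r_squared = NA_real_, p = NA_real_,
                n = length(values), r_trunc2 = NA_real_,
                r_squared_trunc2 = NA_real_))
  ct <- stats::cor.test(values, dosage, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p = ct$p.value, n = length(values),
       r_trunc2 = trunc(r * 100) / 100,
       r_squared_trunc2 = trunc(r^2 * 100) / 100)
}

#' Classify features as dosage-dependent or dosage-independent
#'
#' For every feature of a subgenome, correlates expression across the
#' ploidy series (maternal AACC, hybrid AAC, paternal AA) with the
#' subgenome's relative dosage vector and labels the feature:
#'
#' * `dd-positive` / `dd-negative`: R^2 strictly above `r2_threshold`
#'   (0.64) and BH FDR strictly below `fdr_threshold` (0.05); the sign of
#'   r picks positive vs negative.
#' * `di`: everything else with a defined correlation.
#' * `unclassifiable`: zero expression variance; excluded from the BH
#'   family.
#'
#' The BH family is all classifiable features of the same subgenome.
#' `mode = "mean"` correlates the three per-generation replicate means
#' (three points, as in the reference worked example); `mode = "replicate"`
#' repeats the dosage per replicate (3 x replicates points), which gives
#' the t-test real power and is recommended for calling.
#'
#' @param em [expression_matrix()] with per-feature `subgenome` tags and
#'   maternal/hybrid/paternal samples.
#' @param mode `"mean"` or `"replicate"`.
#' @param designs named list of [dosage_design()] per subgenome.
#' @return data.frame `feature_id`, `subgenome`, `r`, `r_squared`, `p`,
#'   `fdr`, `label`.
#' @export
classify_dosage <- function(em, mode = c("mean", "replicate"),
                            designs = list(A = dosage_design("A"),
                                           C = dosage_design("C"))) {
  mode <- match.arg(mode)
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(em$features) || is.null(em$features$subgenome))
    stop("expression must carry per-feature subgenome tags")
  out <- list()
  for (sub in names(designs)) {
    des <- designs[[sub]]
    feats <- em$features$feature_id[em$features$subgenome == sub]
    if (length(feats) == 0) next
    cols <- lapply(des$generations, function(g) generation_samples(em, g))
    if (any(vapply(cols, length, integer(1)) == 0))
      stop("expression lacks samples for a generation in the design")
    vals <- em$values[feats, , drop = FALSE]
    if (mode == "mean") {
      x <- des$dosage
      y <- vapply(cols, function(cc) rowMeans(vals[, cc, drop = FALSE]),
                  numeric(length(feats)))
      if (length(feats) == 1) y <- matrix(y, nrow = 1)
    } else {
      x <- unlist(lapply(seq_along(cols),
                         function(i) rep(des$dosage[i], length(cols[[i]]))))
      y <- vals[, unlist(cols), drop = FALSE]
    }
    res <- lapply(seq_along(feats), function(i) correlate_dosage(y[i, ], x))
    df <- data.frame(
      feature_id = feats, subgenome = sub,
      r = vapply(res, `[[`, numeric(1), "r"),
      r_squared = vapply(res, `[[`, numeric(1), "r_squared"),
      p = vapply(res, `[[`, numeric(1), "p"),
      stringsAsFactors = FALSE)
    df$fdr <- NA_real_
    ok <- !is.na(df$p)
    df$fdr[ok] <- bh_fdr(df$p[ok])  # BH family: classifiable features, per subgenome
    df$label <- "di"
    df$label[!ok] <- "unclassifiable"
    dd <- ok & df$r_squared > des$r2_threshold & df$fdr < des$fdr_threshold
    df$label[dd & df$r > 0] <- "dd-positive"
    df$label[dd & df$r < 0] <- "dd-negative"
    out[[sub]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tabulate dosage calls per subgenome
#'
#' @param calls data.frame from [classify_dosage()].
#' @return data.frame of counts and fractions per subgenome and label.
#' @export
summarize_dosage <- function(calls) {
  tab <- as.data.frame(table(subgenome = calls$subgenome,
                             label = calls$label), stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  totals <- tapply(tab$n, tab$subgenome, sum)
  tab$fraction <- tab$n / as.numeric(totals[tab$subgenome])
  tab[order(tab$subgenome, -tab$n), ]
}
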