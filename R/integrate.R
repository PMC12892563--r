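#' Cis ncRNA-gene pairs within a distance gate
#'
#' Emits every (ncRNA, gene) pair whose closest-edge gap is at most
#' `max_distance` (inclusive: "within X kb"); overlapping pairs have
#' distance 0. All qualifying genes per ncRNA are emitted; strand is
#' ignored.
#'
#' @param ncrnas,genes `GRanges` with `feature_id`.
#' @param max_distance inclusive gap threshold in bases (5 kb for lncRNAs,
#'   2 kb for phasiRNA loci).
#' @return data.frame `ncrna_id`, `gene_id`, `distance`.
#' @export
cis_pairs <- function(ncrnas, genes, max_distance = 5000L) {
  empty <- data.frame(ncrna_id = character(0), gene_id = character(0),
                      distance = integer(0), stringsAsFactors = FALSE)
  if (length(ncrnas) == 0 || length(genes) == 0) return(empty)
  hits <- GenomicRanges::findOverlaps(ncrnas, genes, maxgap = max_distance,
                                      ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(ncrnas[q], genes[s], ignore.strand = TRUE)
  keep <- !is.na(d) & d <= max_distance
  data.frame(ncrna_id = S4Vectors::mcols(ncrnas)$feature_id[q][keep],
             gene_id = S4Vectors::mcols(genes)$feature_id[s][keep],
             distance = as.integer(d[keep]), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Expression correlation of feature pairs
#'
#' Pearson r per pair on log2(value + 1) across all samples
#' (replicate-level), with a summary splitting pairs at r = 0.
#'
#' @param pairs data.frame with two id columns (first = ncRNA, second =
#'   gene/partner).
#' @param em [expression_matrix()] covering all paired features.
#' @return list with `pairs` (input plus `r`, `r_squared`) and `summary`
#'   (`n_pairs`, `n_positive`, `n_negative`, `fraction_positive`,
#'   `fraction_negative`, `mean_r`).
#' @export
correlate_pairs <- function(pairs, em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (nrow(pairs) == 0)
    return(list(pairs = cbind(pairs, r = numeric(0), r_squared = numeric(0)),
                summary = data.frame(n_pairs = 0L, n_positive = 0L,
                                     n_negative = 0L,
                                     fraction_positive = NA_real_,
                                     fraction_negative = NA_real_,
                                     mean_r = NA_real_)))
  v <- log2(em$values + 1)
  a <- match(pairs[[1]], rownames(v)); b <- match(pairs[[2]], rownames(v))
  if (anyNA(a) || anyNA(b))
    stop("pair member missing from expression: ",
         c(pairs[[1]][is.na(a)], pairs[[2]][is.na(b)])[1])
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    xa <- v[a[i], ]; xb <- v[b[i], ]
    if (stats::sd(xa) == 0 || stats::sd(xb) == 0) return(NA_real_)
    stats::cor(xa, xb)
  }, numeric(1))
  out <- cbind(pairs, r = r, r_squared = r^2)
  ok <- !is.na(r)
  list(pairs = out,
       summary = data.frame(
         n_pairs = nrow(pairs),
         n_positive = sum(r[ok] > 0), n_negative = sum(r[ok] < 0),
         fraction_positive = if (any(ok)) sum(r[ok] > 0) / sum(ok) else NA_real_,
         fraction_negative = if (any(ok)) sum(r[ok] < 0) / sum(ok) else NA_real_,
         mean_r = if (any(ok)) mean(r[ok]) else NA_real_))
}

#' Trans-acting lncRNA-gene co-expression pairs
#'
#' A pair is trans when the partners are on different chromosomes or
#' strictly more than `min_distance` apart (default 5 kb), and is kept iff
#' its squared Pearson correlation strictly exceeds `r2_min` (default
#' 0.81, i.e. |r| > 0.9).
#'
#' @param lncrnas,genes `GRanges` with `feature_id`.
#' @param em [expression_matrix()] covering both sets.
#' @param r2_min strict lower bound on r^2.
#' @param min_distance strict lower bound on the gap for same-chromosome
#'   pairs.
#' @return data.frame `ncrna_id`, `gene_id`, `distance` (NA for different
#'   chromosomes), `r`, `r_squared`.
#' @export
trans_coexpression <- function(lncrnas, genes, em, r2_min = 0.81,
                               min_distance = 5000L) {
  stopifnot(inherits(em, "expression_matrix"))
  empty <- data.frame(ncrna_id = character(0), gene_id = character(0),
                      distance = integer(0), r = numeric(0),
                      r_squared = numeric(0), stringsAsFactors = FALSE)
  if (length(lncrnas) == 0 || length(genes) == 0) return(empty)
  lid <- S4Vectors::mcols(lncrnas)$feature_id
  gid <- S4Vectors::mcols(genes)$feature_id
  v <- log2(em$values + 1)
  if (!all(lid %in% rownames(v)) || !all(gid %in% rownames(v)))
    stop("expression must cover all lncRNAs and genes")
  cmat <- suppressWarnings(stats::cor(t(v[lid, , drop = FALSE]),
                                      t(v[gid, , drop = FALSE])))
  out <- list()
  for (i in seq_along(lncrnas)) for (j in seq_along(genes)) {
    same_chr <- as.character(GenomeInfoDb::seqnames(lncrnas)[i]) ==
      as.character(GenomeInfoDb::seqnames(genes)[j])
    d <- if (same_chr)
      GenomicRanges::distance(lncrnas[i], genes[j], ignore.strand = TRUE)
    else NA_integer_
    is_trans <- !same_chr || (!is.na(d) && d > min_distance)
    if (!is_trans) next
    r <- cmat[i, j]
    if (!is.na(r) && r^2 > r2_min)
      out[[length(out) + 1L]] <- data.frame(
        ncrna_id = lid[i], gene_id = gid[j],
        distance = if (same_chr) as.integer(d) else NA_integer_,
        r = r, r_squared = r^2, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Signal-density metaprofile around target features
#'
#' Distributes weighted signal intervals (siRNA cluster RPM, ACR coverage,
#' ...) over the flank/body layout of [metaprofile()]: each signal interval
#' assigns to every bin the share of its weight proportional to the
#' fraction of the interval overlapping that bin, so total assigned weight
#' equals total input weight within the profiled windows. Per-bin output is
#' summed weight and the mean over target regions.
#'
#' @param targets `GRanges` of profiled features.
#' @param signal `GRanges` with a numeric `weight` metadata column.
#' @param flank,flank_bin,body_bins layout as in [metaprofile()].
#' @return data.frame `bin`, `zone`, `weight` (summed), `mean_weight`
#'   (per target).
#' @export
signal_profile <- function(targets, signal, flank = 2000L, flank_bin = 100L,
                           body_bins = 20L) {
  nf <- as.integer(flank / flank_bin)
  ntot <- 2L * nf + body_bins
  zone <- rep(c("upstream", "body", "downstream"), c(nf, body_bins, nf))
  out <- data.frame(bin = seq_len(ntot), zone = zone, weight = 0,
                    mean_weight = 0)
  if (length(targets) == 0 || length(signal) == 0) return(out)
  w <- S4Vectors::mcols(signal)$weight
  if (is.null(w)) stop("signal needs a weight metadata column")
  bins <- .layout_bins(targets, flank, flank_bin, body_bins)
  hits <- GenomicRanges::findOverlaps(signal, bins$gr, ignore.strand = TRUE)
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ow <- GenomicRanges::width(GenomicRanges::pintersect(
      GenomicRanges::granges(signal)[q], bins$gr[s]))
    contrib <- w[q] * ow / GenomicRanges::width(signal)[q]
    agg <- tapply(contrib, bins$bin[s], sum)
    out$weight[as.integer(names(agg))] <- as.numeric(agg)
  }
  out$mean_weight <- out$weight / length(targets)
  out
}

# explicit per-target bin ranges for the flank/body layout
.layout_bins <- function(targets, flank, flank_bin, body_bins) {
  nf <- as.integer(flank / flank_bin)
  grs <- list(); binidx <- integer(0)
  for (i in seq_along(targets)) {
    rs <- GenomicRanges::start(targets)[i]
    re <- GenomicRanges::end(targets)[i]
    chr <- as.character(GenomeInfoDb::seqnames(targets)[i])
    minus <- as.character(GenomicRanges::strand(targets))[i] == "-"
    # genomic-left flank bins, left to right
    ls <- rs - flank + (seq_len(nf) - 1L) * flank_bin
    left <- GenomicRanges::GRanges(chr, IRanges::IRanges(ls, ls + flank_bin - 1L))
    # body bins by proportional split
    edges <- rs + round((re - rs + 1L) * (0:body_bins) / body_bins)
    bs <- edges[-(body_bins + 1L)]
    be <- edges[-1L] - 1L
    ok <- be >= bs
    body <- GenomicRanges::GRanges(chr, IRanges::IRanges(bs[ok], be[ok]))
    body_ids <- which(ok)
    rs2 <- re + 1L + (seq_len(nf) - 1L) * flank_bin
    right <- GenomicRanges::GRanges(chr, IRanges::IRanges(rs2, rs2 + flank_bin - 1L))
    if (!minus) {
      idx <- c(seq_len(nf), nf + body_ids, nf + body_bins + seq_len(nf))
    } else {
      # minus strand: genomic right flank is upstream (mirrored), body bins
      # mirrored, genomic left flank is downstream (mirrored)
      ntot <- 2L * nf + body_bins
      idx <- c(ntot + 1L - seq_len(nf),          # left flank -> downstream
               nf + body_bins + 1L - body_ids,   # body, mirrored
               nf + 1L - seq_len(nf))            # right flank -> upstream
    }
    grs[[i]] <- c(left, body, right)
    binidx <- c(binidx, idx)
  }
  list(gr = suppressWarnings(do.call(c, grs)), bin = binidx)
}

#' Summarize miRNA-target correlation pairs
#'
#' Consumes an externally predicted miRNA-target pair table and applies the
#' [correlate_pairs()] contract: counts of positively and negatively
#' correlated pairs plus the overall mean r.
#'
#' @param target_pairs data.frame with columns `mirna_id`, `gene_id`.
#' @param em [expression_matrix()] covering miRNAs and targets.
#' @return the [correlate_pairs()] result.
#' @export
mirna_target_summary <- function(target_pairs, em) {
  correlate_pairs(target_pairs, em)
}
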