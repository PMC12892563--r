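#' Weighted methylation level of regions
#'
#' The weighted level of a region is total methylated reads divided by
#' total reads over its valid cytosines (per-site depth at least
#' `min_site_coverage`, default 5) — the count-weighted ratio, not the mean
#' of per-site ratios. Regions without valid sites get `NA`.
#'
#' @param meth methylation `data.table` (see [read_methylation()]).
#' @param regions `GRanges` with `feature_id`.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param config [dmr_config()] object (supplies `min_site_coverage`).
#' @return data.frame `region_id`, `context`, `level`, `n_sites`.
#' @export
weighted_level <- function(meth, regions, context,
                           config = dmr_config()) {
  ctx <- context
  dt <- data.table::as.data.table(meth)
  dt <- dt[dt$context == ctx]
  ids <- S4Vectors::mcols(regions)$feature_id
  out <- data.frame(region_id = ids, context = context,
                    level = NA_real_, n_sites = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(dt) == 0 || length(regions) == 0) return(out)
  dt <- dt[meth + unmeth >= config$min_site_coverage]
  if (nrow(dt) == 0) return(out)
  sites <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$pos, dt$pos))
  hits <- GenomicRanges::findOverlaps(sites, regions, ignore.strand = TRUE)
  if (length(hits) == 0) return(out)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  agg <- data.table::data.table(region = s, m = dt$meth[q],
                                t = dt$meth[q] + dt$unmeth[q])
  agg <- agg[, .(level = sum(m) / sum(t), n = .N), by = "region"]
  out$level[agg$region] <- agg$level
  out$n_sites[agg$region] <- agg$n
  out
}

#' Methylation metaprofile over flanks and scaled bodies
#'
#' Pools cytosine counts into a fixed layout per region — upstream flank
#' (default 2 kb in 100-bp bins), body proportionally rescaled to
#' `body_bins` bins, downstream flank — with strand-aware orientation
#' (for minus-strand regions "upstream" is genomic right and bins are
#' mirrored; unstranded regions use genomic left as upstream). Per-bin
#' levels are count-weighted across regions, so pooling all bins
#' reproduces the global weighted level of the profiled windows. Regions
#' shorter than `body_bins` bases contribute to flank bins only.
#'
#' @param meth methylation `data.table`.
#' @param regions stranded or unstranded `GRanges` with `feature_id`.
#' @param context methylation context.
#' @param flank flank size in bases.
#' @param flank_bin flank bin width in bases.
#' @param body_bins number of body bins.
#' @param config [dmr_config()] (valid-site coverage rule).
#' @return data.frame `bin` (1..n, upstream to downstream), `zone`
#'   (upstream/body/downstream), `level`, `meth_reads`, `total_reads`,
#'   `n_sites`; attribute `skipped_bodies` counts regions too short for
#'   body binning.
#' @export
metaprofile <- function(meth, regions, context, flank = 2000L,
                        flank_bin = 100L, body_bins = 20L,
                        config = dmr_config()) {
  nf <- as.integer(flank / flank_bin)
  ntot <- 2L * nf + body_bins
  zone <- rep(c("upstream", "body", "downstream"), c(nf, body_bins, nf))
  out <- data.frame(bin = seq_len(ntot), zone = zone, level = NA_real_,
                    meth_reads = 0, total_reads = 0, n_sites = 0L)
  if (length(regions) == 0) {
    out <- out[0, ]
    attr(out, "skipped_bodies") <- 0L
    return(out)
  }
  ctx <- context
  dt <- data.table::as.data.table(meth)
  dt <- dt[dt$context == ctx]
  dt <- dt[meth + unmeth >= config$min_site_coverage]
  skipped <- 0L
  if (nrow(dt)) {
    sites <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$pos, dt$pos))
    win <- suppressWarnings(GenomicRanges::trim(GenomicRanges::resize(
      GenomicRanges::granges(regions),
      GenomicRanges::width(regions) + 2L * flank, fix = "center")))
    hits <- GenomicRanges::findOverlaps(sites, win, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    if (length(hits)) {
      rs <- GenomicRanges::start(regions)[s]
      re <- GenomicRanges::end(regions)[s]
      rw <- re - rs + 1L
      str <- as.character(GenomicRanges::strand(regions))[s]
      pos <- dt$pos[q]
      binidx <- integer(length(q))
      for (k in seq_along(q)) {
        b <- .profile_bin(pos[k], rs[k], re[k], rw[k], str[k],
                          flank, flank_bin, nf, body_bins)
        binidx[k] <- b
      }
      short <- GenomicRanges::width(regions) < body_bins
      skipped <- sum(short)
      keep <- binidx > 0L
      if (any(keep)) {
        agg <- data.table::data.table(bin = binidx[keep], m = dt$meth[q[keep]],
                                      t = dt$meth[q[keep]] + dt$unmeth[q[keep]])
        agg <- agg[, .(m = sum(m), t = sum(t), n = .N), by = "bin"]
        out$meth_reads[agg$bin] <- agg$m
        out$total_reads[agg$bin] <- agg$t
        out$n_sites[agg$bin] <- agg$n
        out$level <- ifelse(out$total_reads > 0,
                            out$meth_reads / out$total_reads, NA_real_)
      }
    }
  }
  attr(out, "skipped_bodies") <- skipped
  out
}

# map one site to its profile bin (0 = outside / short-body exclusion)
.profile_bin <- function(pos, rs, re, rw, str, flank, flank_bin, nf,
                         body_bins) {
  minus <- identical(str, "-")
  if (pos < rs) {           # genomic left flank
    d <- rs - pos           # 1..flank
    if (d > flank) return(0L)
    b <- nf - ((d - 1L) %/% flank_bin)          # closest to body = bin nf
    return(if (minus) .mirror_bin(b, nf, body_bins) else b)
  }
  if (pos > re) {           # genomic right flank
    d <- pos - re
    if (d > flank) return(0L)
    b <- nf + body_bins + 1L + ((d - 1L) %/% flank_bin)
    return(if (minus) .mirror_bin(b, nf, body_bins) else b)
  }
  if (rw < body_bins) return(0L)  # body too short to rescale
  off <- pos - rs
  bb <- as.integer(off / rw * body_bins) + 1L
  bb <- min(bb, body_bins)
  if (minus) bb <- body_bins + 1L - bb
  nf + bb
}

.mirror_bin <- function(b, nf, body_bins) {
  ntot <- 2L * nf + body_bins
  ntot + 1L - b
}

#' Call differentially methylated regions on 200-bp bins
#'
#' Tiles the genome into `bin_size` bins per context; a bin is tested when
#' both groups have at least `min_cytosines_per_bin` valid cytosines
#' (per-site depth >= `min_site_coverage`) in it. Pooled
#' methylated/unmethylated read counts of the two groups form a 2x2 table
#' tested by a two-sided Fisher exact test; BH adjustment is applied per
#' context across tested bins. A bin is a DMR iff `padj <
#' padj_threshold` (0.01) and the absolute level difference strictly
#' exceeds the context gate (CG 0.3, CHG 0.2, CHH 0.1). Direction is
#' `hyper` when group 2 gained methylation relative to group 1.
#'
#' @param group1,group2 methylation `data.table`s over the same genome.
#' @param config [dmr_config()] object.
#' @param contexts contexts to test.
#' @return data.frame `chrom`, `bin_start` (1-based), `bin_end`, `context`,
#'   `n_sites1`, `n_sites2`, `level1`, `level2`, `delta`, `pvalue`, `padj`,
#'   `dmr`, `direction`.
#' @export
call_dmrs <- function(group1, group2, config = dmr_config(),
                      contexts = c("CG", "CHG", "CHH")) {
  res <- list()
  for (ctx in contexts) {
    b1 <- .bin_counts(group1, ctx, config)
    b2 <- .bin_counts(group2, ctx, config)
    if (nrow(b1) == 0 || nrow(b2) == 0) next
    mg <- merge(b1, b2, by = c("chrom", "bin"), suffixes = c("1", "2"))
    mg <- mg[mg$n_sites1 >= config$min_cytosines_per_bin &
             mg$n_sites2 >= config$min_cytosines_per_bin, , drop = FALSE]
    if (nrow(mg) == 0) next
    pv <- vapply(seq_len(nrow(mg)), function(i)
      stats::fisher.test(matrix(c(mg$M1[i], mg$U1[i], mg$M2[i], mg$U2[i]),
                                2, 2))$p.value, numeric(1))
    pv <- pmin(pv, 1)  # fisher.test can exceed 1 by floating error
    lev1 <- mg$M1 / (mg$M1 + mg$U1)
    lev2 <- mg$M2 / (mg$M2 + mg$U2)
    delta <- lev2 - lev1
    padj <- bh_fdr(pv)
    res[[ctx]] <- data.frame(
      chrom = mg$chrom,
      bin_start = mg$bin * config$bin_size + 1L,
      bin_end = (mg$bin + 1L) * config$bin_size,
      context = ctx,
      n_sites1 = mg$n_sites1, n_sites2 = mg$n_sites2,
      level1 = lev1, level2 = lev2, delta = delta,
      pvalue = pv, padj = padj,
      dmr = padj < config$padj_threshold &
        abs(delta) > config$delta[[ctx]],
      direction = ifelse(delta > 0, "hyper", ifelse(delta < 0, "hypo", "none")),
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0)
    return(data.frame(chrom = character(0), bin_start = integer(0),
                      bin_end = integer(0), context = character(0),
                      n_sites1 = integer(0), n_sites2 = integer(0),
                      level1 = numeric(0), level2 = numeric(0),
                      delta = numeric(0), pvalue = numeric(0),
                      padj = numeric(0), dmr = logical(0),
                      direction = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# pooled valid-site counts per (chrom, bin) for one context
.bin_counts <- function(meth, ctx, config) {
  dt <- data.table::as.data.table(meth)[context == ctx]
  dt <- dt[meth + unmeth >= config$min_site_coverage]
  if (nrow(dt) == 0)
    return(data.frame(chrom = character(0), bin = integer(0),
                      M = integer(0), U = integer(0), n_sites = integer(0)))
  dt[, bin := (pos - 1L) %/% config$bin_size]
  agg <- dt[, .(M = sum(meth), U = sum(unmeth), n_sites = .N),
            by = c("chrom", "bin")]
  as.data.frame(agg)
}

#' Compare methylation levels across element classes
#'
#' Computes per-region weighted levels for each element class and context,
#' and tests for class differences with the Kruskal-Wallis rank test
#' (skipped when fewer than two classes have data).
#'
#' @param class_regions named list of `GRanges`, one per element class.
#' @param meth methylation `data.table`.
#' @param contexts contexts to profile.
#' @param config [dmr_config()] object.
#' @return list with `levels` (data.frame `class`, `region_id`, `context`,
#'   `level`, `n_sites`) and `tests` (data.frame `context`, `statistic`,
#'   `p`, `n_classes`).
#' @export
compare_element_methylation <- function(class_regions, meth,
                                        contexts = c("CG", "CHG", "CHH"),
                                        config = dmr_config()) {
  levels_df <- list(); tests <- list()
  for (ctx in contexts) {
    per_class <- lapply(names(class_regions), function(cl) {
      wl <- weighted_level(meth, class_regions[[cl]], ctx, config)
      data.frame(class = cl, wl, stringsAsFactors = FALSE)
    })
    lev <- do.call(rbind, per_class)
    levels_df[[ctx]] <- lev
    ok <- lev[!is.na(lev$level), , drop = FALSE]
    if (length(unique(ok$class)) >= 2) {
      kw <- stats::kruskal.test(ok$level, factor(ok$class))
      tests[[ctx]] <- data.frame(context = ctx,
                                 statistic = unname(kw$statistic),
                                 p = kw$p.value,
                                 n_classes = length(unique(ok$class)),
                                 stringsAsFactors = FALSE)
    }
  }
  lv <- do.call(rbind, levels_df)
  rownames(lv) <- NULL
  ts <- if (length(tests)) do.call(rbind, tests) else
    data.frame(context = character(0), statistic = numeric(0),
               p = numeric(0), n_classes = integer(0))
  rownames(ts) <- NULL
  list(levels = lv, tests = ts)
}
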