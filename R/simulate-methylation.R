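#' Simulate two-group per-cytosine methylation with planted DMRs
#'
#' Tiles a region into 200-bp bins, plants cytosines at fixed spacing, draws
#' per-site coverage (negative-binomial around `meth_coverage`) and
#' methylated counts beta-binomially around the per-context baseline. In
#' planted DMR bins the group-2 mean is shifted by `dmr_delta[context]`
#' (capped into [0.02, 0.98]). Coverage is drawn so that sites with five or
#' more reads dominate, matching the valid-site rule of the caller.
#'
#' @param config [sim_config()] object.
#' @param n_bins number of 200-bp bins per context.
#' @param dmr_fraction fraction of bins planted as DMRs.
#' @param sites_per_bin cytosines planted per bin.
#' @param contexts contexts to simulate.
#' @return list with `group1` and `group2` methylation `data.table`s (CX
#'   shape, see [read_methylation()]) and `truth` (data.frame `chrom`,
#'   `bin_start` (1-based), `context`, `planted_dmr`).
#' @export
simulate_methylation <- function(config = sim_config(), n_bins = 60L,
                                 dmr_fraction = 0.25, sites_per_bin = 10L,
                                 contexts = c("CG", "CHG", "CHH")) {
  set.seed(.stream_seed(config, "methylation"))
  stopifnot(sites_per_bin >= 1, n_bins >= 1)
  bin_size <- 200L
  g1 <- list(); g2 <- list(); truth <- list()
  for (ctx in contexts) {
    planted <- rep(FALSE, n_bins)
    planted[sample.int(n_bins, round(dmr_fraction * n_bins))] <- TRUE
    p1 <- config$meth_baseline[[ctx]]
    p2 <- ifelse(planted, pmin(0.98, pmax(0.02,
                                          p1 + config$dmr_delta[[ctx]])), p1)
    # sites at even spacing inside each bin, 1-based positions
    off <- round(seq(10, bin_size - 10, length.out = sites_per_bin))
    pos <- as.vector(outer(off, (seq_len(n_bins) - 1L) * bin_size, "+"))
    nb <- length(pos)
    p1v <- rep(p1, nb)
    p2v <- rep(p2, each = sites_per_bin)
    draw <- function(pv) {
      cov <- stats::rnbinom(nb, mu = config$meth_coverage, size = 20) + 2L
      site_p <- stats::rbeta(nb, pv * config$meth_concentration,
                             (1 - pv) * config$meth_concentration)
      meth <- stats::rbinom(nb, cov, site_p)
      data.table::data.table(
        chrom = "chr1", pos = as.integer(pos),
        strand = rep(c("+", "-"), length.out = nb),
        context = ctx, meth = meth, unmeth = cov - meth,
        total = cov)
    }
    g1[[ctx]] <- draw(p1v)
    g2[[ctx]] <- draw(p2v)
    truth[[ctx]] <- data.frame(
      chrom = "chr1",
      bin_start = (seq_len(n_bins) - 1L) * bin_size + 1L,
      context = ctx, planted_dmr = planted,
      stringsAsFactors = FALSE)
  }
  list(group1 = data.table::rbindlist(g1),
       group2 = data.table::rbindlist(g2),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Simulate replicate ACR peak sets with decoys
#'
#' True ACRs (from [generate_annotation()] or supplied directly) appear in
#' every replicate with independent uniform boundary jitter of at most
#' `acr_jitter` bases per edge; decoy peaks appear in exactly one replicate
#' each, placed on a non-overlapping grid downstream of the true peaks, so
#' the replicate-merge rule must eliminate them.
#'
#' @param acrs `GRanges` of true ACRs.
#' @param config [sim_config()] object.
#' @param n_replicates number of replicate peak sets.
#' @param n_decoys decoy peaks in total (spread over replicates).
#' @return list with `replicates` (list of `GRanges`) and `truth`
#'   (data.frame `feature_id`, `decoy`, `replicate`).
#' @export
simulate_acr_replicates <- function(acrs, config = sim_config(),
                                    n_replicates = 3L, n_decoys = 12L) {
  set.seed(.stream_seed(config, "acr"))
  stopifnot(n_replicates >= 2)
  j <- config$acr_jitter
  right_edge <- if (length(acrs)) max(GenomicRanges::end(acrs)) else 0L
  decoy_start <- right_edge + 5000L + (seq_len(n_decoys) - 1L) * 2000L
  decoy_rep <- rep(seq_len(n_replicates), length.out = n_decoys)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    if (length(acrs)) {
      s <- GenomicRanges::start(acrs) +
        if (j > 0) sample(seq(-j, j), length(acrs), replace = TRUE) else 0L
      e <- GenomicRanges::end(acrs) +
        if (j > 0) sample(seq(-j, j), length(acrs), replace = TRUE) else 0L
      e <- pmax(e, s + 50L)  # keep peaks well-formed under extreme jitter
      tr <- .gr("chr1", s, e, "*",
                paste0(S4Vectors::mcols(acrs)$feature_id, "_rep", r), "ACR")
    } else tr <- .gr(character(0), integer(0), integer(0), character(0),
                     character(0), character(0))
    dec_idx <- which(decoy_rep == r)
    if (length(dec_idx)) {
      dc <- .gr("chr1", decoy_start[dec_idx], decoy_start[dec_idx] + 399L,
                "*", sprintf("decoy%03d_rep%d", dec_idx, r), "ACR")
      tr <- c(tr, dc)
    }
    reps[[r]] <- tr
  }
  truth <- data.frame(
    feature_id = c(if (length(acrs)) S4Vectors::mcols(acrs)$feature_id,
                   sprintf("decoy%03d", seq_len(n_decoys))),
    decoy = c(rep(FALSE, length(acrs)), rep(TRUE, n_decoys)),
    replicate = c(rep(NA_integer_, length(acrs)), decoy_rep),
    stringsAsFactors = FALSE)
  list(replicates = reps, truth = truth)
}
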