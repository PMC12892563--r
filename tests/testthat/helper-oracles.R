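# brute-force oracles and small fixture builders used across test files

mk_gr <- function(start, end, strand = "*", id = NULL, class = "region",
                  chrom = "chr1", ...) {
  n <- length(start)
  if (is.null(id)) id <- sprintf("f%03d", seq_len(n))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr)$feature_id <- id
  S4Vectors::mcols(gr)$feature_class <- rep(class, length.out = n)
  extra <- list(...)
  for (nm in names(extra)) S4Vectors::mcols(gr)[[nm]] <- extra[[nm]]
  gr
}

# gap in bases between two 1-based closed intervals; 0 when overlapping
gap_bases <- function(s1, e1, s2, e2) {
  if (min(e1, e2) >= max(s1, s2)) return(0L)  # overlap
  max(s1, s2) - min(e1, e2) - 1L
}

overlap_bases <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2) + 1L)
}

# quadratic reimplementation of the genic/proximal/distal rule
bf_location <- function(features, genes, proximal = 2000L) {
  fs <- GenomicRanges::start(features); fe <- GenomicRanges::end(features)
  gs <- GenomicRanges::start(genes); ge <- GenomicRanges::end(genes)
  fchr <- as.character(GenomeInfoDb::seqnames(features))
  gchr <- as.character(GenomeInfoDb::seqnames(genes))
  vapply(seq_along(features), function(i) {
    same <- which(gchr == fchr[i])
    if (length(same) == 0) return("distal")
    ovl <- any(vapply(same, function(j)
      overlap_bases(fs[i], fe[i], gs[j], ge[j]) >= 1, logical(1)))
    if (ovl) return("genic")
    gaps <- vapply(same, function(j) gap_bases(fs[i], fe[i], gs[j], ge[j]),
                   integer(1))
    if (min(gaps) < proximal) "proximal" else "distal"
  }, character(1))
}

# quadratic reimplementation of the lncRNA positional classifier
bf_lnc_class <- function(lncrnas, genes, exons) {
  ls <- GenomicRanges::start(lncrnas); le <- GenomicRanges::end(lncrnas)
  lstr <- as.character(GenomicRanges::strand(lncrnas))
  gs <- GenomicRanges::start(genes); ge <- GenomicRanges::end(genes)
  gstr <- as.character(GenomicRanges::strand(genes))
  gid <- S4Vectors::mcols(genes)$feature_id
  pid <- S4Vectors::mcols(exons)$parent_id
  vapply(seq_along(lncrnas), function(i) {
    labs <- character(0)
    for (j in seq_along(genes)) {
      if (overlap_bases(ls[i], le[i], gs[j], ge[j]) < 1) next
      if (lstr[i] == "*") return("overlapping-unstranded")
      if (gstr[j] != lstr[i]) { labs <- c(labs, "AS-lncRNA"); next }
      ex <- exons[pid == gid[j]]
      es <- sort(GenomicRanges::start(ex)); ee <- sort(GenomicRanges::end(ex))
      inside_intron <- FALSE
      if (length(es) > 1)
        for (k in seq_len(length(es) - 1))
          if (ls[i] >= ee[k] + 1 && le[i] <= es[k + 1] - 1)
            inside_intron <- TRUE
      labs <- c(labs, if (inside_intron) "intronic" else "sense")
    }
    if (length(labs) == 0) return("lincRNA")
    pri <- c("AS-lncRNA", "intronic", "sense")
    pri[min(match(labs, pri))]
  }, character(1))
}

# quadratic TE association with the max-overlap / first-position tie rule
bf_te <- function(features, tes) {
  ord <- order(as.character(GenomeInfoDb::seqnames(tes)),
               GenomicRanges::start(tes), GenomicRanges::end(tes))
  tes <- tes[ord]
  fs <- GenomicRanges::start(features); fe <- GenomicRanges::end(features)
  ts <- GenomicRanges::start(tes); te_ <- GenomicRanges::end(tes)
  fam <- S4Vectors::mcols(tes)$superfamily
  out <- data.frame(te_associated = logical(length(features)),
                    te_superfamily = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(features)) {
    ow <- vapply(seq_along(tes), function(j)
      overlap_bases(fs[i], fe[i], ts[j], te_[j]), integer(1))
    if (any(ow >= 1)) {
      out$te_associated[i] <- TRUE
      out$te_superfamily[i] <- fam[which(ow == max(ow))[1]]
    }
  }
  out
}

# per-base ACR coverage fraction of one interval against a peak set
bf_coverage <- function(s, e, peaks) {
  covered <- logical(e - s + 1)
  for (j in seq_along(peaks)) {
    ps <- GenomicRanges::start(peaks)[j]; pe <- GenomicRanges::end(peaks)[j]
    lo <- max(s, ps); hi <- min(e, pe)
    if (lo <= hi) covered[(lo - s + 1):(hi - s + 1)] <- TRUE
  }
  mean(covered)
}

# brute-force BH step-up
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# two-sided Fisher exact p for a 2x2 table from the hypergeometric pmf
bf_fisher_p <- function(m1, u1, m2, u2) {
  k <- m1 + m2; n1 <- m1 + u1; n2 <- m2 + u2
  xs <- max(0, k - n2):min(k, n1)
  pmf <- stats::dhyper(xs, n1, n2, k)
  obs <- stats::dhyper(m1, n1, n2, k)
  sum(pmf[pmf <= obs * (1 + 1e-7)])
}

# small deterministic expression matrix fixture
mk_em <- function(values, generations, unit = "TPM", subgenome = NULL) {
  values <- as.matrix(values)
  reps <- stats::ave(seq_along(generations), generations, FUN = seq_along)
  snames <- paste0(generations, "_r", reps)
  colnames(values) <- snames
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  feats <- if (!is.null(subgenome))
    data.frame(feature_id = rownames(values), subgenome = subgenome,
               stringsAsFactors = FALSE) else NULL
  expression_matrix(values,
                    data.frame(sample = snames, generation = generations,
                               replicate = reps, stringsAsFactors = FALSE),
                    unit = unit, features = feats)
}

balanced_accuracy <- function(truth, call) {
  classes <- unique(truth)
  mean(vapply(classes, function(cl)
    mean(call[truth == cl] == cl), numeric(1)))
}
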