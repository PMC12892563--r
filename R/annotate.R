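#' Filter lncRNA candidates by the identification-pipeline rules
#'
#' A candidate transcript is retained iff it satisfies every rule, applied
#' in a fixed order with the first failing rule recorded:
#'
#' 1. `class_code`: assembly class code is one of `i`, `u`, `o`, `x`
#'    (intronic, intergenic, generic overlap, antisense).
#' 2. `coding_potential`: all three coding-potential screens called the
#'    transcript noncoding.
#' 3. `protein_domain`: no known protein domain.
#' 4. `length`: transcript strictly longer than `min_lncrna_length` nt
#'    (a transcript of exactly 200 nt fails the default).
#' 5. `expression_floor`: maximal TPM across samples at least
#'    `expression_floor_tpm` (candidates with max TPM < 0.5 are dropped).
#'
#' @param candidates data.frame with columns `feature_id`, `length`,
#'   `class_code`, `noncoding_cnci`, `noncoding_cpc`, `noncoding_plek`
#'   (logicals: `TRUE` = called noncoding), `has_protein_domain`, `max_tpm`.
#'   A missing (NA) verdict is an error, never a silent pass.
#' @param config [annotation_config()] object.
#' @return the input with logical `retained` and character `reason`
#'   (`"pass"` or the first failing rule) columns appended.
#' @export
filter_lncrna_candidates <- function(candidates, config = annotation_config()) {
  need <- c("feature_id", "length", "class_code", "noncoding_cnci",
            "noncoding_cpc", "noncoding_plek", "has_protein_domain", "max_tpm")
  miss <- setdiff(need, names(candidates))
  if (length(miss)) stop("candidates missing columns: ",
                         paste(miss, collapse = ", "))
  verdicts <- candidates[, c("noncoding_cnci", "noncoding_cpc",
                             "noncoding_plek", "has_protein_domain")]
  if (anyNA(verdicts))
    stop("missing coding-potential/domain verdict for: ",
         candidates$feature_id[which(!stats::complete.cases(verdicts))[1]])
  reason <- rep("pass", nrow(candidates))
  reason[!(candidates$class_code %in% c("i", "u", "o", "x"))] <- "class_code"
  ok <- reason == "pass"
  noncod <- candidates$noncoding_cnci & candidates$noncoding_cpc &
    candidates$noncoding_plek
  reason[ok & !noncod] <- "coding_potential"
  ok <- reason == "pass"
  reason[ok & candidates$has_protein_domain] <- "protein_domain"
  ok <- reason == "pass"
  reason[ok & !(candidates$length > config$min_lncrna_length)] <- "length"
  ok <- reason == "pass"
  reason[ok & candidates$max_tpm < config$expression_floor_tpm] <-
    "expression_floor"
  out <- candidates
  out$retained <- reason == "pass"
  out$reason <- reason
  out
}

#' Positional classification of lncRNA loci against gene models
#'
#' Assigns each lncRNA one of four classes by its overlap with gene bodies
#' and exons, with priority antisense > intronic > sense when several genes
#' give conflicting labels:
#'
#' * `AS-lncRNA`: overlaps a gene body on the opposite strand.
#' * `intronic`: lies entirely inside an intron of a same-strand gene.
#' * `sense`: overlaps a same-strand gene otherwise (including exon
#'   overlap).
#' * `lincRNA`: overlaps no gene.
#'
#' Unstranded lncRNAs cannot be given a strand-relative class; they are
#' labelled `lincRNA` when they overlap no gene and
#' `overlapping-unstranded` otherwise.
#'
#' @param lncrnas `GRanges` of lncRNA loci.
#' @param genes `GRanges` of gene bodies.
#' @param exons `GRanges` of exons carrying a `parent_id` column.
#' @return character vector of classes, parallel to `lncrnas`.
#' @export
classify_lncrna_locus <- function(lncrnas, genes, exons) {
  n <- length(lncrnas)
  if (n == 0) return(character(0))
  cls <- rep("lincRNA", n)
  if (length(genes) == 0) return(cls)
  hits <- GenomicRanges::findOverlaps(lncrnas, genes, ignore.strand = TRUE)
  if (length(hits) == 0) return(cls)
  lnc_str <- as.character(GenomicRanges::strand(lncrnas))
  gene_str <- as.character(GenomicRanges::strand(genes))
  introns <- .gene_introns(genes, exons)
  for (i in unique(S4Vectors::queryHits(hits))) {
    gs <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    if (lnc_str[i] == "*") { cls[i] <- "overlapping-unstranded"; next }
    labels <- vapply(gs, function(g) {
      if (gene_str[g] != "*" && gene_str[g] != lnc_str[i]) return("AS-lncRNA")
      intr <- introns[[g]]
      inside <- length(intr) > 0 && any(
        GenomicRanges::start(lncrnas)[i] >= GenomicRanges::start(intr) &
        GenomicRanges::end(lncrnas)[i] <= GenomicRanges::end(intr))
      if (inside) "intronic" else "sense"
    }, character(1))
    pri <- c("AS-lncRNA" = 1, "intronic" = 2, "sense" = 3)
    cls[i] <- names(pri)[min(pri[labels])]
  }
  cls
}

# per-gene intron GRanges (gaps between exons within the gene body)
.gene_introns <- function(genes, exons) {
  gid <- S4Vectors::mcols(genes)$feature_id
  pid <- if (length(exons)) S4Vectors::mcols(exons)$parent_id else character(0)
  lapply(seq_along(genes), function(g) {
    e <- exons[pid == gid[g]]
    if (length(e) < 2) return(GenomicRanges::GRanges())
    e <- sort(GenomicRanges::granges(e), ignore.strand = TRUE)
    GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(genes)[g],
      IRanges::IRanges(head(GenomicRanges::end(e), -1) + 1L,
                       GenomicRanges::start(e)[-1] - 1L))
  })
}

#' Categorize features as genic, proximal or distal to genes
#'
#' `genic` means at least 1 bp of overlap with any gene body; otherwise
#' `proximal` when the gap to the nearest gene edge is strictly below
#' `proximal_distance` (default 2 kb) and `distal` when the gap is 2 kb or
#' more. Strand is ignored. An empty gene set makes everything distal.
#'
#' @param features `GRanges` to categorize.
#' @param genes `GRanges` of gene bodies.
#' @param config [annotation_config()] object.
#' @return character vector in `{genic, proximal, distal}`.
#' @export
categorize_location <- function(features, genes, config = annotation_config()) {
  n <- length(features)
  if (n == 0) return(character(0))
  out <- rep("distal", n)
  if (length(genes) == 0) return(out)
  ov <- IRanges::overlapsAny(features, genes, ignore.strand = TRUE)
  out[ov] <- "genic"
  near <- GenomicRanges::distanceToNearest(features, genes,
                                           ignore.strand = TRUE)
  d <- rep(NA_integer_, n)
  d[S4Vectors::queryHits(near)] <- S4Vectors::mcols(near)$distance
  out[!ov & !is.na(d) & d < config$proximal_distance] <- "proximal"
  out
}

#' Transposable-element association of features
#'
#' A feature is TE-associated when it overlaps any TE by at least
#' `te_min_overlap_bases` (default 1 bp, strand ignored). The reported
#' superfamily is that of the TE with the largest overlap; ties are broken
#' by the TE earliest in genomic order.
#'
#' @param features `GRanges` to flag.
#' @param tes `GRanges` of TEs with a `superfamily` metadata column.
#' @param config [annotation_config()] object.
#' @return data.frame with `feature_id`, `te_associated`, `te_superfamily`
#'   (NA when unassociated) and `overlap_bases`.
#' @export
te_association <- function(features, tes, config = annotation_config()) {
  ids <- S4Vectors::mcols(features)$feature_id
  out <- data.frame(feature_id = ids,
                    te_associated = rep(FALSE, length(features)),
                    te_superfamily = NA_character_,
                    overlap_bases = 0L,
                    stringsAsFactors = FALSE)
  if (length(features) == 0 || length(tes) == 0) return(out)
  ord <- order(as.factor(GenomeInfoDb::seqnames(tes)),
               GenomicRanges::start(tes), GenomicRanges::end(tes))
  tes <- tes[ord]
  hits <- GenomicRanges::findOverlaps(features, tes, ignore.strand = TRUE,
                                      minoverlap = config$te_min_overlap_bases)
  if (length(hits) == 0) return(out)
  ow <- GenomicRanges::width(GenomicRanges::pintersect(
    GenomicRanges::granges(features)[S4Vectors::queryHits(hits)],
    GenomicRanges::granges(tes)[S4Vectors::subjectHits(hits)]))
  for (i in unique(S4Vectors::queryHits(hits))) {
    sel <- S4Vectors::queryHits(hits) == i
    w <- ow[sel]; te_idx <- S4Vectors::subjectHits(hits)[sel]
    best <- te_idx[w == max(w)]
    best <- min(best)  # earliest genomic position among ties
    out$te_associated[i] <- TRUE
    out$te_superfamily[i] <- S4Vectors::mcols(tes)$superfamily[best]
    out$overlap_bases[i] <- max(w)
  }
  out
}

#' Merge replicate peak sets into reproducible ACRs
#'
#' A peak survives iff a peak from at least one other replicate overlaps it
#' by strictly more than `acr_min_overlap_bases` (default 50 bp; an overlap
#' of exactly 50 bp does not qualify). Mutually supporting peaks are
#' connected into components, and each component supported by at least
#' `acr_min_replicates` distinct replicates contributes the union of its
#' peaks to the output.
#'
#' @param replicate_peaks list of two or more `GRanges` peak sets.
#' @param config [annotation_config()] object.
#' @return `GRanges` of merged reproducible ACRs (feature ids `ACRmerged_i`).
#' @export
merge_replicate_acrs <- function(replicate_peaks, config = annotation_config()) {
  if (!is.list(replicate_peaks) || length(replicate_peaks) < 2)
    stop("need at least 2 replicate peak sets")
  all_peaks <- suppressWarnings(do.call(c, lapply(replicate_peaks,
                                                  GenomicRanges::granges)))
  rep_of <- rep(seq_along(replicate_peaks),
                vapply(replicate_peaks, length, integer(1)))
  n <- length(all_peaks)
  if (n == 0) return(.gr(character(0), integer(0), integer(0), character(0),
                         character(0), character(0)))
  hits <- GenomicRanges::findOverlaps(
    all_peaks, all_peaks, ignore.strand = TRUE,
    minoverlap = config$acr_min_overlap_bases + 1L)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  cross <- rep_of[q] != rep_of[s]
  # union-find over cross-replicate support edges
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in which(cross)) {
    a <- find(q[k]); b <- find(s[k])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(n), find, integer(1))
  keep <- logical(n)
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    if (length(unique(rep_of[members])) >= config$acr_min_replicates)
      keep[members] <- TRUE
  }
  if (!any(keep)) return(.gr(character(0), integer(0), integer(0),
                             character(0), character(0), character(0)))
  merged <- GenomicRanges::reduce(all_peaks[keep], ignore.strand = TRUE)
  S4Vectors::mcols(merged)$feature_id <- sprintf("ACRmerged_%03d",
                                                 seq_along(merged))
  S4Vectors::mcols(merged)$feature_class <- "ACR"
  merged
}

#' Flag lncRNAs majority-covered by accessible chromatin
#'
#' A lncRNA is an ACR-lncRNA when, in at least `acr_min_replicates`
#' replicates, the fraction of its locus covered by ACR bases is strictly
#' greater than `acr_lncrna_coverage_fraction` (default 0.5; a coverage of
#' exactly one half does not qualify). Coverage is measured from the lncRNA
#' side: covered bases / lncRNA length.
#'
#' @param lncrnas `GRanges` of lncRNA loci.
#' @param acr_replicates list of `GRanges`, one ACR set per replicate.
#' @param config [annotation_config()] object.
#' @return data.frame with `feature_id`, per-replicate coverage fractions
#'   (`coverage_rep1`, ...), `n_replicates_covered` and logical
#'   `acr_lncrna`.
#' @export
call_acr_lncrna <- function(lncrnas, acr_replicates,
                            config = annotation_config()) {
  nrep <- length(acr_replicates)
  frac <- matrix(0, length(lncrnas), nrep)
  for (r in seq_len(nrep)) {
    acr <- GenomicRanges::reduce(GenomicRanges::granges(acr_replicates[[r]]),
                                 ignore.strand = TRUE)
    if (length(acr) && length(lncrnas)) {
      cov <- GenomicRanges::intersect(
        GenomicRanges::granges(lncrnas), acr, ignore.strand = TRUE)
      # per-lncRNA covered bases
      hits <- GenomicRanges::findOverlaps(lncrnas, acr, ignore.strand = TRUE)
      if (length(hits)) {
        pw <- GenomicRanges::width(GenomicRanges::pintersect(
          GenomicRanges::granges(lncrnas)[S4Vectors::queryHits(hits)],
          acr[S4Vectors::subjectHits(hits)]))
        covered <- tapply(pw, S4Vectors::queryHits(hits), sum)
        idx <- as.integer(names(covered))
        frac[idx, r] <- as.numeric(covered) / GenomicRanges::width(lncrnas)[idx]
      }
    }
  }
  nrep_cov <- rowSums(frac > config$acr_lncrna_coverage_fraction)
  out <- data.frame(feature_id = S4Vectors::mcols(lncrnas)$feature_id,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrep)) out[[paste0("coverage_rep", r)]] <- frac[, r]
  out$n_replicates_covered <- as.integer(nrep_cov)
  out$acr_lncrna <- nrep_cov >= config$acr_min_replicates
  out
}

#' Flag hybrid-specific (novel) ACR-lncRNAs
#'
#' Among ACR-lncRNAs, a locus is "novel" when it is expressed in the F1
#' hybrid (TPM strictly above `novel_hybrid_tpm`, default 0.5) but in
#' neither parent (both parental TPM strictly below `novel_parent_tpm`,
#' default 0.1). Generation-level TPM is the mean across that generation's
#' replicates.
#'
#' @param acr_flags data.frame from [call_acr_lncrna()] (only rows with
#'   `acr_lncrna == TRUE` are eligible).
#' @param expression [expression_matrix()] with TPM values and maternal,
#'   paternal and hybrid samples covering the flagged features.
#' @param config [annotation_config()] object.
#' @return the input data.frame with `hybrid_tpm`, `maternal_tpm`,
#'   `paternal_tpm` and logical `novel_acr_lncrna` appended.
#' @export
call_novel_acr_lncrna <- function(acr_flags, expression,
                                  config = annotation_config()) {
  stopifnot(inherits(expression, "expression_matrix"))
  gen_mean <- function(gen) {
    cols <- generation_samples(expression, gen)
    if (length(cols) == 0) stop("expression has no ", gen, " samples")
    rowMeans(expression$values[, cols, drop = FALSE])
  }
  hm <- gen_mean("hybrid"); mm <- gen_mean("maternal"); pm <- gen_mean("paternal")
  idx <- match(acr_flags$feature_id, rownames(expression$values))
  if (anyNA(idx)) stop("expression missing feature: ",
                       acr_flags$feature_id[is.na(idx)][1])
  out <- acr_flags
  out$hybrid_tpm <- hm[idx]
  out$maternal_tpm <- mm[idx]
  out$paternal_tpm <- pm[idx]
  out$novel_acr_lncrna <- out$acr_lncrna &
    out$hybrid_tpm > config$novel_hybrid_tpm &
    out$maternal_tpm < config$novel_parent_tpm &
    out$paternal_tpm < config$novel_parent_tpm
  out
}

#' Activated / silenced calls for phasiRNA loci
#'
#' An activated locus has hybrid reads strictly above the activation floor
#' (default 1, so a single read is not enough) with zero reads in both
#' parents; a silenced locus has zero hybrid reads with both parents
#' strictly above the floor. Everything else is `neither`. Raw locus read
#' counts are expected: the zero-read clause is only meaningful for counts.
#'
#' @param hybrid,maternal,paternal numeric vectors of raw read counts,
#'   parallel over loci.
#' @param config [annotation_config()] object.
#' @return character vector in `{activated, silenced, neither}`.
#' @export
call_activated_silenced <- function(hybrid, maternal, paternal,
                                    config = annotation_config()) {
  stopifnot(length(hybrid) == length(maternal),
            length(hybrid) == length(paternal))
  floor_ <- config$activation_read_floor
  out <- rep("neither", length(hybrid))
  out[hybrid > floor_ & maternal == 0 & paternal == 0] <- "activated"
  out[hybrid == 0 & maternal > floor_ & paternal > floor_] <- "silenced"
  out
}

#' Constitutive-expression flag
#'
#' A feature is constitutively expressed when every sample's TPM is
#' strictly above the floor (default 0.5); a single sample at exactly the
#' floor fails.
#'
#' @param expression [expression_matrix()] of TPM values.
#' @param floor_tpm the per-sample TPM floor.
#' @return named logical vector over features.
#' @export
constitutive_flag <- function(expression, floor_tpm = 0.5) {
  stopifnot(inherits(expression, "expression_matrix"))
  apply(expression$values > floor_tpm, 1, all)
}
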