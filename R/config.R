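#' Configuration objects
#'
#' Constructors for the tuning-parameter bundles used across the pipeline.
#' Every threshold that appears in a positional or statistical rule lives in
#' one of these objects so that a run manifest can echo the exact values used.
#'
#' `annotation_config()` holds the positional-annotation rules: the
#' genic/proximal/distal distance cut (default 2 kb, strict `<` on the gap),
#' the replicate-peak merge rule for accessible chromatin regions (ACRs;
#' overlap strictly greater than 50 bp, at least 2 replicates), the
#' ACR-lncRNA coverage rule (strictly more than 50% of the lncRNA covered, in
#' at least 2 replicates), the lncRNA candidate filters (length strictly
#' greater than 200 nt, maximal TPM at least 0.5), the novel ACR-lncRNA
#' expression gates (hybrid TPM strictly above 0.5, both parents strictly
#' below 0.1), and the activation read floor (hybrid reads strictly above 1).
#'
#' `dmr_config()` holds the differential-methylation rule: 200-bp bins, at
#' least 5 valid cytosines per bin in each group, per-site read depth at
#' least 5, BH-adjusted p strictly below 0.01, and context-specific
#' methylation-difference gates (CG 0.3, CHG 0.2, CHH 0.1, strict `>`).
#'
#' `dosage_design()` holds the ploidy-series design: generation order
#' (maternal AACC, hybrid AAC, paternal AA), the relative dosage vectors
#' (A subgenome 1/2, 2/3, 1; C subgenome 1/2, 1/3, 0), and the
#' dosage-dependence gates R^2 strictly above 0.64 and FDR strictly below
#' 0.05.
#'
#' @param proximal_distance gap in bases below which a feature is "proximal"
#'   to a gene (strict `<`).
#' @param acr_min_overlap_bases replicate peaks must overlap by strictly more
#'   than this many bases to be merged.
#' @param acr_min_replicates minimum number of replicates supporting an ACR
#'   or an ACR-lncRNA call.
#' @param acr_lncrna_coverage_fraction fraction of the lncRNA locus that must
#'   be covered by ACR bases (strict `>`).
#' @param min_lncrna_length minimum transcript length in nt (strict `>`).
#' @param expression_floor_tpm candidates whose maximal TPM is below this are
#'   dropped.
#' @param novel_hybrid_tpm,novel_parent_tpm hybrid/parental TPM gates for
#'   novel ACR-lncRNAs (strict `>` and strict `<` respectively).
#' @param activation_read_floor hybrid read count must exceed this for an
#'   "activated" call (strict `>`).
#' @param te_min_overlap_bases minimal overlap with a TE to flag association.
#' @return a named list with class `"triadNC_config"`.
#' @examples
#' cfg <- annotation_config()
#' cfg$proximal_distance
#' @export
annotation_config <- function(proximal_distance = 2000L,
                              acr_min_overlap_bases = 50L,
                              acr_min_replicates = 2L,
                              acr_lncrna_coverage_fraction = 0.5,
                              min_lncrna_length = 200L,
                              expression_floor_tpm = 0.5,
                              novel_hybrid_tpm = 0.5,
                              novel_parent_tpm = 0.1,
                              activation_read_floor = 1,
                              te_min_overlap_bases = 1L) {
  stopifnot(proximal_distance >= 0, acr_min_overlap_bases >= 0,
            acr_min_replicates >= 1,
            acr_lncrna_coverage_fraction > 0, acr_lncrna_coverage_fraction <= 1,
            min_lncrna_length >= 0, expression_floor_tpm >= 0,
            novel_hybrid_tpm >= 0, novel_parent_tpm >= 0,
            activation_read_floor >= 0, te_min_overlap_bases >= 1)
  structure(list(
    proximal_distance = as.integer(proximal_distance),
    acr_min_overlap_bases = as.integer(acr_min_overlap_bases),
    acr_min_replicates = as.integer(acr_min_replicates),
    acr_lncrna_coverage_fraction = acr_lncrna_coverage_fraction,
    min_lncrna_length = as.integer(min_lncrna_length),
    expression_floor_tpm = expression_floor_tpm,
    novel_hybrid_tpm = novel_hybrid_tpm,
    novel_parent_tpm = novel_parent_tpm,
    activation_read_floor = activation_read_floor,
    te_min_overlap_bases = as.integer(te_min_overlap_bases)
  ), class = "triadNC_config")
}

#' @rdname annotation_config
#' @param bin_size tiling bin width in bases.
#' @param min_cytosines_per_bin minimum valid cytosines per bin in each group.
#' @param min_site_coverage minimum reads at a cytosine for it to count.
#' @param padj_threshold BH-adjusted p gate (strict `<`).
#' @param delta named vector of methylation-difference gates per context
#'   (strict `>`).
#' @export
dmr_config <- function(bin_size = 200L,
                       min_cytosines_per_bin = 5L,
                       min_site_coverage = 5L,
                       padj_threshold = 0.01,
                       delta = c(CG = 0.3, CHG = 0.2, CHH = 0.1)) {
  stopifnot(bin_size > 0, min_cytosines_per_bin >= 1, min_site_coverage >= 0,
            padj_threshold > 0, padj_threshold < 1,
            all(c("CG", "CHG", "CHH") %in% names(delta)),
            all(delta > 0), all(delta < 1))
  structure(list(
    bin_size = as.integer(bin_size),
    min_cytosines_per_bin = as.integer(min_cytosines_per_bin),
    min_site_coverage = as.integer(min_site_coverage),
    padj_threshold = padj_threshold,
    delta = delta
  ), class = "triadNC_config")
}

#' @rdname annotation_config
#' @param subgenome `"A"` or `"C"`.
#' @param r2_threshold squared-correlation gate for dosage dependence
#'   (strict `>`).
#' @param fdr_threshold BH FDR gate (strict `<`).
#' @export
dosage_design <- function(subgenome = c("A", "C"),
                          r2_threshold = 0.64,
                          fdr_threshold = 0.05) {
  subgenome <- match.arg(subgenome)
  stopifnot(r2_threshold > 0, r2_threshold < 1,
            fdr_threshold > 0, fdr_threshold < 1)
  dosage <- if (subgenome == "A") c(1 / 2, 2 / 3, 1) else c(1 / 2, 1 / 3, 0)
  structure(list(
    subgenome = subgenome,
    generations = c("maternal", "hybrid", "paternal"),
    dosage = dosage,
    r2_threshold = r2_threshold,
    fdr_threshold = fdr_threshold
  ), class = "triadNC_config")
}

#' @export
print.triadNC_config <- function(x, ...) {
  cat("<triadNC config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %s: %s\n", nm, paste(format(v, digits = 4), collapse = ", ")))
  }
  invisible(x)
}
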