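#' Simulation configuration
#'
#' Parameters of the synthetic study: a single chromosome carrying genes
#' (with exons), transposable elements, lncRNAs placed to realize each
#' positional class, siRNA clusters placed genic/proximal/distal, and true
#' accessible-chromatin regions; plus the count-noise, methylation and
#' replicate-jitter settings used by the draw functions. The master `seed`
#' fixes every downstream draw; each sub-generator consumes its own RNG
#' stream derived from it, so extending one generator never perturbs
#' another's output.
#'
#' @param seed master seed (integer).
#' @param n_genes,n_tes,n_lncrnas,n_clusters,n_acrs feature counts.
#' @param chrom_length chromosome length in bases.
#' @param replicates biological replicates per generation.
#' @param nb_dispersion negative-binomial dispersion of simulated counts
#'   (variance = mu + dispersion * mu^2).
#' @param effect_log2fc planted fold-change magnitude on the log2 scale.
#' @param library_size target library depth per sample.
#' @param depth_jitter half-width of the uniform relative depth variation
#'   around the target (0.2 = within +/- 20%); 0 gives equal library
#'   sizes, the noiseless-limit condition.
#' @param dosage_noise_sd multiplicative (log-normal, log2-scale) noise on
#'   the dosage-series generation means.
#' @param meth_baseline named per-context baseline methylation proportions.
#' @param dmr_delta named per-context planted methylation differences.
#' @param meth_concentration beta-binomial concentration of per-site
#'   methylation proportions (larger = closer to binomial).
#' @param meth_coverage mean per-cytosine read depth.
#' @param acr_jitter maximal replicate boundary noise on true ACRs, bases.
#' @return a named list with class `"triadNC_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 80L, n_tes = 40L, n_lncrnas = 60L,
                       n_clusters = 45L, n_acrs = 30L,
                       chrom_length = 3e6,
                       replicates = 3L,
                       nb_dispersion = 0.05,
                       effect_log2fc = 2.0,
                       library_size = 3e5,
                       depth_jitter = 0.2,
                       dosage_noise_sd = 0.25,
                       meth_baseline = c(CG = 0.3, CHG = 0.25, CHH = 0.08),
                       dmr_delta = c(CG = 0.5, CHG = 0.35, CHH = 0.2),
                       meth_concentration = 100,
                       meth_coverage = 30,
                       acr_jitter = 20L) {
  stopifnot(n_genes >= 0, n_tes >= 0, n_lncrnas >= 0, n_clusters >= 0,
            n_acrs >= 0, chrom_length > 0, replicates >= 1,
            nb_dispersion >= 0, library_size > 0,
            depth_jitter >= 0, depth_jitter < 1,
            all(meth_baseline >= 0 & meth_baseline <= 1),
            all(dmr_delta >= 0 & dmr_delta <= 1),
            all(c("CG", "CHG", "CHH") %in% names(meth_baseline)),
            all(c("CG", "CHG", "CHH") %in% names(dmr_delta)),
            acr_jitter >= 0)
  structure(list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes), n_tes = as.integer(n_tes),
    n_lncrnas = as.integer(n_lncrnas), n_clusters = as.integer(n_clusters),
    n_acrs = as.integer(n_acrs),
    chrom_length = as.integer(chrom_length),
    replicates = as.integer(replicates),
    nb_dispersion = nb_dispersion,
    effect_log2fc = effect_log2fc,
    library_size = library_size,
    depth_jitter = depth_jitter,
    dosage_noise_sd = dosage_noise_sd,
    meth_baseline = meth_baseline,
    dmr_delta = dmr_delta,
    meth_concentration = meth_concentration,
    meth_coverage = meth_coverage,
    acr_jitter = as.integer(acr_jitter)
  ), class = "triadNC_config")
}

# per-subgenerator RNG streams derived from the master seed; offsets are
# part of the contract (documented stream order)
.stream_seed <- function(config, stream) {
  offsets <- c(annotation = 101L, expression = 211L, dosage = 307L,
               methylation = 401L, acr = 503L, hybrid = 601L)
  if (!stream %in% names(offsets)) stop("unknown RNG stream: ", stream)
  (config$seed * 7919L + offsets[[stream]]) %% .Machine$integer.max
}

.gr <- function(chrom, start, end, strand, id, class, ...) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr)$feature_id <- id
  S4Vectors::mcols(gr)$feature_class <- class
  extra <- list(...)
  for (nm in names(extra)) S4Vectors::mcols(gr)[[nm]] <- extra[[nm]]
  gr
}

#' Generate a synthetic annotation with planted ground truth
#'
#' Lays features out on a slot grid (10 kb slots) along one chromosome:
#' genes with three exons, lncRNAs placed to realize a planted class
#' (antisense over an exon on the opposite strand, fully intronic on the
#' same strand, sense-overlapping an exon, or intergenic more than 2 kb
#' from any gene), siRNA clusters placed genic / proximal (gap < 2 kb) /
#' distal (gap > 2 kb), TEs partly overlapping lincRNAs (for TE-association
#' tests) and partly free, and true ACRs either spanning a lncRNA (planted
#' ACR-lncRNA) or placed in free slots. The returned truth table records
#' every planted label.
#'
#' @param config [sim_config()] object.
#' @return list with elements `genes`, `exons`, `tes`, `lncrnas`,
#'   `clusters`, `acrs` (each a `GRanges`) and `truth` (data.frame with one
#'   row per feature: `feature_id`, `feature_class`, `planted_lnc_class`,
#'   `planted_location`, `planted_acr_lncrna`, `te_superfamily`).
#' @export
generate_annotation <- function(config) {
  set.seed(.stream_seed(config, "annotation"))
  W <- 10000L
  chrom <- "chr1"
  n_lnc_genic <- if (config$n_lncrnas > 0)
    sum(.lnc_classes(config$n_lncrnas) != "lincRNA") else 0L
  if (n_lnc_genic > config$n_genes && config$n_lncrnas > 0)
    stop("infeasible packing: need at least ", n_lnc_genic,
         " genes to host genic lncRNAs")
  n_linc <- config$n_lncrnas - n_lnc_genic
  if (config$n_genes > 0) {
    n_prox_clusters <- ceiling(config$n_clusters / 3)
    n_genic_clusters <- floor(config$n_clusters / 3)
  } else {
    n_prox_clusters <- n_genic_clusters <- 0L
  }
  n_distal_clusters <- config$n_clusters - n_prox_clusters - n_genic_clusters
  n_te_free <- ceiling(config$n_tes / 2)
  n_acr_free <- max(0L, config$n_acrs - min(config$n_acrs, config$n_lncrnas))
  n_slots <- config$n_genes + n_linc + n_distal_clusters + n_te_free +
    n_acr_free + 2L
  if (n_slots * W > config$chrom_length)
    stop("infeasible packing: need ", n_slots * W,
         " bases but chrom_length is ", config$chrom_length)
  slot_start <- function(i) (i - 1L) * W + 1L  # 1-based

  empty <- .gr(character(0), integer(0), integer(0), character(0),
               character(0), character(0))
  genes <- exons <- tes <- lncrnas <- clusters <- acrs <- empty
  truth <- list()
  slot <- 1L

  # --- genes: body 3000 bp in slot center, exons 600 bp at offsets 0/1200/2400
  if (config$n_genes > 0) {
    gs <- slot_start(seq_len(config$n_genes) + (slot - 1L)) + 3000L
    strd <- rep(c("+", "-"), length.out = config$n_genes)
    gid <- sprintf("gene%03d", seq_len(config$n_genes))
    genes <- .gr(chrom, gs, gs + 2999L, strd, gid, "gene")
    ex_off <- c(0L, 1200L, 2400L)
    exons <- .gr(chrom,
                 rep(gs, each = 3) + ex_off,
                 rep(gs, each = 3) + ex_off + 599L,
                 rep(strd, each = 3),
                 paste0(rep(gid, each = 3), ".e", 1:3),
                 "exon", parent_id = rep(gid, each = 3))
    slot <- slot + config$n_genes
  }

  # --- lncRNAs
  if (config$n_lncrnas > 0) {
    cls <- .lnc_classes(config$n_lncrnas)
    lid <- sprintf("lnc%03d", seq_len(config$n_lncrnas))
    host <- rep(NA_integer_, config$n_lncrnas)
    host[cls != "lincRNA"] <- seq_len(n_lnc_genic)  # one genic lncRNA per gene
    lstart <- lend <- integer(config$n_lncrnas)
    lstrand <- character(config$n_lncrnas)
    linc_slot <- slot
    for (i in seq_len(config$n_lncrnas)) {
      if (cls[i] == "lincRNA") {
        s <- slot_start(linc_slot) + 4000L
        lstart[i] <- s; lend[i] <- s + 799L
        lstrand[i] <- if (i %% 2 == 0) "+" else "-"
        linc_slot <- linc_slot + 1L
      } else {
        g <- host[i]
        gs <- GenomicRanges::start(genes)[g]
        gstr <- as.character(GenomicRanges::strand(genes))[g]
        opp <- if (gstr == "+") "-" else "+"
        if (cls[i] == "AS-lncRNA") {          # across exon 1, opposite strand
          lstart[i] <- gs + 100L; lend[i] <- gs + 699L; lstrand[i] <- opp
        } else if (cls[i] == "intronic") {    # inside intron 1, same strand
          lstart[i] <- gs + 700L; lend[i] <- gs + 1099L; lstrand[i] <- gstr
        } else {                              # sense: across exon 2
          lstart[i] <- gs + 1100L; lend[i] <- gs + 1899L; lstrand[i] <- gstr
        }
      }
    }
    lncrnas <- .gr(chrom, lstart, lend, lstrand, lid, "lncRNA")
    slot <- linc_slot
    truth$lnc <- data.frame(feature_id = lid, feature_class = "lncRNA",
                            planted_lnc_class = cls,
                            stringsAsFactors = FALSE)
  }

  # --- siRNA clusters (unstranded, 300 bp)
  if (config$n_clusters > 0) {
    loc <- rep(c("genic", "proximal", "distal"),
               c(n_genic_clusters, n_prox_clusters, n_distal_clusters))
    if (config$n_genes == 0) loc[] <- "distal"  # nothing to be near
    cid <- sprintf("cluster%03d", seq_len(config$n_clusters))
    cs <- integer(config$n_clusters)
    for (i in seq_len(config$n_clusters)) {
      if (loc[i] == "genic") {
        g <- ((i - 1L) %% config$n_genes) + 1L
        cs[i] <- GenomicRanges::start(genes)[g] + 2000L
      } else if (loc[i] == "proximal") {
        # 500 bp gap upstream of a gene body (still inside its slot)
        g <- ((i - 1L) %% config$n_genes) + 1L
        cs[i] <- GenomicRanges::start(genes)[g] - 800L
      } else {
        cs[i] <- slot_start(slot) + 4850L
        slot <- slot + 1L
      }
    }
    clusters <- .gr(chrom, cs, cs + 299L, "*", cid, "siRNA_cluster")
    truth$cluster <- data.frame(feature_id = cid,
                                feature_class = "siRNA_cluster",
                                planted_location = loc,
                                stringsAsFactors = FALSE)
  }

  # --- TEs (1 kb): half overlapping lincRNAs, half in free slots
  if (config$n_tes > 0) {
    fams <- c("LTR/Gypsy", "LTR/Copia", "DNA/MuDR", "LINE/L1")
    tid <- sprintf("TE%03d", seq_len(config$n_tes))
    tstart <- integer(config$n_tes)
    linc_idx <- which(truth$lnc$planted_lnc_class == "lincRNA")
    n_on_linc <- min(config$n_tes - n_te_free, length(linc_idx))
    k <- 0L
    for (i in seq_len(config$n_tes)) {
      if (i <= n_on_linc) {
        l <- linc_idx[i]
        tstart[i] <- GenomicRanges::start(lncrnas)[l] - 200L  # overlaps lincRNA
      } else {
        tstart[i] <- slot_start(slot + k) + 4500L
        k <- k + 1L
      }
    }
    slot <- slot + k
    tes <- .gr(chrom, tstart, tstart + 999L, "*", tid, "TE",
               superfamily = rep(fams, length.out = config$n_tes))
  }

  # --- true ACRs: first min(n_acrs, n_lncrnas) span a lncRNA entirely
  if (config$n_acrs > 0) {
    aid <- sprintf("ACR%03d", seq_len(config$n_acrs))
    astart <- aend <- integer(config$n_acrs)
    n_on_lnc <- min(config$n_acrs, config$n_lncrnas)
    k <- 0L
    for (i in seq_len(config$n_acrs)) {
      if (i <= n_on_lnc) {
        astart[i] <- GenomicRanges::start(lncrnas)[i] - 100L
        aend[i] <- GenomicRanges::end(lncrnas)[i] + 100L
      } else {
        astart[i] <- slot_start(slot + k) + 6500L
        aend[i] <- astart[i] + 499L
        k <- k + 1L
      }
    }
    slot <- slot + k
    acrs <- .gr(chrom, astart, aend, "*", aid, "ACR")
    if (config$n_lncrnas > 0)
      truth$lnc$planted_acr_lncrna <- seq_len(config$n_lncrnas) <= n_on_lnc
  }

  truth_df <- .bind_truth(truth, genes, tes)
  ann <- list(genes = genes, exons = exons, tes = tes, lncrnas = lncrnas,
              clusters = clusters, acrs = acrs, truth = truth_df)
  if (length(exons)) validate_gene_models(genes, exons)
  ann
}

.lnc_classes <- function(n) {
  # deterministic class cycle per 10: 4 lincRNA, 3 antisense, 2 intronic, 1 sense
  base <- c("lincRNA", "AS-lncRNA", "lincRNA", "intronic", "sense",
            "AS-lncRNA", "lincRNA", "AS-lncRNA", "lincRNA", "intronic")
  rep(base, length.out = n)
}

.bind_truth <- function(truth, genes, tes) {
  pieces <- list()
  if (!is.null(truth$lnc)) {
    t1 <- truth$lnc
    if (is.null(t1$planted_acr_lncrna)) t1$planted_acr_lncrna <- FALSE
    t1$planted_location <- NA_character_
    pieces$lnc <- t1
  }
  if (!is.null(truth$cluster)) {
    t2 <- truth$cluster
    t2$planted_lnc_class <- NA_character_
    t2$planted_acr_lncrna <- NA
    pieces$cluster <- t2
  }
  if (length(genes)) {
    pieces$gene <- data.frame(
      feature_id = S4Vectors::mcols(genes)$feature_id,
      feature_class = "gene", planted_lnc_class = NA_character_,
      planted_acr_lncrna = NA, planted_location = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (length(tes)) {
    pieces$te <- data.frame(
      feature_id = S4Vectors::mcols(tes)$feature_id,
      feature_class = "TE", planted_lnc_class = NA_character_,
      planted_acr_lncrna = NA, planted_location = NA_character_,
      stringsAsFactors = FALSE)
  }
  cols <- c("feature_id", "feature_class", "planted_lnc_class",
            "planted_location", "planted_acr_lncrna")
  if (length(pieces) == 0) {
    out <- data.frame(feature_id = character(0), feature_class = character(0),
                      planted_lnc_class = character(0),
                      planted_location = character(0),
                      planted_acr_lncrna = logical(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, lapply(pieces, function(p) p[, cols]))
  rownames(out) <- NULL
  out
}
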