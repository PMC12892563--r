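#' Construct an in-silico hybrid from the two parents
#'
#' Emulates a 1:1 computational mixture of the parental libraries. In
#' `"mean"` mode parental replicates are paired in order and the mid-parent
#' value (arithmetic mean of depth-normalized values, counts-per-million
#' for count input) is returned per feature. In `"pooled-count"` mode each
#' parental library of a pair is subsampled without replacement
#' (multivariate hypergeometric) to half the target depth and the halves
#' are summed, so each in-silico library hits the target depth exactly;
#' the draw is deterministic given `seed`.
#'
#' @param maternal,paternal [expression_matrix()] objects over the same
#'   features with equally many replicates.
#' @param mode `"mean"` or `"pooled-count"`.
#' @param seed RNG seed for the subsampling draw (pooled-count mode).
#' @param target_depth per-library target depth for pooled-count mode;
#'   default is the smaller parental library of each pair, rounded down to
#'   an even number.
#' @return an [expression_matrix()] with generation `"insilico"`; unit
#'   `"RPM"` in mean mode (CPM scale), `"count"` in pooled-count mode.
#' @export
make_insilico_hybrid <- function(maternal, paternal,
                                 mode = c("mean", "pooled-count"),
                                 seed = 1L, target_depth = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(maternal, "expression_matrix"),
            inherits(paternal, "expression_matrix"))
  if (!identical(rownames(maternal$values), rownames(paternal$values)))
    stop("maternal and paternal feature sets differ")
  nm <- ncol(maternal$values); np <- ncol(paternal$values)
  if (nm != np) stop("parental replicate counts differ (", nm, " vs ", np, ")")
  if (mode == "mean") {
    m <- normalize_cpm(maternal)$values
    p <- normalize_cpm(paternal)$values
    v <- (m + p) / 2
    unit <- if (maternal$unit == "count") "RPM" else maternal$unit
  } else {
    if (maternal$unit != "count" || paternal$unit != "count")
      stop("pooled-count mode needs raw counts")
    set.seed(seed)
    v <- matrix(0, nrow(maternal$values), nm)
    for (k in seq_len(nm)) {
      mk <- maternal$values[, k]; pk <- paternal$values[, k]
      tk <- if (is.null(target_depth)) 2 * (min(sum(mk), sum(pk)) %/% 2)
            else target_depth
      v[, k] <- .subsample_counts(mk, tk / 2) + .subsample_counts(pk, tk / 2)
    }
    unit <- "count"
  }
  snames <- paste0("insilico_r", seq_len(nm))
  dimnames(v) <- list(rownames(maternal$values), snames)
  expression_matrix(v,
    data.frame(sample = snames, generation = "insilico",
               replicate = seq_len(nm), stringsAsFactors = FALSE),
    unit = unit, features = maternal$features)
}

# multivariate hypergeometric draw of k reads from integer count vector x
.subsample_counts <- function(x, k) {
  x <- as.integer(round(x))
  total <- sum(x)
  if (k > total) stop("cannot subsample ", k, " reads from ", total)
  out <- integer(length(x))
  remaining_pop <- total
  remaining_draw <- as.integer(k)
  for (i in seq_along(x)) {
    if (remaining_draw == 0) break
    remaining_pop <- remaining_pop - x[i]
    out[i] <- stats::rhyper(1, x[i], remaining_pop, remaining_draw)
    remaining_draw <- remaining_draw - out[i]
  }
  out
}

#' Pairwise differential-expression test between two sample groups
#'
#' Built-in test: two-sided Welch t-test per feature on log2(normalized
#' value + 1) — counts are CPM-normalized first — with BH adjustment across
#' features. The log2 fold change is the difference of group means on the
#' same scale. A feature is flagged significant only when both gates hold:
#' `padj < alpha` and `|log2fc| >= lfc_threshold` (1.5 for transcripts and
#' lncRNAs, 1.0 for small RNAs). Externally computed tables (e.g. a
#' DESeq2-style result) can be substituted anywhere a `de` result is
#' consumed, as long as they carry the same columns.
#'
#' @param em [expression_matrix()] object.
#' @param group_a,group_b sample id vectors (at least 2 each for the
#'   built-in test). The fold change is oriented A minus B.
#' @param comparison label stored in the result (e.g. `"HvsM"`).
#' @param lfc_threshold absolute log2-fold-change gate.
#' @param alpha BH-adjusted p gate.
#' @param engine `"moderated"` (limma empirical-Bayes pooled variance, the
#'   recommended choice at 2-3 replicates) or `"welch"` (per-feature Welch
#'   t-test).
#' @return data.frame `feature_id`, `comparison`, `log2fc`, `pvalue`,
#'   `padj`, `significant`.
#' @export
pairwise_de <- function(em, group_a, group_b, comparison = "AvsB",
                        lfc_threshold = 1.5, alpha = 0.05,
                        engine = c("moderated", "welch")) {
  stopifnot(inherits(em, "expression_matrix"))
  engine <- match.arg(engine)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("built-in test needs >= 2 replicates per group")
  v <- log2(normalize_cpm(em)$values + 1)
  a <- v[, group_a, drop = FALSE]
  b <- v[, group_b, drop = FALSE]
  lfc <- rowMeans(a) - rowMeans(b)
  if (engine == "welch") {
    pv <- vapply(seq_len(nrow(v)), function(i) .welch_p(a[i, ], b[i, ]),
                 numeric(1))
  } else {
    x <- cbind(a, b)
    grp <- factor(rep(c("A", "B"), c(ncol(a), ncol(b))), levels = c("B", "A"))
    design <- stats::model.matrix(~grp)
    fit <- limma::eBayes(limma::lmFit(x, design))
    pv <- fit$p.value[, "grpA"]
    pv[is.na(pv)] <- 1  # zero-variance rows with equal means
  }
  padj <- bh_fdr(pv)
  data.frame(feature_id = rownames(v), comparison = comparison,
             log2fc = lfc, pvalue = pv, padj = padj,
             significant = padj < alpha & abs(lfc) >= lfc_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

.welch_p <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  stats::t.test(x, y)$p.value
}

# twelve-bin lookup: sign triple (HvsM, HvsP, MvsP) with -1/0/+1 from the
# significance flag and the fold-change sign. Bins I-VI have M > P,
# VII-XII the mirror; degenerate triples map to "none".
.twelve_bin_table <- function() {
  tab <- rbind(
    c( 0,  1,  1, "I"),    # H = M > P              (maternal dominance)
    c(-1,  0,  1, "II"),   # M > H = P              (paternal dominance)
    c( 1,  1,  1, "III"),  # H above both, M > P    (transgressive up)
    c(-1, -1,  1, "IV"),   # H below both, M > P    (transgressive down)
    c( 0,  0,  1, "V"),    # H intermediate, neither H-test fires (additive-like)
    c(-1,  1,  1, "VI"),   # M > H > P, both fire   (intermediate)
    c( 0, -1, -1, "VII"),  # H = M < P
    c( 1,  0, -1, "VIII"), # M < H = P
    c( 1,  1, -1, "IX"),   # H above both, M < P
    c(-1, -1, -1, "X"),    # H below both, M < P
    c( 0,  0, -1, "XI"),   # H intermediate, M < P
    c( 1, -1, -1, "XII"))  # M < H < P, both fire
  data.frame(hm = as.integer(tab[, 1]), hp = as.integer(tab[, 2]),
             mp = as.integer(tab[, 3]), bin = tab[, 4],
             stringsAsFactors = FALSE)
}

#' Classify features into additivity / dominance / transgression patterns
#'
#' Consumes the four pairwise comparisons per feature — hybrid vs maternal
#' (HvsM), hybrid vs paternal (HvsP), maternal vs paternal (MvsP) and
#' hybrid vs mid-parent (HvsMPV) — and assigns exactly one grouped label by
#' a fixed cascade:
#'
#' 1. `no-change`: none of HvsM / HvsP / MvsP significant.
#' 2. `transgressive-up` / `transgressive-down`: HvsM and HvsP both
#'    significant with the hybrid above (below) both parents.
#' 3. `additive`: MvsP significant, HvsMPV not significant, hybrid between
#'    the parents. Additivity explicitly requires the mid-parent test,
#'    which should be run with a sensitive fold-change floor (see
#'    [call_patterns()]): rejecting additivity is an equivalence-style
#'    screen, so a large fold-change floor there would misroute
#'    dominant features into the additive class.
#' 4. `ELD-M`: HvsM not significant, HvsP significant (hybrid looks
#'    maternal); `ELD-P` symmetric.
#' 5. `ambiguous`: any remaining sign pattern.
#'
#' A twelve-bin sign code over (HvsM, HvsP, MvsP) is always recorded so any
#' alternative grouping can be applied post hoc; degenerate sign triples
#' carry bin `"none"`.
#'
#' @param de_hm,de_hp,de_mp,de_hmpv data.frames from [pairwise_de()] (or
#'   external tables with the same columns), fold changes oriented
#'   hybrid - maternal, hybrid - paternal, maternal - paternal, hybrid -
#'   midparent. All four must cover the same features.
#' @param min_guard_lfc floor on the adaptive closeness guards (see
#'   Details).
#' @param eld_guard_lfc hard cap on |log2fc| of the non-significant H
#'   comparison for an ELD call (the hybrid must actually sit near the
#'   retained parent).
#' @details
#' Verdicts alone cannot separate additivity from expression-level
#' dominance reliably: on the log scale the arithmetic mid-parent lies
#' only `g + 1 - log2(1 + 2^g)` below the high parent for a parental gap
#' of `g` log2 units (0.68 for a 4-fold gap), well inside the fold-change
#' gate. The classifier therefore adds closeness guards placed at the
#' midpoint between the additive and the nearest dominant hypothesis,
#' computed per feature from the observed parental gap and applied
#' one-sided toward the confusable hypothesis.
#' @return data.frame `feature_id`, `twelve_bin`, `pattern`.
#' @export
classify_pattern <- function(de_hm, de_hp, de_mp, de_hmpv,
                             min_guard_lfc = 0.25, eld_guard_lfc = 0.75) {
  ids <- de_hm$feature_id
  for (d in list(de_hp, de_mp, de_hmpv))
    if (!setequal(d$feature_id, ids))
      stop("the four comparisons cover different feature sets")
  de_hp <- de_hp[match(ids, de_hp$feature_id), ]
  de_mp <- de_mp[match(ids, de_mp$feature_id), ]
  de_hmpv <- de_hmpv[match(ids, de_hmpv$feature_id), ]
  sgn <- function(d) ifelse(d$significant, ifelse(d$log2fc > 0, 1L, -1L), 0L)
  s_hm <- sgn(de_hm); s_hp <- sgn(de_hp); s_mp <- sgn(de_mp)
  tab <- .twelve_bin_table()
  key <- paste(s_hm, s_hp, s_mp)
  bin <- tab$bin[match(key, paste(tab$hm, tab$hp, tab$mp))]
  bin[is.na(bin)] <- "none"

  pattern <- rep("ambiguous", length(ids))
  none_sig <- s_hm == 0 & s_hp == 0 & s_mp == 0
  pattern[none_sig] <- "no-change"
  tr_up <- s_hm == 1 & s_hp == 1
  tr_dn <- s_hm == -1 & s_hp == -1
  pattern[tr_up] <- "transgressive-up"
  pattern[tr_dn] <- "transgressive-down"
  between <- de_hm$log2fc * de_hp$log2fc <= 0  # hybrid between the parents
  # hypothesis offsets on the log2 scale, given the observed parental gap:
  # distance from the arithmetic mid-parent to the high and low parent
  g <- abs(de_mp$log2fc)
  delta_high <- g + 1 - log2(1 + 2^g)
  delta_low <- log2(1 + 2^g) - 1
  # additive: mid-parent deviation must stay below the midpoint to the
  # nearest dominant hypothesis, per side
  toward_high <- de_hmpv$log2fc > 0  # above the MPV = toward the high parent
  add_thr <- pmax(min_guard_lfc,
                  ifelse(toward_high, delta_high, delta_low) / 2)
  additive <- pattern == "ambiguous" & !none_sig & s_mp != 0 &
    !de_hmpv$significant & abs(de_hmpv$log2fc) < add_thr & between
  pattern[additive] <- "additive"
  # ELD: hybrid close to the retained parent, with the closeness bound at
  # the midpoint toward the mid-parent (one-sided) plus a hard cap
  m_is_high <- de_mp$log2fc > 0
  eld_m_thr <- pmax(min_guard_lfc, ifelse(m_is_high, delta_high, delta_low) / 2)
  eld_p_thr <- pmax(min_guard_lfc, ifelse(m_is_high, delta_low, delta_high) / 2)
  toward_mpv_m <- -sign(de_mp$log2fc) * de_hm$log2fc  # >0 = drifting to MPV
  toward_mpv_p <- sign(de_mp$log2fc) * de_hp$log2fc
  free <- pattern == "ambiguous"
  eld_m <- free & s_hm == 0 & s_hp != 0 &
    toward_mpv_m < eld_m_thr & abs(de_hm$log2fc) < eld_guard_lfc
  pattern[eld_m] <- "ELD-M"
  free <- pattern == "ambiguous"
  eld_p <- free & s_hp == 0 & s_hm != 0 &
    toward_mpv_p < eld_p_thr & abs(de_hp$log2fc) < eld_guard_lfc
  pattern[eld_p] <- "ELD-P"
  data.frame(feature_id = ids, twelve_bin = bin, pattern = pattern,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the four comparisons and classify every feature
#'
#' Convenience wrapper: builds the in-silico mid-parent (mean mode), runs
#' [pairwise_de()] for HvsM, HvsP, MvsP and HvsMPV, and calls
#' [classify_pattern()].
#'
#' @param em [expression_matrix()] with maternal, paternal and hybrid
#'   samples.
#' @param lfc_threshold,alpha,engine passed to [pairwise_de()].
#' @param mpv_lfc_threshold fold-change floor for the hybrid-vs-midparent
#'   comparison only; kept small (default 0.5) because this test screens
#'   for deviation from additivity rather than for a biologically large
#'   change.
#' @param refine apply the nearest-hypothesis refinement: for features
#'   with significantly different parents whose verdict-based call landed
#'   in the additive/ELD/ambiguous set, the final label is the hypothesis
#'   (mid-parent value, maternal level, paternal level) closest to the
#'   observed hybrid mean on the log2 scale. The twelve-bin code is left
#'   untouched.
#' @return list with `calls` (the [classify_pattern()] result) and `de`
#'   (named list of the four comparison tables).
#' @export
call_patterns <- function(em, lfc_threshold = 1.5, alpha = 0.05,
                          mpv_lfc_threshold = 0.5,
                          engine = c("moderated", "welch"),
                          refine = TRUE) {
  engine <- match.arg(engine)
  stopifnot(inherits(em, "expression_matrix"))
  mat <- generation_samples(em, "maternal")
  pat <- generation_samples(em, "paternal")
  hyb <- generation_samples(em, "hybrid")
  if (!length(mat) || !length(pat) || !length(hyb))
    stop("expression must contain maternal, paternal and hybrid samples")
  m_em <- subset_expression(em, samples = mat)
  p_em <- subset_expression(em, samples = pat)
  mpv <- make_insilico_hybrid(m_em, p_em, mode = "mean")
  # one normalized matrix across generations + the midparent columns
  norm <- normalize_cpm(em)
  joint <- cbind(norm$values, mpv$values)
  smeta <- rbind(norm$samples, mpv$samples)
  jem <- expression_matrix(joint, smeta, unit = norm$unit)
  joint <- log2(joint + 1)
  de <- list(
    HvsM = pairwise_de(jem, hyb, mat, "HvsM", lfc_threshold, alpha, engine),
    HvsP = pairwise_de(jem, hyb, pat, "HvsP", lfc_threshold, alpha, engine),
    MvsP = pairwise_de(jem, mat, pat, "MvsP", lfc_threshold, alpha, engine),
    HvsMPV = pairwise_de(jem, hyb, colnames(mpv$values), "HvsMPV",
                         mpv_lfc_threshold, alpha, engine))
  calls <- classify_pattern(de$HvsM, de$HvsP, de$MvsP, de$HvsMPV)
  if (refine) {
    # nearest-hypothesis refinement: among features whose parents differ
    # and whose verdict-based call landed in the confusable set, reassign
    # additive / ELD-M / ELD-P by which hypothesis (mid-parent, maternal
    # or paternal level) best predicts the observed hybrid mean
    gmean <- function(cols) rowMeans(joint[, cols, drop = FALSE])
    mbar <- gmean(mat); pbar <- gmean(pat); hbar <- gmean(hyb)
    mpvbar <- log2((2^mbar + 2^pbar) / 2)
    ids <- calls$feature_id
    k <- match(ids, rownames(joint))
    mp_sig <- de$MvsP$significant[match(ids, de$MvsP$feature_id)]
    cand <- calls$pattern %in% c("additive", "ELD-M", "ELD-P", "ambiguous") &
      mp_sig
    dist3 <- cbind(abs(hbar - mpvbar)[k], abs(hbar - mbar)[k],
                   abs(hbar - pbar)[k])
    best <- c("additive", "ELD-M", "ELD-P")[apply(dist3, 1, which.min)]
    calls$pattern[cand] <- best[cand]
  }
  list(calls = calls, de = de)
}

#' Tabulate pattern fractions
#'
#' @param calls data.frame from [classify_pattern()], optionally with a
#'   `feature_type` column.
#' @return data.frame `feature_type`, `pattern`, `n`, `fraction`; fractions
#'   sum to 1 within each feature type.
#' @export
summarize_patterns <- function(calls) {
  if (nrow(calls) == 0)
    return(data.frame(feature_type = character(0), pattern = character(0),
                      n = integer(0), fraction = numeric(0)))
  type <- if ("feature_type" %in% names(calls)) calls$feature_type
          else rep("all", nrow(calls))
  tab <- as.data.frame(table(feature_type = type, pattern = calls$pattern),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab <- tab[tab$n > 0 | TRUE, ]
  totals <- tapply(tab$n, tab$feature_type, sum)
  tab$fraction <- tab$n / as.numeric(totals[tab$feature_type])
  tab[order(tab$feature_type, -tab$n), ]
}

#' Correlation between a real and an in-silico hybrid
#'
#' Pearson correlation over expressed features (mean hybrid abundance
#' strictly above `min_expression`, mirroring the "TPM greater than 1"
#' expressed-gene rule) of per-feature mean log2(value + 1).
#'
#' @param hybrid,insilico [expression_matrix()] objects over the same
#'   features.
#' @param min_expression expression floor applied to the hybrid means.
#' @return list with `r`, `n_features`.
#' @export
hybrid_vs_insilico_correlation <- function(hybrid, insilico,
                                           min_expression = 1) {
  stopifnot(inherits(hybrid, "expression_matrix"),
            inherits(insilico, "expression_matrix"))
  if (!identical(rownames(hybrid$values), rownames(insilico$values)))
    stop("feature sets differ")
  h <- rowMeans(normalize_cpm(hybrid)$values)
  s <- rowMeans(normalize_cpm(insilico)$values)
  keep <- h > min_expression
  if (sum(keep) < 3) stop("fewer than 3 expressed features")
  list(r = stats::cor(log2(h[keep] + 1), log2(s[keep] + 1)),
       n_features = sum(keep))
}
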