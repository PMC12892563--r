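#' Run the full synthetic-study pipeline
#'
#' Orchestrates simulate -> annotate -> patterns -> dosage -> methylation ->
#' integrate, with every stage communicating through files in `outdir`
#' (GFF3/BED/TSV), so each stage can be rerun on real upstream-tool outputs.
#' A run manifest (YAML) records the seed, the package version, an md5 of
#' the configuration and every threshold used. Reruns with the same
#' configuration and seed reproduce byte-identical stage outputs.
#' Truth-vs-call confusion matrices are written for every planted label
#' set.
#'
#' @param config [sim_config()] object (or path to a YAML file of its
#'   fields).
#' @param outdir output directory (created).
#' @param ann_config [annotation_config()] object.
#' @param dmr_cfg [dmr_config()] object.
#' @param verbose print stage progress.
#' @return invisibly, a list of the main in-memory results.
#' @export
run_pipeline <- function(config = sim_config(), outdir = tempfile("triadNC_"),
                         ann_config = annotation_config(),
                         dmr_cfg = dmr_config(), verbose = FALSE) {
  if (is.character(config)) config <- do.call(sim_config, yaml::read_yaml(config))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[triadNC] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  say("simulate")
  ann <- stage("simulate", generate_annotation(config))
  write_intervals(c(ann$genes, ann$exons), file.path(outdir, "genes.gff3"),
                  format = "gff3")
  for (nm in c("tes", "lncrnas", "clusters", "acrs"))
    write_intervals(ann[[nm]], file.path(outdir, paste0(nm, ".bed")),
                    format = "bed")
  sim <- stage("simulate", simulate_expression(ann$truth, config))
  write_expression(sim$expression, file.path(outdir, "expression.tsv"),
                   file.path(outdir, "expression_samples.tsv"))
  dos <- stage("simulate", simulate_dosage_series(config))
  write_expression(dos$expression, file.path(outdir, "dosage_expression.tsv"),
                   file.path(outdir, "dosage_samples.tsv"))
  met <- stage("simulate", simulate_methylation(config))
  write_methylation(met$group1, file.path(outdir, "methylation_group1.tsv"))
  write_methylation(met$group2, file.path(outdir, "methylation_group2.tsv"))
  acr <- stage("simulate", simulate_acr_replicates(ann$acrs, config))
  for (r in seq_along(acr$replicates))
    write_intervals(acr$replicates[[r]],
                    file.path(outdir, sprintf("acr_rep%d.bed", r)),
                    format = "bed")
  truth <- merge(ann$truth, sim$truth, by = "feature_id", all.x = TRUE)
  .tsv(truth, file.path(outdir, "truth_annotation.tsv"))
  .tsv(dos$truth, file.path(outdir, "truth_dosage.tsv"))
  .tsv(met$truth, file.path(outdir, "truth_methylation.tsv"))

  say("annotate")
  lnc_class <- stage("annotate",
    classify_lncrna_locus(ann$lncrnas, ann$genes, ann$exons))
  loc <- stage("annotate",
    categorize_location(ann$clusters, ann$genes, ann_config))
  te <- stage("annotate", te_association(ann$lncrnas, ann$tes, ann_config))
  acr_flags <- stage("annotate",
    call_acr_lncrna(ann$lncrnas, acr$replicates, ann_config))
  merged_acrs <- stage("annotate",
    merge_replicate_acrs(acr$replicates, ann_config))
  ann_out <- data.frame(
    feature_id = S4Vectors::mcols(ann$lncrnas)$feature_id,
    lnc_class = lnc_class, stringsAsFactors = FALSE)
  ann_out <- merge(ann_out, te, by = "feature_id")
  ann_out <- merge(ann_out,
                   acr_flags[, c("feature_id", "n_replicates_covered",
                                 "acr_lncrna")], by = "feature_id")
  .tsv(ann_out, file.path(outdir, "lncrna_annotation.tsv"))
  .tsv(data.frame(feature_id = S4Vectors::mcols(ann$clusters)$feature_id,
                  location = loc), file.path(outdir, "cluster_location.tsv"))
  write_intervals(merged_acrs, file.path(outdir, "acrs_merged.bed"),
                  format = "bed")

  say("patterns")
  pat <- stage("patterns", call_patterns(sim$expression))
  .tsv(pat$calls, file.path(outdir, "patterns.tsv"))
  .tsv(summarize_patterns(pat$calls), file.path(outdir, "patterns_summary.tsv"))

  say("dosage")
  dcalls <- stage("dosage", classify_dosage(dos$expression, mode = "replicate"))
  .tsv(dcalls, file.path(outdir, "dosage_calls.tsv"))
  .tsv(summarize_dosage(dcalls), file.path(outdir, "dosage_summary.tsv"))

  say("methylation")
  dmrs <- stage("methylation", call_dmrs(met$group1, met$group2, dmr_cfg))
  .tsv(dmrs, file.path(outdir, "dmrs.tsv"))

  say("integrate")
  cis <- stage("integrate", cis_pairs(ann$lncrnas, ann$genes, 5000L))
  .tsv(cis, file.path(outdir, "cis_pairs.tsv"))

  say("confusion matrices")
  conf <- list(
    pattern = .confusion(truth$planted_pattern,
                         pat$calls$pattern[match(truth$feature_id,
                                                 pat$calls$feature_id)]),
    dosage = .confusion(dos$truth$planted_dosage,
                        dcalls$label[match(dos$truth$feature_id,
                                           dcalls$feature_id)]),
    lnc_class = .confusion(
      truth$planted_lnc_class[truth$feature_class == "lncRNA"],
      lnc_class))
  for (nm in names(conf))
    .tsv(conf[[nm]], file.path(outdir, paste0("confusion_", nm, ".tsv")))

  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(.manifest_fields(config), cfg_path)
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("triadNC")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    thresholds = c(.manifest_fields(ann_config), .manifest_fields(dmr_cfg)))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(list(annotation = ann, expression = sim, dosage = dos,
                 methylation = met, acr = acr, patterns = pat,
                 dosage_calls = dcalls, dmrs = dmrs,
                 merged_acrs = merged_acrs, confusion = conf,
                 outdir = outdir))
}

.tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.confusion <- function(truth, call) {
  keep <- !is.na(truth)
  as.data.frame(table(truth = truth[keep], call = call[keep]),
                stringsAsFactors = FALSE)
}

.manifest_fields <- function(cfg) {
  lapply(unclass(cfg), function(v) if (is.null(names(v))) v else as.list(v))
}
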