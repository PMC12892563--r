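#' Simulate a parent/hybrid expression experiment with planted patterns
#'
#' Draws a counts matrix for maternal, paternal and hybrid generations
#' (`replicates` each) in which every feature carries one planted pattern:
#'
#' * `no-change`: all three generation means equal.
#' * `additive`: parents differ by `effect_log2fc` on the log2 scale and the
#'   hybrid mean is the mid-parent value.
#' * `ELD-M` / `ELD-P`: hybrid mean equals the maternal (paternal) mean while
#'   the parents differ by `effect_log2fc`.
#' * `transgressive-up` / `transgressive-down`: parents share a mean and the
#'   hybrid sits `effect_log2fc` above the higher (below the lower) parent.
#'
#' Counts are negative-binomial around per-sample expected values; library
#' sizes are drawn uniformly within `depth_jitter` of the target and
#' expected values are scaled by each sample's relative depth, so depth
#' normalization is required (and tested) downstream.
#'
#' @param truth data.frame with a `feature_id` column (typically the
#'   annotation truth); a planted pattern column is added to the returned
#'   truth. `n_features` synthetic ids are generated when `truth` is `NULL`.
#' @param config [sim_config()] object.
#' @param n_features number of features when `truth` is `NULL`.
#' @return list with `expression` (an [expression_matrix()] of counts) and
#'   `truth` (data.frame `feature_id`, `planted_pattern`).
#' @export
simulate_expression <- function(truth = NULL, config = sim_config(),
                                n_features = 300L) {
  set.seed(.stream_seed(config, "expression"))
  ids <- if (!is.null(truth)) as.character(truth$feature_id)
         else sprintf("feat%04d", seq_len(n_features))
  n <- length(ids)
  patterns <- c("no-change", "additive", "ELD-M", "ELD-P",
                "transgressive-up", "transgressive-down")
  planted <- rep(patterns, length.out = n)[sample.int(n)]
  base <- 2^runif(n, 4, 9)  # baseline mean counts, 16..512
  eff <- 2^config$effect_log2fc
  half <- 2^(config$effect_log2fc / 2)
  # random direction of the parental difference keeps expected library
  # composition equal across generations (no normalization bias)
  dir <- sample(c(-1, 1), n, replace = TRUE)
  m <- p <- h <- numeric(n)
  for (i in seq_len(n)) {
    hi <- base[i] * half; lo <- base[i] / half
    mm <- if (dir[i] > 0) lo else hi   # which parent is the high one
    pp <- if (dir[i] > 0) hi else lo
    switch(planted[i],
      "no-change" = { m[i] <- base[i]; p[i] <- base[i]; h[i] <- base[i] },
      "additive" = { m[i] <- mm; p[i] <- pp; h[i] <- (mm + pp) / 2 },
      "ELD-M" = { m[i] <- mm; p[i] <- pp; h[i] <- mm },
      "ELD-P" = { m[i] <- mm; p[i] <- pp; h[i] <- pp },
      "transgressive-up" = { m[i] <- base[i]; p[i] <- base[i]
                             h[i] <- base[i] * eff },
      "transgressive-down" = { m[i] <- base[i] * eff; p[i] <- base[i] * eff
                               h[i] <- base[i] })
  }
  mu <- cbind(matrix(rep(m, config$replicates), ncol = config$replicates),
              matrix(rep(p, config$replicates), ncol = config$replicates),
              matrix(rep(h, config$replicates), ncol = config$replicates))
  gens <- rep(c("maternal", "paternal", "hybrid"), each = config$replicates)
  reps <- rep(seq_len(config$replicates), times = 3)
  snames <- paste0(gens, "_r", reps)
  # per-sample depth factors around the target
  depth <- runif(ncol(mu), 1 - config$depth_jitter, 1 + config$depth_jitter)
  depth <- depth * ncol(mu) / sum(depth) # mean factor 1, keeps overall scale
  mu <- sweep(mu, 2, depth, "*")
  counts <- .draw_nb(mu, config$nb_dispersion)
  dimnames(counts) <- list(ids, snames)
  em <- expression_matrix(counts,
                          data.frame(sample = snames, generation = gens,
                                     replicate = reps,
                                     stringsAsFactors = FALSE),
                          unit = "count")
  list(expression = em,
       truth = data.frame(feature_id = ids, planted_pattern = planted,
                          stringsAsFactors = FALSE))
}

.draw_nb <- function(mu, dispersion) {
  out <- mu
  if (dispersion <= 0) {
    out[] <- round(mu)
  } else {
    out[] <- stats::rnbinom(length(mu), mu = as.vector(mu),
                            size = 1 / dispersion)
  }
  out
}

#' Simulate a ploidy-series (AACC / AAC / AA) dosage experiment
#'
#' Each feature belongs to one subgenome (A or C) and carries a planted
#' dosage label: `dd-positive` features have generation means proportional
#' to the subgenome's relative dosage vector (A: 1/2, 2/3, 1; C: 1/2, 1/3,
#' 0), `dd-negative` features have means affinely decreasing in dosage, and
#' `di` features have a dosage-unrelated constant mean. Multiplicative
#' log-normal noise (`dosage_noise_sd` on the log2 scale) is applied per
#' replicate. Values are emitted on a TPM-like continuous scale.
#'
#' @param config [sim_config()] object.
#' @param n_features number of simulated features.
#' @return list with `expression` (an [expression_matrix()], unit TPM, with
#'   per-feature `subgenome` tags) and `truth` (data.frame `feature_id`,
#'   `subgenome`, `planted_dosage`).
#' @export
simulate_dosage_series <- function(config = sim_config(), n_features = 200L) {
  set.seed(.stream_seed(config, "dosage"))
  n <- n_features
  ids <- sprintf("dfeat%04d", seq_len(n))
  sub <- rep(c("A", "C"), length.out = n)
  planted <- rep(c("dd-positive", "dd-negative", "di"), length.out = n)
  base <- 2^runif(n, 2, 6)
  gens <- c("maternal", "hybrid", "paternal")
  reps <- config$replicates
  mu <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    d <- dosage_design(sub[i])$dosage
    mu[i, ] <- switch(planted[i],
      "dd-positive" = base[i] * d,
      "dd-negative" = base[i] * (1.2 * max(d) - d),
      "di" = rep(base[i], 3))
  }
  vals <- matrix(0, n, 3 * reps)
  for (g in 1:3) for (r in seq_len(reps)) {
    col <- (g - 1) * reps + r
    noise <- 2^stats::rnorm(n, 0, config$dosage_noise_sd)
    vals[, col] <- mu[, g] * noise
  }
  snames <- paste0(rep(gens, each = reps), "_r", rep(seq_len(reps), 3))
  dimnames(vals) <- list(ids, snames)
  em <- expression_matrix(vals,
    data.frame(sample = snames,
               generation = rep(gens, each = reps),
               replicate = rep(seq_len(reps), 3),
               stringsAsFactors = FALSE),
    unit = "TPM",
    features = data.frame(feature_id = ids, subgenome = sub,
                          stringsAsFactors = FALSE))
  list(expression = em,
       truth = data.frame(feature_id = ids, subgenome = sub,
                          planted_dosage = planted,
                          stringsAsFactors = FALSE))
}
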