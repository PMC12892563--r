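mk_meth <- function(pos, meth, unmeth, context = "CG", strand = "+",
                    chrom = "chr1") {
  data.table::data.table(chrom = chrom, pos = as.integer(pos),
                         strand = strand, context = context,
                         meth = as.integer(meth),
                         unmeth = as.integer(unmeth))
}

test_that("weighted level is the count-weighted ratio over valid sites", {
  region <- mk_gr(100, 300, "+", "r1", "gene")
  # all reads methylated at every valid site
  dt <- mk_meth(c(120, 180, 250), c(10, 8, 30), c(0, 0, 0))
  expect_equal(weighted_level(dt, region, "CG")$level, 1)
  # sites below 5 reads are excluded; weighting is by counts, not site means
  dt2 <- mk_meth(c(120, 180, 250), c(2, 10, 0), c(1, 10, 40))
  # site 1 has depth 3 -> dropped; level = (10 + 0) / (20 + 40)
  wl <- weighted_level(dt2, region, "CG")
  expect_equal(wl$level, 10 / 60)
  expect_equal(wl$n_sites, 2L)
  # a region with no valid sites is missing, not zero
  none <- weighted_level(mk_meth(150, 1, 1), region, "CG")
  expect_true(is.na(none$level))
  expect_equal(none$n_sites, 0L)
  # contexts are separated
  mixed <- rbind(mk_meth(150, 10, 0, "CG"), mk_meth(160, 0, 10, "CHH"))
  expect_equal(weighted_level(mixed, region, "CHH")$level, 0)
})

test_that("weighted level equals a per-read tally on random regions", {
  set.seed(21)
  pos <- sort(sample(1:50000, 4000))
  dt <- mk_meth(pos, rbinom(4000, 25, 0.35), 0)
  dt$unmeth <- pmax(0L, 25L - dt$meth)
  dt$meth <- as.integer(dt$meth)
  starts <- sample(1:45000, 20)
  regions <- mk_gr(starts, starts + sample(500:4000, 20, TRUE), "+",
                   sprintf("r%02d", 1:20), "gene")
  wl <- weighted_level(dt, regions, "CG")
  for (i in seq_len(20)) {
    sel <- dt$pos >= GenomicRanges::start(regions)[i] &
      dt$pos <= GenomicRanges::end(regions)[i] &
      (dt$meth + dt$unmeth) >= 5
    want <- if (any(sel)) sum(dt$meth[sel]) / sum(dt$meth[sel] + dt$unmeth[sel])
            else NA_real_
    expect_equal(wl$level[i], want, tolerance = 1e-12)
  }
})

test_that("union-of-regions level is the count-weighted mean of the parts", {
  set.seed(22)
  pos <- sort(sample(1:20000, 2000))
  dt <- mk_meth(pos, rbinom(2000, 20, 0.3), 0)
  dt$unmeth <- 20L - dt$meth
  parts <- mk_gr(c(1000, 6000, 12000), c(3000, 9000, 15000), "+",
                 c("a", "b", "c"), "gene")
  whole <- mk_gr(1, 20000, "+", "w", "gene")
  wl_parts <- weighted_level(dt, parts, "CG")
  # reconstruct the union level from part-level numerators/denominators
  sel <- function(i) dt$pos >= GenomicRanges::start(parts)[i] &
    dt$pos <= GenomicRanges::end(parts)[i]
  num <- sum(sapply(1:3, function(i) sum(dt$meth[sel(i)])))
  den <- sum(sapply(1:3, function(i) sum(dt$meth[sel(i)] + dt$unmeth[sel(i)])))
  pooled <- num / den
  w <- sapply(1:3, function(i) sum(dt$meth[sel(i)] + dt$unmeth[sel(i)]))
  expect_equal(sum(wl_parts$level * w) / sum(w), pooled, tolerance = 1e-12)
})

test_that("metaprofile is flat under constant methylation and conserves counts", {
  set.seed(23)
  pos <- seq(5, 30000, by = 7)
  n <- length(pos)
  dt <- mk_meth(pos, rbinom(n, 20, 0.4), 0)
  dt$unmeth <- 20L - dt$meth
  regions <- mk_gr(c(5000, 15000), c(7000, 17500), c("+", "-"),
                   c("r1", "r2"), "gene")
  prof <- metaprofile(dt, regions, "CG")
  expect_equal(nrow(prof), 60)  # 20 + 20 + 20
  # constant-rate methylation: every bin close to the global rate
  expect_true(all(abs(prof$level - 0.4) < 0.12, na.rm = TRUE))
  # conservation: pooled profile counts equal the window tally
  total_m <- 0; total_t <- 0
  for (i in 1:2) {
    s <- GenomicRanges::start(regions)[i] - 2000
    e <- GenomicRanges::end(regions)[i] + 2000
    selw <- dt$pos >= s & dt$pos <= e
    total_m <- total_m + sum(dt$meth[selw])
    total_t <- total_t + sum(dt$meth[selw] + dt$unmeth[selw])
  }
  expect_equal(sum(prof$meth_reads), total_m)
  expect_equal(sum(prof$total_reads), total_t)
  # empty region set gives an empty profile
  expect_equal(nrow(metaprofile(dt, regions[0], "CG")), 0)
})

test_that("metaprofiles mirror when all strands flip", {
  set.seed(24)
  pos <- sort(sample(1:40000, 5000))
  dt <- mk_meth(pos, rbinom(5000, 30, runif(5000, 0.1, 0.9)), 0)
  dt$unmeth <- 30L - dt$meth
  plus <- mk_gr(18000, 21000, "+", "r1", "gene")
  minus <- mk_gr(18000, 21000, "-", "r1", "gene")
  p1 <- metaprofile(dt, plus, "CG")
  p2 <- metaprofile(dt, minus, "CG")
  expect_equal(p1$level, rev(p2$level))
  expect_equal(p1$meth_reads, rev(p2$meth_reads))
})

test_that("identical groups give zero DMRs", {
  set.seed(25)
  pos <- seq(10, 4000, by = 15)
  dt <- mk_meth(pos, rbinom(length(pos), 20, 0.3), 0)
  dt$unmeth <- 20L - dt$meth
  dmrs <- call_dmrs(dt, data.table::copy(dt))
  expect_gt(nrow(dmrs), 0)
  expect_equal(sum(dmrs$dmr), 0)
  expect_equal(unique(dmrs$delta), 0)
})

test_that("the context delta gate blocks significant but small differences", {
  # CHH bin with a tiny but highly significant shift: delta 0.05 < 0.1
  pos <- seq(10, 190, by = 4)  # 46 sites in one bin
  g1 <- mk_meth(pos, 100, 900, context = "CHH")
  g2 <- mk_meth(pos, 150, 850, context = "CHH")
  dmrs <- call_dmrs(g1, g2)
  expect_equal(nrow(dmrs), 1)
  expect_lt(dmrs$padj, 0.01)        # overwhelming counts: tiny p
  expect_lt(abs(dmrs$delta), 0.1)   # but below the CHH delta gate
  expect_false(dmrs$dmr)
  # the same shift in CG would also fail its larger 0.3 gate
  # a 0.5 shift in CG passes both gates
  g3 <- mk_meth(pos, 300, 700, context = "CG")
  g4 <- mk_meth(pos, 800, 200, context = "CG")
  d2 <- call_dmrs(g3, g4)
  expect_true(d2$dmr)
  expect_equal(d2$direction, "hyper")
})

test_that("bins need five valid cytosines in both groups to be tested", {
  pos <- c(10, 50, 90, 130, 170)  # exactly 5 sites in bin 1
  g1 <- mk_meth(pos, 10, 10)
  g2 <- mk_meth(pos, 10, 10)
  expect_equal(nrow(call_dmrs(g1, g2)), 1)
  # dropping one site below coverage 5 kills the bin
  g1b <- data.table::copy(g1); g1b$meth[1] <- 2L; g1b$unmeth[1] <- 2L
  expect_equal(nrow(call_dmrs(g1b, g2)), 0)
})

test_that("per-bin Fisher p-values match the hypergeometric-tail oracle", {
  set.seed(26)
  n_bins <- 200
  rows <- list()
  for (b in seq_len(n_bins)) {
    pos <- (b - 1) * 200 + seq(10, 190, by = 30)  # 7 sites per bin
    p1 <- runif(1, 0.05, 0.95)
    p2 <- if (b %% 3 == 0) runif(1, 0.05, 0.95) else p1
    rows[[2 * b - 1]] <- mk_meth(pos, rbinom(7, 20, p1), 0)
    rows[[2 * b - 1]]$unmeth <- 20L - rows[[2 * b - 1]]$meth
    rows[[2 * b]] <- mk_meth(pos, rbinom(7, 20, p2), 0)
    rows[[2 * b]]$unmeth <- 20L - rows[[2 * b]]$meth
  }
  g1 <- data.table::rbindlist(rows[seq(1, 2 * n_bins, 2)])
  g2 <- data.table::rbindlist(rows[seq(2, 2 * n_bins, 2)])
  dmrs <- call_dmrs(g1, g2)
  expect_equal(nrow(dmrs), n_bins)
  for (i in seq_len(nrow(dmrs))) {
    s1 <- g1$pos >= dmrs$bin_start[i] & g1$pos <= dmrs$bin_end[i]
    s2 <- g2$pos >= dmrs$bin_start[i] & g2$pos <= dmrs$bin_end[i]
    want <- bf_fisher_p(sum(g1$meth[s1]), sum(g1$unmeth[s1]),
                        sum(g2$meth[s2]), sum(g2$unmeth[s2]))
    expect_equal(dmrs$pvalue[i], want, tolerance = 1e-9)
  }
})

test_that("planted DMRs are recovered with direction at default settings", {
  cfg <- sim_config(seed = 31)
  met <- simulate_methylation(cfg, n_bins = 50)
  dmrs <- call_dmrs(met$group1, met$group2)
  key <- paste(dmrs$bin_start, dmrs$context)
  truth_key <- paste(met$truth$bin_start, met$truth$context)
  called <- dmrs$dmr[match(truth_key, key)]
  called[is.na(called)] <- FALSE
  tab <- table(planted = met$truth$planted_dmr, called = called)
  # every planted bin recovered, nothing else called
  expect_equal(sum(called & !met$truth$planted_dmr), 0)
  expect_gte(mean(called[met$truth$planted_dmr]), 0.95)
  # planted shifts are upward: direction hyper
  expect_true(all(dmrs$direction[dmrs$dmr] == "hyper"))
})

test_that("element-class comparison runs the rank test when classes differ", {
  set.seed(27)
  pos1 <- seq(10, 20000, by = 9)
  dt <- rbind(
    mk_meth(pos1, rbinom(length(pos1), 20, 0.7), 0),
    mk_meth(pos1 + 30000, rbinom(length(pos1), 20, 0.2), 0))
  dt$unmeth <- 20L - dt$meth
  hi_starts <- seq(100, 18000, by = 2000)
  lo_starts <- hi_starts + 30000
  classes <- list(
    hyper = mk_gr(hi_starts, hi_starts + 1500, "+",
                  sprintf("h%02d", seq_along(hi_starts)), "TE"),
    hypo = mk_gr(lo_starts, lo_starts + 1500, "+",
                 sprintf("l%02d", seq_along(lo_starts)), "gene"))
  res <- compare_element_methylation(classes, dt, contexts = "CG")
  expect_lt(res$tests$p, 0.01)
  lev <- tapply(res$levels$level, res$levels$class, mean, na.rm = TRUE)
  expect_gt(lev["hyper"], lev["hypo"])
  # a single class yields levels but no test
  res1 <- compare_element_methylation(classes["hyper"], dt, contexts = "CG")
  expect_equal(nrow(res1$tests), 0)
})
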