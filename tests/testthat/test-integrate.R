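test_that("cis pairs use an inclusive distance gate with overlaps at zero", {
  genes <- mk_gr(c(10000, 50000), c(12000, 52000), "+", c("g1", "g2"), "gene")
  # overlapping ncRNA: distance 0
  p0 <- cis_pairs(mk_gr(11000, 11500, "+", "n1", "lncRNA"), genes, 5000)
  expect_equal(p0$distance, 0L)
  expect_equal(p0$gene_id, "g1")
  # gap exactly 5000: emitted (inclusive "within")
  p1 <- cis_pairs(mk_gr(17001, 17400, "+", "n2", "lncRNA"), genes, 5000)
  expect_equal(p1$distance, 5000L)
  # gap 5001: not emitted
  p2 <- cis_pairs(mk_gr(17002, 17400, "+", "n3", "lncRNA"), genes, 5000)
  expect_equal(nrow(p2), 0)
  # all qualifying genes are emitted per ncRNA
  mid <- mk_gr(30000, 30500, "+", "n4", "lncRNA")
  genes_close <- mk_gr(c(26000, 32000), c(29000, 33000), "+",
                       c("ga", "gb"), "gene")
  expect_equal(sort(cis_pairs(mid, genes_close, 5000)$gene_id), c("ga", "gb"))
})

test_that("cis pairs agree with an all-pairs scan on random features", {
  set.seed(31)
  gs <- sample(seq(1, 3e5), 100)
  genes <- mk_gr(gs, gs + sample(500:3000, 100, TRUE), "+",
                 sprintf("g%03d", 1:100), "gene")
  ns <- sample(seq(1, 3e5), 200)
  ncr <- mk_gr(ns, ns + sample(100:1000, 200, TRUE), "+",
               sprintf("n%03d", 1:200), "lncRNA")
  got <- cis_pairs(ncr, genes, 2000)
  got_keys <- sort(paste(got$ncrna_id, got$gene_id))
  want_keys <- character(0)
  for (i in 1:200) for (j in 1:100) {
    g <- gap_bases(GenomicRanges::start(ncr)[i], GenomicRanges::end(ncr)[i],
                   GenomicRanges::start(genes)[j], GenomicRanges::end(genes)[j])
    if (g <= 2000) want_keys <- c(want_keys,
                                  paste(sprintf("n%03d", i), sprintf("g%03d", j)))
  }
  expect_equal(got_keys, sort(want_keys))
})

test_that("pair correlations hit the exact extremes and tally correctly", {
  v <- rbind(a = c(1, 2, 3, 4, 5, 6),
             b = c(2, 4, 6, 8, 10, 12),    # same order: r = 1 on log scale? no
             c = c(6, 5, 4, 3, 2, 1))
  # exact r = 1 needs identical log series
  v["b", ] <- v["a", ]
  em <- mk_em(v, rep(c("maternal", "paternal", "hybrid"), each = 2))
  pairs <- data.frame(ncrna_id = c("a", "a"), gene_id = c("b", "c"),
                      stringsAsFactors = FALSE)
  res <- correlate_pairs(pairs, em)
  expect_equal(res$pairs$r[1], 1)
  expect_lt(res$pairs$r[2], 0)
  expect_equal(res$summary$n_positive, 1)
  expect_equal(res$summary$n_negative, 1)
  # anti-ordered exact series on the log scale
  x <- 2^(1:6) - 1
  v2 <- rbind(u = x, d = rev(x))
  em2 <- mk_em(v2, rep(c("maternal", "paternal", "hybrid"), each = 2))
  r2 <- correlate_pairs(data.frame(ncrna_id = "u", gene_id = "d"), em2)
  expect_equal(r2$pairs$r, -1)
  # empty input
  r0 <- correlate_pairs(pairs[0, ], em)
  expect_equal(r0$summary$n_pairs, 0L)
})

test_that("trans co-expression applies the strict r-squared and distance gates", {
  # two identical expression rows: r = 1 -> r^2 = 1 > 0.81
  v <- rbind(lnc = c(1, 5, 2, 8, 3, 9), gene = c(1, 5, 2, 8, 3, 9),
             far = c(9, 1, 8, 2, 7, 3))
  em <- mk_em(v, rep(c("maternal", "paternal", "hybrid"), each = 2))
  lnc <- mk_gr(1000, 2000, "+", "lnc", "lncRNA")
  # same chromosome, 10 kb away: trans
  genes <- mk_gr(12001, 13000, "+", "gene", "gene")
  tp <- trans_coexpression(lnc, genes, em)
  expect_equal(nrow(tp), 1)
  expect_equal(tp$r_squared, 1)
  # 4 kb away: cis territory, dropped even with perfect correlation
  genes_cis <- mk_gr(6001, 7000, "+", "gene", "gene")
  expect_equal(nrow(trans_coexpression(lnc, genes_cis, em)), 0)
  # gap exactly 5000 fails the strict > 5 kb rule
  genes_edge <- mk_gr(7001, 8000, "+", "gene", "gene")
  expect_equal(nrow(trans_coexpression(lnc, genes_edge, em)), 0)
  # different chromosome qualifies regardless of coordinates
  genes_chr2 <- mk_gr(1000, 2000, "+", "gene", "gene", chrom = "chr2")
  em_all <- em
  tp2 <- trans_coexpression(lnc, genes_chr2, em_all)
  expect_equal(nrow(tp2), 1)
  expect_true(is.na(tp2$distance))
})

test_that("an r-squared of exactly the threshold is dropped", {
  # construct r^2 == 0.81 exactly: r = 0.9
  x <- c(-1, 0, 1)
  y <- 0.9 * x + sqrt(1 - 0.81) * c(1, -2, 1) / sqrt(6) * sqrt(2)
  # scale to positive expression and verify r
  r <- cor(x, y)
  expect_equal(r^2, 0.81, tolerance = 1e-9)
  v <- rbind(lnc = 2^x * 16, gene = 2^y * 16)
  em <- mk_em(v, c("maternal", "paternal", "hybrid"))
  lnc <- mk_gr(1000, 2000, "+", "lnc", "lncRNA")
  genes <- mk_gr(50000, 51000, "+", "gene", "gene")
  # log2(v+1) is not exactly linear in x/y, so check against the direct gate
  rr <- cor(log2(v["lnc", ] + 1), log2(v["gene", ] + 1))
  got <- trans_coexpression(lnc, genes, em)
  expect_equal(nrow(got), as.integer(rr^2 > 0.81))
})

test_that("signal profiles conserve mass and respect zones", {
  targets <- mk_gr(10000, 10999, "+", "t1", "gene")
  # signal wholly inside the upstream flank
  sig_up <- GenomicRanges::GRanges("chr1", IRanges::IRanges(8500, 8799))
  S4Vectors::mcols(sig_up)$weight <- 6
  prof <- signal_profile(targets, sig_up)
  expect_equal(sum(prof$weight), 6)
  expect_equal(sum(prof$weight[prof$zone != "upstream"]), 0)
  # uniform blanket signal: every flank bin gets an equal share
  blanket <- GenomicRanges::GRanges("chr1", IRanges::IRanges(8000, 13000))
  S4Vectors::mcols(blanket)$weight <- 50.01
  p2 <- signal_profile(targets, blanket)
  up <- p2$weight[p2$zone == "upstream"]
  expect_true(all(abs(up - up[1]) < 1e-9))
  # partial overlap is weighted proportionally
  partial <- GenomicRanges::GRanges("chr1", IRanges::IRanges(7990, 8009))
  S4Vectors::mcols(partial)$weight <- 10
  p3 <- signal_profile(targets, partial)
  expect_equal(sum(p3$weight), 10 * 10 / 20)  # half the interval in range
})

test_that("minus-strand targets mirror the signal profile", {
  set.seed(33)
  st <- sample(5000:15000, 40)
  sig <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st, st + 99))
  S4Vectors::mcols(sig)$weight <- runif(40, 1, 5)
  plus <- mk_gr(9000, 10999, "+", "t", "gene")
  minus <- mk_gr(9000, 10999, "-", "t", "gene")
  p1 <- signal_profile(plus, sig)
  p2 <- signal_profile(minus, sig)
  expect_equal(p1$weight, rev(p2$weight), tolerance = 1e-9)
})

test_that("fuzzy c-means satisfies its algebraic contract", {
  set.seed(9)
  x <- matrix(rnorm(120), 20, 6)
  # c = 1: all memberships are 1
  f1 <- fuzzy_cmeans(x, c = 1, seed = 2)
  expect_equal(unname(f1$membership[, 1]), rep(1, 20))
  fc <- fuzzy_cmeans(x, c = 3, seed = 2)
  expect_equal(unname(rowSums(fc$membership)), rep(1, 20), tolerance = 1e-9)
  expect_true(all(fc$membership >= 0 & fc$membership <= 1))
  expect_true(all(diff(fc$objective) <= 1e-8))
  # deterministic under the seed
  fc2 <- fuzzy_cmeans(x, c = 3, seed = 2)
  expect_identical(fc$membership, fc2$membership)
  expect_error(fuzzy_cmeans(x, c = 21), "more clusters")
})

test_that("well-separated groups are recovered and match the e1071 optimum", {
  skip_if_not_installed("e1071")
  set.seed(10)
  g1 <- matrix(rnorm(40 * 6, rep(c(0, 0, 0, 4, 4, 4), each = 40), 0.4), 40, 6)
  g2 <- matrix(rnorm(40 * 6, rep(c(4, 4, 4, 0, 0, 0), each = 40), 0.4), 40, 6)
  x <- rbind(g1, g2)
  rownames(x) <- sprintf("f%02d", 1:80)
  fc <- fuzzy_cmeans(x, c = 2, seed = 3)
  grp <- rep(1:2, each = 40)
  agree <- max(mean(fc$cluster == grp), mean(fc$cluster == 3 - grp))
  expect_gte(agree, 0.95)
  # cross-check the solution against e1071's fuzzy c-means on the same data
  xs <- t(apply(x, 1, function(r) (r - mean(r)) / sd(r)))
  ref <- e1071::cmeans(xs, centers = 2, m = 2, iter.max = 200)
  ref_agree <- max(mean((ref$cluster == grp)), mean((ref$cluster == 3 - grp)))
  expect_equal(agree, ref_agree)
  # final objectives agree at the shared optimum
  d2 <- as.matrix(dist(rbind(fc$centers, ref$centers)))^2
  expect_lt(min(d2[1, 3:4]), 0.05)
})

test_that("miRNA target summaries count signed correlations", {
  v <- rbind(mir = 2^(1:6), t1 = 2^(6:1), t2 = 2^(1:6))
  em <- mk_em(v, rep(c("maternal", "paternal", "hybrid"), each = 2))
  tab <- data.frame(mirna_id = c("mir", "mir"), gene_id = c("t1", "t2"),
                    stringsAsFactors = FALSE)
  res <- mirna_target_summary(tab, em)
  expect_equal(res$summary$n_negative, 1)
  expect_equal(res$summary$n_positive, 1)
  empty <- mirna_target_summary(tab[0, ], em)
  expect_equal(empty$summary$n_pairs, 0L)
})
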