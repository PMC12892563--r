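mk_candidates <- function(...) {
  base <- data.frame(feature_id = "c1", length = 500L, class_code = "u",
                     noncoding_cnci = TRUE, noncoding_cpc = TRUE,
                     noncoding_plek = TRUE, has_protein_domain = FALSE,
                     max_tpm = 2.0, stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

test_that("lncRNA candidate filter applies each rule with strict boundaries", {
  expect_true(filter_lncrna_candidates(mk_candidates())$retained)
  # length exactly 200 nt fails the strictly-longer-than rule
  r <- filter_lncrna_candidates(mk_candidates(length = 200L))
  expect_false(r$retained); expect_equal(r$reason, "length")
  expect_true(filter_lncrna_candidates(mk_candidates(length = 201L))$retained)
  # max TPM below the floor
  r <- filter_lncrna_candidates(mk_candidates(max_tpm = 0.4))
  expect_equal(r$reason, "expression_floor")
  expect_true(filter_lncrna_candidates(mk_candidates(max_tpm = 0.5))$retained)
  # class code outside i/u/o/x
  r <- filter_lncrna_candidates(mk_candidates(class_code = "="))
  expect_equal(r$reason, "class_code")
  # any coding verdict kills it
  r <- filter_lncrna_candidates(mk_candidates(noncoding_plek = FALSE))
  expect_equal(r$reason, "coding_potential")
  r <- filter_lncrna_candidates(mk_candidates(has_protein_domain = TRUE))
  expect_equal(r$reason, "protein_domain")
  # the first failing rule is the one reported
  r <- filter_lncrna_candidates(mk_candidates(class_code = "=", length = 10L))
  expect_equal(r$reason, "class_code")
  # a missing verdict is an error, never a silent pass
  expect_error(filter_lncrna_candidates(mk_candidates(noncoding_cpc = NA)),
               "missing")
})

test_that("lncRNA locus classes follow the definitions and priority", {
  genes <- mk_gr(1000, 4000, "+", "g1", "gene")
  exons <- mk_gr(c(1000, 2200, 3400), c(1600, 2800, 4000), "+",
                 c("g1.e1", "g1.e2", "g1.e3"), "exon",
                 parent_id = rep("g1", 3))
  cases <- list(
    list(gr = mk_gr(1100, 1500, "-", "x1", "lncRNA"), want = "AS-lncRNA"),
    list(gr = mk_gr(1700, 2100, "+", "x2", "lncRNA"), want = "intronic"),
    list(gr = mk_gr(2500, 3600, "+", "x3", "lncRNA"), want = "sense"),
    list(gr = mk_gr(14000, 14500, "+", "x4", "lncRNA"), want = "lincRNA"),
    list(gr = mk_gr(1100, 1500, "*", "x5", "lncRNA"),
         want = "overlapping-unstranded"),
    list(gr = mk_gr(20000, 20400, "*", "x6", "lncRNA"), want = "lincRNA"))
  for (cs in cases)
    expect_equal(classify_lncrna_locus(cs$gr, genes, exons), cs$want)
})

test_that("random locus classification matches the brute-force oracle", {
  set.seed(101)
  for (rep_ in 1:5) {
    n_genes <- 40
    gs <- sort(sample(seq(1000, 4e5, by = 100), n_genes))
    genes <- mk_gr(gs, gs + 2999, rep(c("+", "-"), length.out = n_genes),
                   sprintf("g%02d", 1:n_genes), "gene")
    exons <- mk_gr(c(rbind(gs, gs + 1200, gs + 2400)),
                   c(rbind(gs + 599, gs + 1799, gs + 2999)),
                   rep(rep(c("+", "-"), length.out = n_genes), each = 3),
                   sprintf("e%03d", 1:(3 * n_genes)), "exon",
                   parent_id = rep(sprintf("g%02d", 1:n_genes), each = 3))
    ls <- sample(seq(1, 4.2e5), 200)
    lnc <- mk_gr(ls, ls + sample(100:2000, 200, TRUE),
                 sample(c("+", "-"), 200, TRUE),
                 sprintf("l%03d", 1:200), "lncRNA")
    expect_equal(classify_lncrna_locus(lnc, genes, exons),
                 bf_lnc_class(lnc, genes, exons))
  }
})

test_that("genic/proximal/distal respects the strict 2 kb boundary", {
  genes <- mk_gr(10000, 12000, "+", "g1", "gene")
  # 1 bp overlap is genic
  expect_equal(categorize_location(mk_gr(12000, 12500), genes), "genic")
  # gap of exactly 2000 is distal (strict <)
  expect_equal(categorize_location(mk_gr(14001, 14500), genes), "distal")
  # gap of 1999 is proximal
  expect_equal(categorize_location(mk_gr(14000, 14500), genes), "proximal")
  # empty gene set: everything distal
  expect_equal(categorize_location(mk_gr(1, 10), genes[0]), "distal")
})

test_that("location categories match the brute-force scan on random data", {
  set.seed(202)
  gs <- sort(sample(seq(1000, 8e5, 50), 60))
  genes <- mk_gr(gs, gs + sample(500:3000, 60, TRUE), "+",
                 sprintf("g%02d", 1:60), "gene")
  fs <- sample(seq(1, 8.1e5), 500)
  feats <- mk_gr(fs, fs + sample(50:400, 500, TRUE), "*",
                 sprintf("f%03d", 1:500), "siRNA_cluster")
  expect_equal(categorize_location(feats, genes), bf_location(feats, genes))
})

test_that("TE association reports the largest overlap with positional ties", {
  tes <- mk_gr(c(100, 260), c(210, 500), "*", c("te1", "te2"), "TE",
               superfamily = c("DNA/MuDR", "LTR/Gypsy"))
  # overlaps te1 by 30 bp and te2 by 81 bp -> LTR wins
  f <- mk_gr(181, 340, "+", "x", "lncRNA")
  res <- te_association(f, tes)
  expect_true(res$te_associated)
  expect_equal(res$te_superfamily, "LTR/Gypsy")
  # no TEs at all
  res0 <- te_association(f, tes[0])
  expect_false(res0$te_associated)
  # equal overlaps: first genomic position wins
  tes2 <- mk_gr(c(500, 100), c(599, 199), "*", c("b", "a"), "TE",
                superfamily = c("late", "early"))
  f2 <- mk_gr(100, 599, "+", "y", "lncRNA")
  expect_equal(te_association(f2, tes2)$te_superfamily, "early")
})

test_that("TE association equals the quadratic oracle on random features", {
  set.seed(303)
  ts <- sample(seq(1, 2e5), 80)
  tes <- mk_gr(ts, ts + sample(200:1500, 80, TRUE), "*",
               sprintf("te%02d", 1:80), "TE",
               superfamily = sample(c("LTR/Gypsy", "LTR/Copia", "DNA/MuDR"),
                                    80, TRUE))
  fs <- sample(seq(1, 2e5), 300)
  feats <- mk_gr(fs, fs + sample(100:800, 300, TRUE), "+",
                 sprintf("f%03d", 1:300), "lncRNA")
  got <- te_association(feats, tes)
  want <- bf_te(feats, tes)
  expect_equal(got$te_associated, want$te_associated)
  expect_equal(got$te_superfamily, want$te_superfamily)
})

test_that("replicate ACR merge requires overlap strictly above 50 bp", {
  cfg <- annotation_config()
  # exactly 50 bp of overlap: not merged
  r1 <- mk_gr(1000, 1500, "*", "p1", "ACR")
  r2 <- mk_gr(1451, 1900, "*", "p2", "ACR")
  expect_length(merge_replicate_acrs(list(r1, r2), cfg), 0)
  # 51 bp: merged, output is the union of the contributing peaks
  r2b <- mk_gr(1450, 1900, "*", "p2", "ACR")
  m <- merge_replicate_acrs(list(r1, r2b), cfg)
  expect_length(m, 1)
  expect_equal(GenomicRanges::start(m), 1000)
  expect_equal(GenomicRanges::end(m), 1900)
  # identical replicate sets reproduce the input peaks
  peaks <- mk_gr(c(100, 5000, 9000), c(600, 5800, 9400), "*",
                 c("a", "b", "c"), "ACR")
  mm <- merge_replicate_acrs(list(peaks, peaks, peaks), cfg)
  expect_equal(GenomicRanges::ranges(mm), GenomicRanges::ranges(peaks))
  # fewer than two replicate sets is an error
  expect_error(merge_replicate_acrs(list(peaks), cfg), "2 replicate")
})

test_that("ACR-lncRNA coverage uses a strict one-half from the lncRNA side", {
  cfg <- annotation_config()
  lnc <- mk_gr(1000, 1999, "+", "l1", "lncRNA")  # 1000 bp
  # exactly half covered in every replicate: not flagged
  half <- mk_gr(1000, 1499, "*", "a1", "ACR")
  res <- call_acr_lncrna(lnc, list(half, half, half), cfg)
  expect_equal(res$coverage_rep1, 0.5)
  expect_false(res$acr_lncrna)
  # 501 bp covered in two replicates: flagged
  more <- mk_gr(1000, 1500, "*", "a1", "ACR")
  res2 <- call_acr_lncrna(lnc, list(more, more, half), cfg)
  expect_true(res2$acr_lncrna)
  expect_equal(res2$n_replicates_covered, 2L)
  # fully contained lncRNA in all replicates: flagged
  big <- mk_gr(500, 2500, "*", "a1", "ACR")
  expect_true(call_acr_lncrna(lnc, list(big, big), cfg)$acr_lncrna)
})

test_that("ACR coverage fractions equal a per-base tally on random cases", {
  set.seed(404)
  for (rep_ in 1:4) {
    ls <- sample(seq(1000, 50000), 25)
    lnc <- mk_gr(ls, ls + sample(200:1500, 25, TRUE), "+",
                 sprintf("l%02d", 1:25), "lncRNA")
    ps <- sample(seq(1, 52000), 40)
    peaks <- mk_gr(ps, ps + sample(100:900, 40, TRUE), "*",
                   sprintf("p%02d", 1:40), "ACR")
    res <- call_acr_lncrna(lnc, list(peaks), annotation_config())
    red <- GenomicRanges::reduce(peaks, ignore.strand = TRUE)
    want <- vapply(seq_along(lnc), function(i)
      bf_coverage(GenomicRanges::start(lnc)[i], GenomicRanges::end(lnc)[i],
                  red), numeric(1))
    expect_equal(res$coverage_rep1, want, tolerance = 1e-12)
  }
})

test_that("novel ACR-lncRNA gates are strict on both sides", {
  flags <- data.frame(feature_id = c("l1", "l2", "l3", "l4"),
                      acr_lncrna = c(TRUE, TRUE, TRUE, FALSE),
                      stringsAsFactors = FALSE)
  v <- rbind(l1 = c(0.05, 0.02, 0.6), l2 = c(0.05, 0.02, 0.5),
             l3 = c(0.10, 0.02, 0.9), l4 = c(0.0, 0.0, 3.0))
  em <- mk_em(v, c("maternal", "paternal", "hybrid"))
  res <- call_novel_acr_lncrna(flags, em)
  expect_true(res$novel_acr_lncrna[1])   # 0.6 > 0.5, parents < 0.1
  expect_false(res$novel_acr_lncrna[2])  # hybrid exactly 0.5
  expect_false(res$novel_acr_lncrna[3])  # maternal exactly 0.1
  expect_false(res$novel_acr_lncrna[4])  # not an ACR-lncRNA at all
})

test_that("activated/silenced phasiRNA rules use strict read thresholds", {
  h <- c(5, 1, 0, 0, 2, 0)
  m <- c(0, 0, 3, 1, 0, 0)
  p <- c(0, 0, 2, 3, 1, 0)
  want <- c("activated",  # hybrid > 1, parents 0
            "neither",    # hybrid exactly 1 fails the strict > 1
            "silenced",   # hybrid 0, both parents > 1
            "neither",    # one parent at exactly 1
            "neither",    # parent expressed
            "neither")
  expect_equal(call_activated_silenced(h, m, p), want)
})

test_that("constitutive flag equals the row-minimum rule on a random matrix", {
  set.seed(505)
  v <- matrix(round(stats::rexp(9000, 1), 3), 1000, 9)
  rownames(v) <- sprintf("f%04d", 1:1000)
  em <- mk_em(v, rep(c("maternal", "paternal", "hybrid"), each = 3))
  flag <- constitutive_flag(em, floor_tpm = 0.5)
  expect_equal(unname(flag), unname(apply(v, 1, min) > 0.5))
  # one sample at exactly the floor fails
  v2 <- matrix(c(0.6, 0.5, 0.9), 1, 3, dimnames = list("x", NULL))
  em2 <- mk_em(v2, c("maternal", "paternal", "hybrid"))
  expect_false(unname(constitutive_flag(em2)))
})
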