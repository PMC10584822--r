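# Window binning, the window filter, Fisher/BH machinery, DMR calling,
# feature annotation, density differences and DMR-set overlap.

mk_sites <- function(pos, n_meth, n_unmeth, context = "CG", chrom = "c",
                     strand = "+") {
  data.table::data.table(chrom = chrom, pos = as.integer(pos),
                         strand = strand, context = context,
                         trinucleotide = "CGA",
                         n_meth = as.integer(n_meth),
                         n_unmeth = as.integer(n_unmeth))
}

test_that("windows land on the fixed genomic grid", {
  s <- mk_sites(c(50L, 51L, 100L), c(1L, 2L, 3L), c(1L, 0L, 1L))
  w <- bin_windows(s)
  # 1-based positions 51 and 100 both fall inside [50, 100)
  expect_equal(w$start, c(0L, 50L))
  expect_equal(w[start == 50L, n_sites], 2L)
  expect_equal(w[start == 50L, n_meth], 5L)
  expect_equal(w[start == 50L, min_site_depth], 2L)
  expect_equal(nrow(bin_windows(s[0])), 0L)
})

test_that("window pooling matches a brute-force tally on simulated data", {
  cfg <- small_config()
  sim <- simulate_cross(cfg, samples = "egg")
  sites <- extract_cytosine_counts(sim$reads$egg[[1]], sim$genomes$maternal)
  w <- bin_windows(sites)
  df <- as.data.frame(sites)
  df$ws <- ((df$pos - 1) %/% 50) * 50
  tal <- aggregate(cbind(n_meth, n_unmeth) ~ chrom + ws + context, df, sum)
  key_w <- paste(w$chrom, w$start, w$context)
  key_t <- paste(tal$chrom, tal$ws, tal$context)
  expect_setequal(key_w, key_t)
  expect_equal(w$n_meth[match(key_t, key_w)], tal$n_meth)
  expect_equal(w$n_unmeth[match(key_t, key_w)], tal$n_unmeth)
})

test_that("window filter requires 5 cytosines each at 3x in both samples", {
  w4 <- bin_windows(mk_sites(1:4, rep(5L, 4), rep(5L, 4)))
  w5 <- bin_windows(mk_sites(1:5, rep(5L, 5), rep(5L, 5)))
  w5lo <- bin_windows(mk_sites(1:5, c(5L, 5L, 5L, 5L, 1L),
                               c(5L, 5L, 5L, 5L, 1L)))
  # 4 cytosines: removed
  expect_equal(nrow(filter_windows(pair_windows(w4, w4))), 0L)
  # 5 cytosines, one at depth 2: removed
  expect_equal(nrow(filter_windows(pair_windows(w5lo, w5lo))), 0L)
  # 5 cytosines all at depth >= 3 in both samples: retained
  expect_equal(nrow(filter_windows(pair_windows(w5, w5))), 1L)
  # failing in only one sample also removes the window
  expect_equal(nrow(filter_windows(pair_windows(w5, w5lo))), 0L)
})

test_that("Fisher p-values are exact on canonical tables", {
  expect_equal(fisher_exact_2x2(5L, 5L, 5L, 5L), 1.0)
  # [[10,0],[0,10]]: 2 / choose(20, 10)
  expect_equal(fisher_exact_2x2(10L, 0L, 0L, 10L), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(0L, 0L, 0L, 0L), 1.0)
  expect_equal(fisher_exact_2x2(0L, 5L, 0L, 7L), 1.0)
})

test_that("Fisher p-values agree with stats::fisher.test on random tables", {
  set.seed(99)
  tab <- matrix(sample(0:40, 4 * 200, replace = TRUE), ncol = 4)
  mine <- fisher_exact_2x2(tab[, 1], tab[, 2], tab[, 3], tab[, 4])
  ref <- apply(tab, 1, function(r) {
    stats::fisher.test(matrix(r, 2, byrow = TRUE))$p.value
  })
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("BH adjustment matches the definitional step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("every emitted DMR satisfies its context cutoff and the FDR rule", {
  cfg <- small_config(seed = 43L)
  sim <- simulate_cross(cfg, samples = c("egg", "sperm"))
  egg <- pooled_sites(sim, "egg", sim$genomes$maternal)
  sperm <- pooled_sites(sim, "sperm", sim$genomes$maternal)
  dmrs <- call_dmrs(egg, sperm)
  expect_gt(nrow(dmrs), 0)
  tau <- c(CG = 0.5, CHG = 0.3, CHH = 0.1)
  expect_true(all(abs(dmrs$delta) > tau[dmrs$context]))
  expect_true(all(dmrs$fdr < 0.05))
  expect_true(all(dmrs$direction == ifelse(dmrs$delta > 0, "hyper", "hypo")))
  expect_true(all(dmrs$m1 >= 0 & dmrs$m1 <= 1 & dmrs$m2 >= 0 & dmrs$m2 <= 1))
  # a CG window below the 0.5 cutoff is never a DMR however small its p
  s1 <- mk_sites(1:10, rep(9L, 10), rep(11L, 10))   # level 0.45
  s2 <- mk_sites(1:10, rep(0L, 10), rep(20L, 10))   # level 0, delta 0.45
  expect_equal(nrow(call_dmrs(s1, s2)), 0L)
})

test_that("DMR calling is symmetric up to direction swap", {
  cfg <- small_config(seed = 47L)
  sim <- simulate_cross(cfg, samples = c("egg", "sperm"))
  egg <- pooled_sites(sim, "egg", sim$genomes$maternal)
  sperm <- pooled_sites(sim, "sperm", sim$genomes$maternal)
  ab <- call_dmrs(egg, sperm)
  ba <- call_dmrs(sperm, egg)
  expect_equal(nrow(ab), nrow(ba))
  key <- function(d) paste(d$chrom, d$start, d$context)
  expect_setequal(key(ab), key(ba))
  m <- match(key(ab), key(ba))
  expect_equal(ab$delta, -ba$delta[m])
  expect_equal(ab$p_value, ba$p_value[m], tolerance = 1e-12)
  swapped <- ifelse(ba$direction[m] == "hyper", "hypo", "hyper")
  expect_identical(ab$direction, swapped)
})

test_that("feature annotation follows the TE_gene > TE > gene_body precedence", {
  dmrs <- data.table::data.table(
    chrom = "c", start = c(0L, 100L, 200L, 300L), end = c(50L, 150L, 250L,
                                                          350L),
    context = "CG")
  genes <- data.table::data.table(chrom = "c", start = c(0L, 200L),
                                  end = c(60L, 260L))
  tes <- data.table::data.table(chrom = "c", start = c(100L, 210L),
                                end = c(160L, 240L))
  ann <- annotate_dmrs(dmrs, genes, tes)
  expect_equal(ann$feature_class,
               c("gene_body", "TE", "TE_gene", "intergenic"))
})

test_that("feature annotation matches a brute-force overlap oracle", {
  set.seed(11)
  dmrs <- data.table::data.table(
    chrom = "c", start = sample(0:2000, 300) * 1L)
  dmrs[, end := start + 50L]
  dmrs[, context := "CG"]
  genes <- data.table::data.table(chrom = "c",
                                  start = sample(0:2000, 30) * 1L)
  genes[, end := start + sample(20:400, 30, replace = TRUE)]
  tes <- data.table::data.table(chrom = "c", start = sample(0:2000, 30) * 1L)
  tes[, end := start + sample(20:200, 30, replace = TRUE)]
  ann <- annotate_dmrs(dmrs, genes, tes)
  brute <- vapply(seq_len(nrow(dmrs)), function(i) {
    s <- dmrs$start[i]; e <- dmrs$end[i]
    ing <- any(genes$start < e & genes$end > s)
    int <- any(tes$start < e & tes$end > s)
    if (int && ing) "TE_gene" else if (int) "TE" else if (ing) "gene_body"
    else "intergenic"
  }, character(1))
  expect_identical(ann$feature_class, brute)
})

test_that("density differences apply informativeness and ratio filters", {
  # bin [0,50): total depth 19 in sample 1 -> excluded
  s_19 <- mk_sites(1:5, c(4L, 4L, 4L, 4L, 2L), c(0L, 0L, 0L, 0L, 1L))
  s_hi <- mk_sites(1:5, rep(8L, 5), rep(0L, 5))
  d <- density_difference(s_19, s_hi, "CG")
  expect_equal(nrow(d$bins), 0L)
  # CG bin with levels 0.4 and 0.3: neither reaches 0.5 -> excluded
  s_40 <- mk_sites(1:5, rep(4L, 5), rep(6L, 5))
  s_30 <- mk_sites(1:5, rep(3L, 5), rep(7L, 5))
  expect_equal(nrow(density_difference(s_40, s_30, "CG")$bins), 0L)
  # the same levels pass the laxer CHH threshold
  s_40h <- mk_sites(1:5, rep(4L, 5), rep(6L, 5), context = "CHH")
  s_30h <- mk_sites(1:5, rep(3L, 5), rep(7L, 5), context = "CHH")
  expect_equal(nrow(density_difference(s_40h, s_30h, "CHH")$bins), 1L)
  # identical samples yield exactly zero differences
  d0 <- density_difference(s_hi, s_hi, "CG")
  expect_equal(d0$bins$delta, 0)
  expect_equal(sum(d0$freq$frequency), 1)
  # bin level is the average of per-cytosine levels
  s_mix <- mk_sites(1:5, c(10L, 0L, 10L, 0L, 10L), c(0L, 10L, 0L, 10L, 0L))
  dm <- density_difference(s_mix, s_hi, "CG")
  expect_equal(dm$bins$m1, 0.6)
})

test_that("DMR-set overlap counts match a brute-force pairwise oracle", {
  mk_set <- function(starts, context = "CG") {
    data.table::data.table(chrom = "c", start = as.integer(starts),
                           end = as.integer(starts) + 50L, context = context)
  }
  a <- mk_set(c(0, 100, 200))
  expect_equal(overlap_dmr_sets(a, a)$fraction_shared, 1)
  b <- mk_set(c(1000, 2000))
  expect_equal(overlap_dmr_sets(a, b)$n_shared, 0L)
  expect_equal(overlap_dmr_sets(a, b)$fraction_shared, 0)
  # contexts must match for sharing
  expect_equal(overlap_dmr_sets(a, mk_set(0, "CHH"))$n_shared, 0L)
  set.seed(21)
  ra <- mk_set(sample(0:500, 40) * 10)
  rb <- mk_set(sample(0:500, 40) * 10)
  got <- overlap_dmr_sets(ra, rb)
  brute_a <- sum(vapply(seq_len(nrow(ra)), function(i) {
    any(rb$start < ra$end[i] & rb$end > ra$start[i])
  }, logical(1)))
  brute_b <- sum(vapply(seq_len(nrow(rb)), function(i) {
    any(ra$start < rb$end[i] & ra$end > rb$start[i])
  }, logical(1)))
  expect_equal(got$n_shared, brute_a)
  expect_equal(got$n_b_only, nrow(rb) - brute_b)
})

test_that("merging adjacent DMRs concatenates book-ended windows", {
  d <- data.table::data.table(
    chrom = "c", start = c(0L, 50L, 150L), end = c(50L, 100L, 200L),
    context = "CG", direction = "hyper")
  m <- merge_adjacent_dmrs(d)
  expect_equal(nrow(m), 2L)
  expect_equal(m$end[1] - m$start[1], 100L)
  expect_equal(m$n_windows, c(2L, 1L))
})
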