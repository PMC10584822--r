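# The synthetic hybrid-cross generator: determinism, limiting cases,
# truth consistency and the remodeling rule.

test_that("identical configurations reproduce identical outputs", {
  cfg <- small_config()
  a <- simulate_cross(cfg, samples = c("egg", "zygote"))
  b <- simulate_cross(cfg, samples = c("egg", "zygote"))
  expect_identical(a$genomes$maternal, b$genomes$maternal)
  expect_identical(a$genomes$paternal, b$genomes$paternal)
  expect_identical(a$genomes$snps, b$genomes$snps)
  expect_identical(as.data.frame(a$truth$cytosines),
                   as.data.frame(b$truth$cytosines))
  expect_identical(as.data.frame(a$reads$zygote[[2]]$calls),
                   as.data.frame(b$reads$zygote[[2]]$calls))
  e1 <- generate_allelic_expression_counts(200L, cfg)
  e2 <- generate_allelic_expression_counts(200L, cfg)
  expect_identical(e1, e2)
})

test_that("zero SNP rate yields identical haplotypes and an empty SNP table", {
  cfg <- sim_config(genome_length = 5000L, snp_rate = 0,
                    n_planted_dmrs = c(CG = 2L, CHG = 0L, CHH = 0L),
                    seed = 3L)
  g <- simulate_parental_genomes(cfg)
  expect_identical(g$maternal, g$paternal)
  expect_equal(nrow(g$snps), 0L)
})

test_that("paternal genome differs from maternal exactly at SNP positions", {
  cfg <- small_config()
  g <- simulate_parental_genomes(cfg)
  m <- strsplit(g$maternal[[1]], "")[[1]]
  p <- strsplit(g$paternal[[1]], "")[[1]]
  diff_pos <- which(m != p)
  expect_identical(diff_pos, g$snps$pos)
  expect_identical(m[diff_pos], g$snps$maternal_base)
  expect_identical(p[diff_pos], g$snps$paternal_base)
  # ambiguity flag marks exactly the transition pairs
  is_ti <- with(g$snps, (maternal_base %in% c("C", "T") &
                           paternal_base %in% c("C", "T")) |
                  (maternal_base %in% c("G", "A") &
                     paternal_base %in% c("G", "A")))
  expect_identical(g$snps$bisulfite_ambiguous, is_ti)
})

test_that("empty annotation makes every site intergenic", {
  cfg <- sim_config(genome_length = 5000L, te_fraction = 0, gene_fraction = 0,
                    n_planted_dmrs = c(CG = 2L, CHG = 0L, CHH = 0L), seed = 5L)
  g <- simulate_parental_genomes(cfg)
  expect_equal(nrow(g$annotation), 0L)
  tr <- simulate_methylomes(g, cfg)
  expect_true(all(tr$cytosines$compartment == "intergenic"))
})

test_that("planted DMRs respect effect size, grid and context cytosine minimum", {
  cfg <- small_config()
  sim <- simulate_cross(cfg, samples = character(0))
  pd <- sim$truth$planted_dmrs
  expect_equal(nrow(pd), 15L)
  expect_true(all(abs(pd$m_egg - pd$m_sperm) >= cfg$planted_effect - 1e-9))
  expect_true(all(pd$start %% 50L == 0L))
  cyt <- sim$truth$cytosines
  for (i in seq_len(nrow(pd))) {
    inw <- cyt[chrom == pd$chrom[i] & pos > pd$start[i] & pos <= pd$end[i] &
                 context == pd$context[i]]
    expect_gte(nrow(inw), 5L)
    expect_true(all(inw$m_egg == pd$m_egg[i]))
    expect_true(all(inw$m_sperm == pd$m_sperm[i]))
  }
})

test_that("the remodeling rule hits its limits: rho 0, 1 and midpoint", {
  base <- list(genome_length = 20000L,
               n_planted_dmrs = c(CG = 5L, CHG = 5L, CHH = 0L), seed = 11L)
  for (r in c(0, 0.5, 1)) {
    cfg <- do.call(sim_config, c(base, list(rho = r)))
    g <- simulate_parental_genomes(cfg)
    tr <- simulate_methylomes(g, cfg)
    cg <- tr$cytosines[context %in% c("CG", "CHG")]
    expect_equal(cg$m_zygote_pat, r * cg$m_egg + (1 - r) * cg$m_sperm,
                 tolerance = 1e-12)
    expect_equal(cg$m_zygote_mat, cg$m_egg)
    # globular embryo reverts to gamete-of-origin levels
    expect_equal(cg$m_ge_pat, cg$m_sperm)
    expect_equal(cg$m_ge_mat, cg$m_egg)
  }
  # explicit midpoint: rho = 0.5 with egg 0.9 / sperm 0.1 gives 0.5
  cfg <- do.call(sim_config, c(base, list(rho = 0.5)))
  tr <- simulate_methylomes(simulate_parental_genomes(cfg), cfg)
  pd <- tr$planted_dmrs[context == "CG"][1]
  at <- tr$cytosines[chrom == pd$chrom & pos > pd$start & pos <= pd$end &
                       context == "CG"]
  expect_equal(unique(at$m_zygote_pat), 0.5, tolerance = 1e-12)
})

test_that("CHH zygote levels follow the lower parent under the default rule", {
  cfg <- sim_config(genome_length = 20000L,
                    n_planted_dmrs = c(CG = 0L, CHG = 0L, CHH = 8L),
                    chh_rule = "lower_parent", seed = 13L)
  tr <- simulate_methylomes(simulate_parental_genomes(cfg), cfg)
  chh <- tr$cytosines[context == "CHH"]
  expect_equal(chh$m_zygote_pat, pmin(chh$m_egg, chh$m_sperm))
  expect_equal(chh$m_zygote_mat, pmin(chh$m_egg, chh$m_sperm))
})

test_that("observed methylation converges to truth with conversion-failure floor", {
  # all-unmethylated genome at high depth: unconverted fraction ~ failure rate
  cfg <- sim_config(genome_length = 2000L, snp_rate = 0,
                    n_planted_dmrs = c(CG = 0L, CHG = 0L, CHH = 0L),
                    meth_baseline = list(
                      CG = c(gene = 0, TE = 0, intergenic = 0),
                      CHG = c(gene = 0, TE = 0, intergenic = 0),
                      CHH = c(gene = 0, TE = 0, intergenic = 0)),
                    baseline_concentration = 1e6,
                    conversion_failure = 0.01, depth = 500, seed = 17L)
  g <- simulate_parental_genomes(cfg)
  tr <- simulate_methylomes(g, cfg)
  rd <- generate_bisulfite_reads(tr, g, cfg, "egg", 1)
  n_calls <- nrow(rd$calls)
  frac <- mean(rd$calls$meth)
  se <- sqrt(0.01 * 0.99 / n_calls)
  expect_lt(abs(frac - 0.01), 3 * se + 1e-6)
  # and a fully methylated site reports all-unconverted without failure noise
  cfg2 <- sim_config(genome_length = 1000L, snp_rate = 0,
                     n_planted_dmrs = c(CG = 0L, CHG = 0L, CHH = 0L),
                     meth_baseline = list(
                       CG = c(gene = 1, TE = 1, intergenic = 1),
                       CHG = c(gene = 1, TE = 1, intergenic = 1),
                       CHH = c(gene = 1, TE = 1, intergenic = 1)),
                     baseline_concentration = 1e6,
                     conversion_failure = 0, depth = 20, seed = 19L)
  g2 <- simulate_parental_genomes(cfg2)
  tr2 <- simulate_methylomes(g2, cfg2)
  rd2 <- generate_bisulfite_reads(tr2, g2, cfg2, "egg", 1)
  expect_true(all(rd2$calls$meth))
})

test_that("read SNP bases equal the allele-of-origin base at non-cytosine SNPs", {
  cfg <- small_config(convert_snp_bases = FALSE)
  sim <- simulate_cross(cfg, samples = "zygote")
  rd <- sim$reads$zygote[[1]]
  obs <- merge(rd$snp_obs, sim$genomes$snps, by = c("chrom", "pos"))
  obs <- merge(obs, rd$reads[, .(read_id, allele)], by = "read_id")
  expected <- ifelse(obs$allele == "maternal", obs$maternal_base,
                     obs$paternal_base)
  expect_identical(obs$base, expected)
})

test_that("zero depth produces an empty, valid read collection", {
  cfg <- small_config()
  sim <- simulate_cross(cfg, samples = character(0))
  rd <- generate_bisulfite_reads(sim$truth, sim$genomes, cfg, "egg",
                                 depth = 0)
  expect_equal(n_reads(rd), 0L)
  expect_equal(nrow(rd$calls), 0L)
})

test_that("too many planted DMRs for the genome is a sizing error", {
  expect_error(sim_config(genome_length = 1000L,
                          n_planted_dmrs = c(CG = 50L, CHG = 0L, CHH = 0L)),
               "too small")
})

test_that("expression counts respect imprinting truth and background fraction", {
  cfg <- small_config()
  ex <- generate_allelic_expression_counts(500L, cfg)
  tr <- ex$truth
  for (cross in list(ex$cross1, ex$cross2)) {
    pegs <- cross[gene %in% tr$pegs]
    frac_pat <- sum(pegs$paternal_count) /
      sum(pegs$maternal_count + pegs$paternal_count)
    expect_gte(frac_pat, 0.95)
    megs <- cross[gene %in% tr$megs]
    frac_mat <- sum(megs$maternal_count) /
      sum(megs$maternal_count + megs$paternal_count)
    expect_gte(frac_mat, 0.95)
    bg <- cross[!gene %in% c(tr$pegs, tr$megs, tr$seq_specific)]
    f <- sum(bg$maternal_count) / sum(bg$maternal_count + bg$paternal_count)
    expect_lt(abs(f - 0.5), 0.02)
  }
})

test_that("bisulfite read simulation conserves coverage bookkeeping", {
  cfg <- small_config()
  sim <- simulate_cross(cfg, samples = "egg")
  rd <- sim$reads$egg[[1]]
  # every call lies inside its read interval on the read's strand
  j <- merge(rd$calls, rd$reads, by = c("read_id", "chrom"),
             suffixes = c("", ".r"))
  expect_true(all(j$pos >= j$start & j$pos <= j$end))
  expect_true(all(j$strand == j$strand.r))
  # per-site coverage equals the number of covering same-strand reads of
  # valid context (extraction conservation, checked in aggregate)
  sites <- extract_cytosine_counts(rd, sim$genomes$maternal)
  expect_equal(sum(sites$n_meth + sites$n_unmeth), nrow(rd$calls))
})
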