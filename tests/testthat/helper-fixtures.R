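# Shared fixtures: small seeded simulations and hand-built read objects.

small_config <- function(...) {
  args <- list(...)
  defaults <- list(genome_length = 20000L, snp_rate = 0.01, depth = 30,
                   n_planted_dmrs = c(CG = 5L, CHG = 5L, CHH = 5L),
                   seed = 101L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# a bisreads object built by hand: reads described as list(chrom, start,
# end, strand, calls = data.frame(pos, meth), snps = data.frame(pos, base))
manual_bisreads <- function(reads) {
  rd <- rbindlist(lapply(seq_along(reads), function(i) {
    r <- reads[[i]]
    data.table::data.table(read_id = i, chrom = r$chrom, start = r$start,
                           end = r$end, strand = r$strand)
  }))
  calls <- rbindlist(lapply(seq_along(reads), function(i) {
    r <- reads[[i]]
    if (is.null(r$calls) || !nrow(r$calls)) return(NULL)
    data.table::data.table(read_id = i, chrom = r$chrom, pos = r$calls$pos,
                           strand = r$strand, meth = r$calls$meth)
  }))
  snp_obs <- rbindlist(lapply(seq_along(reads), function(i) {
    r <- reads[[i]]
    if (is.null(r$snps) || !nrow(r$snps)) return(NULL)
    data.table::data.table(read_id = i, chrom = r$chrom, pos = r$snps$pos,
                           base = r$snps$base)
  }))
  empty_calls <- data.table::data.table(read_id = integer(0),
                                        chrom = character(0),
                                        pos = integer(0),
                                        strand = character(0),
                                        meth = logical(0))
  empty_snps <- data.table::data.table(read_id = integer(0),
                                       chrom = character(0),
                                       pos = integer(0), base = character(0))
  bisreads(rd,
           if (nrow(calls)) calls else empty_calls,
           if (nrow(snp_obs)) snp_obs else empty_snps)
}

rbindlist <- data.table::rbindlist

# pooled, coverage-filtered cytosine counts for one simulated sample
pooled_sites <- function(sim, sample, reference, min_depth = 3L) {
  filter_coverage(
    pool_replicates(lapply(sim$reads[[sample]], extract_cytosine_counts,
                           reference = reference)),
    min_depth)
}

# independent brute-force Fisher two-sided p via direct binomial-coefficient
# enumeration (never dhyper)
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (n == 0 || c1 == 0 || c1 == n) return(1)
  ks <- max(0, c1 - r2):min(c1, r1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  probs <- exp(logp)
  p_obs <- probs[ks == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# definitional BH step-up oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
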