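# Seeded generator for every input the pipeline consumes: two parental
# haplotypes differing at SNPs, gene/TE annotation, per-cytosine cell-type
# methylomes with plantable egg-sperm DMRs and a parametric zygotic
# remodeling rule, simplified aligned bisulfite reads, and allelic
# expression counts for reciprocal crosses.

#' Configuration for the synthetic hybrid-cross generator
#'
#' Collects and validates every tunable of the simulator. Defaults emulate
#' a toy-scale rice-like setting: SNP density comparable to an indica
#' intervarietal cross (~3.5 variants/kb, roughly two thirds of them
#' transitions and therefore bisulfite-ambiguous), TE-rich heavily
#' methylated compartments, CG > CHG > CHH methylation ordering, two
#' biological replicates per cell type, and full paternal remodeling
#' toward the maternal level in the zygote (`rho = 1`) with the CHH
#' context following the lower parent.
#'
#' @param genome_length bases per chromosome.
#' @param n_chromosomes number of chromosomes.
#' @param snp_rate per-base probability of a biallelic SNP between the
#'   parental genomes.
#' @param ambiguous_snp_fraction fraction of SNPs drawn as transitions
#'   (C/T or G/A allele pairs), which bisulfite conversion renders
#'   strand-specifically uninformative.
#' @param te_fraction,gene_fraction approximate fractions of the genome
#'   covered by transposable-element and gene annotations; their sum must
#'   not exceed 1.
#' @param gene_length,te_length lengths (bases) of simulated gene blocks
#'   and TE insertions.
#' @param meth_baseline named list with elements `CG`, `CHG`, `CHH`, each
#'   a numeric vector `c(gene=, TE=, intergenic=)` of mean methylation
#'   levels per compartment.
#' @param baseline_concentration Beta concentration of per-cytosine true
#'   levels around the compartment mean (larger = tighter).
#' @param n_planted_dmrs named integer vector `c(CG=, CHG=, CHH=)`: number
#'   of egg-sperm DMRs planted per context on the 50-bp grid.
#' @param planted_effect egg-sperm methylation difference at planted DMRs.
#' @param rho remodeling coefficient in `[0, 1]`: the fraction by which
#'   the paternal allele's zygotic CG/CHG methylation moves from the sperm
#'   level toward the egg level (`m_pat = rho * m_egg + (1 - rho) * m_sperm`).
#' @param chh_rule `"lower_parent"` (zygotic CHH follows
#'   `min(m_egg, m_sperm)` on both alleles) or `"rho_mix"` (CHH treated
#'   like CG/CHG).
#' @param read_length,depth read length (bases) and mean per-base coverage
#'   per sample replicate.
#' @param conversion_failure probability that an unmethylated cytosine
#'   escapes bisulfite conversion and reads as methylated.
#' @param convert_snp_bases if `TRUE` (default), read bases recorded at
#'   SNPs undergo bisulfite conversion when the allele base is a cytosine
#'   on the read's strand, reproducing why transition SNPs are unusable.
#' @param n_replicates biological replicates per cell type.
#' @param maternal_fraction background maternal read fraction for allelic
#'   expression counts.
#' @param expr_mean,expr_dispersion negative-binomial mean and size of
#'   per-gene total allelic counts.
#' @param n_pegs,n_megs,n_seq_specific numbers of planted paternally
#'   expressed, maternally expressed, and genotype-biased genes.
#' @param imprint_purity allelic purity of planted imprinted genes (PEGs
#'   draw this fraction of paternal reads in both crosses; MEGs mirror).
#' @param seed integer RNG seed; identical configurations reproduce
#'   byte-identical outputs.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 100000L,
                       n_chromosomes = 1L,
                       snp_rate = 0.0035,
                       ambiguous_snp_fraction = 2 / 3,
                       te_fraction = 0.35,
                       gene_fraction = 0.30,
                       gene_length = 2000L,
                       te_length = 400L,
                       meth_baseline = list(
                         CG  = c(gene = 0.55, TE = 0.90, intergenic = 0.40),
                         CHG = c(gene = 0.25, TE = 0.65, intergenic = 0.25),
                         CHH = c(gene = 0.05, TE = 0.12, intergenic = 0.05)
                       ),
                       baseline_concentration = 20,
                       n_planted_dmrs = c(CG = 50L, CHG = 50L, CHH = 50L),
                       planted_effect = 0.8,
                       rho = 1,
                       chh_rule = c("lower_parent", "rho_mix"),
                       read_length = 100L,
                       depth = 30,
                       conversion_failure = 0.005,
                       convert_snp_bases = TRUE,
                       n_replicates = 2L,
                       maternal_fraction = 0.5,
                       expr_mean = 200,
                       expr_dispersion = 5,
                       n_pegs = 20L,
                       n_megs = 50L,
                       n_seq_specific = 10L,
                       imprint_purity = 0.97,
                       seed = 1L) {
  chh_rule <- match.arg(chh_rule)
  cfg <- list(
    genome_length = as.integer(genome_length),
    n_chromosomes = as.integer(n_chromosomes),
    snp_rate = snp_rate,
    ambiguous_snp_fraction = ambiguous_snp_fraction,
    te_fraction = te_fraction,
    gene_fraction = gene_fraction,
    gene_length = as.integer(gene_length),
    te_length = as.integer(te_length),
    meth_baseline = meth_baseline,
    baseline_concentration = baseline_concentration,
    n_planted_dmrs = n_planted_dmrs,
    planted_effect = planted_effect,
    rho = rho,
    chh_rule = chh_rule,
    read_length = as.integer(read_length),
    depth = depth,
    conversion_failure = conversion_failure,
    convert_snp_bases = isTRUE(convert_snp_bases),
    n_replicates = as.integer(n_replicates),
    maternal_fraction = maternal_fraction,
    expr_mean = expr_mean,
    expr_dispersion = expr_dispersion,
    n_pegs = as.integer(n_pegs),
    n_megs = as.integer(n_megs),
    n_seq_specific = as.integer(n_seq_specific),
    imprint_purity = imprint_purity,
    seed = as.integer(seed)
  )
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  .check_prob(cfg$snp_rate, "snp_rate")
  .check_prob(cfg$ambiguous_snp_fraction, "ambiguous_snp_fraction")
  .check_prob(cfg$te_fraction, "te_fraction")
  .check_prob(cfg$gene_fraction, "gene_fraction")
  .check_prob(cfg$planted_effect, "planted_effect")
  .check_prob(cfg$rho, "rho")
  .check_prob(cfg$conversion_failure, "conversion_failure")
  .check_prob(cfg$maternal_fraction, "maternal_fraction")
  .check_prob(cfg$imprint_purity, "imprint_purity")
  if (cfg$te_fraction + cfg$gene_fraction > 1) {
    stop("te_fraction + gene_fraction must not exceed 1")
  }
  if (cfg$depth < 0) stop("depth must be non-negative")
  if (cfg$genome_length < 3L) stop("genome_length too small")
  if (cfg$read_length < 1L) stop("read_length must be positive")
  if (cfg$n_replicates < 1L) stop("n_replicates must be >= 1")
  baselines <- unlist(cfg$meth_baseline)
  .check_prob(baselines, "meth_baseline")
  if (!all(c("CG", "CHG", "CHH") %in% names(cfg$meth_baseline))) {
    stop("meth_baseline must name CG, CHG and CHH")
  }
  # coarse sizing check: planted DMRs occupy distinct 50-bp grid windows
  need <- sum(cfg$n_planted_dmrs)
  have <- (cfg$genome_length %/% 50L) * cfg$n_chromosomes
  if (need > have %/% 2L) {
    stop(sprintf(
      "genome_length too small to place %d planted DMRs (only %d grid windows)",
      need, have))
  }
  invisible(cfg)
}

#' Simulate two parental haplotypes, their SNP table and annotation
#'
#' Draws a random maternal genome, derives the paternal genome by
#' substituting bases at Bernoulli-placed SNPs, and lays down
#' non-overlapping gene blocks plus uniformly placed TE insertions (which
#' may fall inside genes, yielding TE-gene regions). A configured fraction
#' of SNPs are transitions, flagged `bisulfite_ambiguous` because a C/T
#' (or, mirrored on the other strand, G/A) pair cannot be distinguished
#' from bisulfite conversion on the affected strand.
#'
#' @param config a [sim_config()].
#' @return list of class `parental_genomes` with elements `maternal` and
#'   `paternal` (named character vectors of chromosome sequences), `snps`
#'   (`data.table`: `chrom`, `pos` 1-based, `maternal_base`,
#'   `paternal_base`, `bisulfite_ambiguous`), and `annotation`
#'   (`data.table`: `chrom`, `start`, `end` 0-based half-open, `feature`
#'   in `gene`/`TE`).
#' @export
simulate_parental_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    chroms <- sprintf("chr%02d", seq_len(config$n_chromosomes))
    L <- config$genome_length
    maternal <- list(); paternal <- list()
    snps <- list(); annot <- list()
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    for (ch in chroms) {
      b <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      # genes: non-overlapping blocks on a fixed partition
      glen <- min(config$gene_length, max(50L, L %/% 10L))
      n_blocks <- L %/% glen
      gene_blocks <- integer(0)
      if (n_blocks > 0L && config$gene_fraction > 0) {
        gene_blocks <- which(stats::runif(n_blocks) < config$gene_fraction)
      }
      genes <- if (length(gene_blocks)) {
        data.table(chrom = ch, start = (gene_blocks - 1L) * glen,
                   end = gene_blocks * glen, feature = "gene")
      } else NULL
      # TEs: uniform placements, overlaps with genes allowed
      n_te <- round(config$te_fraction * L / config$te_length)
      tes <- if (n_te > 0L && L > config$te_length) {
        ts <- sort(sample.int(L - config$te_length, n_te, replace = TRUE)) - 1L
        data.table(chrom = ch, start = ts, end = ts + config$te_length,
                   feature = "TE")
      } else NULL
      annot[[ch]] <- rbindlist(list(genes, tes))
      # SNPs
      is_snp <- stats::runif(L) < config$snp_rate
      spos <- which(is_snp)
      mb <- b[spos]
      pb <- character(length(spos))
      if (length(spos)) {
        is_ti <- stats::runif(length(spos)) < config$ambiguous_snp_fraction
        pb[is_ti] <- unname(transition[mb[is_ti]])
        if (any(!is_ti)) {
          # transversion: one of the two non-transition alternatives
          tv <- lapply(mb[!is_ti], function(x) {
            setdiff(c("A", "C", "G", "T"), c(x, transition[[x]]))
          })
          pick <- stats::runif(sum(!is_ti)) < 0.5
          pb[!is_ti] <- mapply(function(alt, first) if (first) alt[1] else alt[2],
                               tv, pick)
        }
      }
      p <- b
      p[spos] <- pb
      maternal[[ch]] <- paste(b, collapse = "")
      paternal[[ch]] <- paste(p, collapse = "")
      amb <- (mb %in% c("C", "T") & pb %in% c("C", "T")) |
        (mb %in% c("G", "A") & pb %in% c("G", "A"))
      snps[[ch]] <- data.table(chrom = ch, pos = spos,
                               maternal_base = mb, paternal_base = pb,
                               bisulfite_ambiguous = amb)
    }
    snp_dt <- rbindlist(snps)
    setorder(snp_dt, chrom, pos)
    ann_dt <- rbindlist(annot)
    if (nrow(ann_dt)) setorder(ann_dt, chrom, start)
    structure(list(
      maternal = unlist(maternal),
      paternal = unlist(paternal),
      snps = snp_dt,
      annotation = ann_dt
    ), class = "parental_genomes")
  })
}

# compartment of each position given the annotation: TE beats gene beats
# intergenic (TE methylation dominates even inside genes)
.site_compartment <- function(sites, annotation) {
  comp <- rep("intergenic", nrow(sites))
  if (!is.null(annotation) && nrow(annotation)) {
    for (feat in c("gene", "TE")) {
      iv <- annotation[feature == feat]
      if (!nrow(iv)) next
      hits <- .overlaps_any(sites$chrom, sites$pos - 1L, sites$pos, iv)
      comp[hits] <- feat
    }
  }
  comp
}

# any-overlap of 0-based half-open queries against an interval table
.overlaps_any <- function(chrom, start, end, intervals) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  s <- GenomicRanges::GRanges(intervals$chrom,
                              IRanges::IRanges(intervals$start + 1L,
                                               intervals$end))
  IRanges::overlapsAny(q, s)
}

#' Simulate true cell-type methylomes under a zygotic remodeling rule
#'
#' Draws a true methylation level for every reference cytosine from a Beta
#' distribution around its compartment/context baseline (shared between
#' egg and sperm outside planted DMRs), plants the requested number of
#' egg-sperm DMRs on the 50-bp grid (half hyper, half hypo, with the
#' configured effect size, each window compartment-pure and containing at
#' least five cytosines of its context), and derives the zygote and
#' globular-embryo allelic levels: the maternal allele keeps the egg
#' level, the paternal allele's CG/CHG level moves toward the egg level by
#' `rho`, zygotic CHH follows the lower parent under the default rule, and
#' globular-embryo alleles revert to their gamete-of-origin levels.
#'
#' @param genomes output of [simulate_parental_genomes()].
#' @param config the same [sim_config()].
#' @return list of class `truth_set` with `cytosines` (per-site truth
#'   incl. `m_egg`, `m_sperm`, `m_zygote_mat`, `m_zygote_pat`, `m_ge_mat`,
#'   `m_ge_pat`, `compartment`, `pat_is_c`) and `planted_dmrs`
#'   (`chrom`, `start`, `end`, `context`, `direction`, `m_egg`, `m_sperm`).
#' @export
simulate_methylomes <- function(genomes, config) {
  stopifnot(inherits(genomes, "parental_genomes"),
            inherits(config, "sim_config"))
  .with_seed(config$seed + 1L, {
    sites <- cytosine_sites(genomes$maternal)
    sites[, compartment := .site_compartment(sites, genomes$annotation)]
    # does the paternal allele carry a cytosine at this site/strand?
    pat_chars <- lapply(genomes$paternal,
                        function(s) strsplit(s, "", fixed = TRUE)[[1]])
    pb <- character(nrow(sites))
    for (ch in names(pat_chars)) {
      sel <- sites$chrom == ch
      pb[sel] <- pat_chars[[ch]][sites$pos[sel]]
    }
    sites[, pat_is_c := (strand == "+" & pb == "C") |
            (strand == "-" & pb == "G")]

    base_mean <- mapply(function(cx, cp) config$meth_baseline[[cx]][[cp]],
                        sites$context, sites$compartment)
    k <- config$baseline_concentration
    a <- pmax(base_mean * k, 1e-3)
    bshape <- pmax((1 - base_mean) * k, 1e-3)
    lv <- stats::rbeta(nrow(sites), a, bshape)
    sites[, m_egg := lv]
    sites[, m_sperm := lv]

    # plant egg-sperm DMRs on the fixed 50-bp grid
    sites[, window_start := ((pos - 1L) %/% 50L) * 50L]
    win <- sites[, .(n = .N, pure = data.table::uniqueN(compartment) == 1L),
                 by = .(chrom, window_start, context)]
    eligible <- win[n >= 5L & pure == TRUE]
    planted <- list()
    used <- character(0)
    half <- config$planted_effect / 2
    lo <- max(0.5 - half, 0.02); hi <- min(0.5 + half, 0.98)
    for (cx in c("CG", "CHG", "CHH")) {
      n_want <- config$n_planted_dmrs[[cx]]
      if (is.na(n_want) || n_want < 1L) next
      pool <- eligible[context == cx &
                         !(paste(chrom, window_start) %in% used)]
      if (nrow(pool) < n_want) {
        stop(sprintf(
          "genome too small: only %d eligible %s windows for %d planted DMRs",
          nrow(pool), cx, n_want))
      }
      pick <- pool[sample.int(nrow(pool), n_want)]
      used <- c(used, paste(pick$chrom, pick$window_start))
      hyper <- rep_len(c(TRUE, FALSE), n_want)  # hyper: egg > sperm
      pick[, direction := fifelse(hyper, "hyper", "hypo")]
      pick[, m_egg := fifelse(hyper, hi, lo)]
      pick[, m_sperm := fifelse(hyper, lo, hi)]
      sites[pick, on = c("chrom", "window_start", "context"),
            c("m_egg", "m_sperm") := list(i.m_egg, i.m_sperm)]
      planted[[cx]] <- pick[, .(chrom, start = window_start,
                                end = window_start + 50L, context,
                                direction, m_egg, m_sperm)]
    }
    sites[, window_start := NULL]

    # zygote: maternal allele keeps egg level; paternal CG/CHG moves toward
    # the egg level by rho; CHH follows the lower parent by default
    sites[, m_zygote_mat := m_egg]
    sites[, m_zygote_pat := config$rho * m_egg + (1 - config$rho) * m_sperm]
    if (config$chh_rule == "lower_parent") {
      sites[context == "CHH",
            c("m_zygote_mat", "m_zygote_pat") :=
              list(pmin(m_egg, m_sperm), pmin(m_egg, m_sperm))]
    }
    # globular embryo: parental allelic levels reestablished
    sites[, m_ge_mat := m_egg]
    sites[, m_ge_pat := m_sperm]

    planted_dt <- rbindlist(planted)
    if (nrow(planted_dt)) setorder(planted_dt, chrom, start, context)
    structure(list(cytosines = sites[], planted_dmrs = planted_dt,
                   config = config),
              class = "truth_set")
  })
}

# truth level columns per sample/allele
.truth_level_col <- function(sample, allele) {
  switch(sample,
    egg = "m_egg",
    sperm = "m_sperm",
    zygote = if (allele == "maternal") "m_zygote_mat" else "m_zygote_pat",
    globular_embryo = if (allele == "maternal") "m_ge_mat" else "m_ge_pat",
    stop("unknown sample: ", sample)
  )
}

#' Generate simplified aligned bisulfite reads for one sample replicate
#'
#' Reads are emitted as already-aligned fragments (alignment itself is not
#' modeled): each read has an interval on the maternal-backbone reference,
#' a strand, a hidden allele of origin (egg reads are purely maternal,
#' sperm purely paternal, zygote and globular-embryo reads half and half),
#' a conversion call at every covered cytosine of its strand that exists
#' on its allele (Bernoulli at the true level, with unmethylated cytosines
#' escaping conversion at rate `conversion_failure`), and the observed
#' base at every covered SNP. When `convert_snp_bases` is on, a SNP base
#' that is a cytosine on the read's strand is itself subject to bisulfite
#' conversion, which is what makes transition SNPs strand-specifically
#' uninformative.
#'
#' @param truth a [simulate_methylomes()] truth set.
#' @param genomes the matching [simulate_parental_genomes()] output.
#' @param config the [sim_config()].
#' @param sample_name one of `"egg"`, `"sperm"`, `"zygote"`,
#'   `"globular_embryo"`.
#' @param replicate replicate index (seeds are derived per sample and
#'   replicate, so replicates are independent but reproducible).
#' @param depth mean per-base coverage; defaults to `config$depth`.
#' @return a [bisreads] object; `reads$allele` records the hidden truth.
#' @export
generate_bisulfite_reads <- function(truth, genomes, config,
                                     sample_name = c("egg", "sperm", "zygote",
                                                     "globular_embryo"),
                                     replicate = 1L,
                                     depth = config$depth) {
  sample_name <- match.arg(sample_name)
  stopifnot(inherits(truth, "truth_set"), inherits(genomes, "parental_genomes"))
  offset <- match(sample_name,
                  c("egg", "sperm", "zygote", "globular_embryo")) * 101L
  .with_seed(config$seed + 1000L * offset + replicate, {
    sizes <- .chrom_sizes(genomes$maternal)
    rl <- config$read_length
    cyt <- truth$cytosines
    reads_l <- list(); calls_l <- list(); snp_l <- list()
    next_id <- 0L
    for (ch in names(sizes)) {
      L <- sizes[[ch]]
      n_reads <- stats::rpois(1L, depth * L / rl)
      if (n_reads == 0L || L < rl) next
      start <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
      rd <- data.table(
        read_id = next_id + seq_len(n_reads),
        chrom = ch, start = start, end = start + rl - 1L,
        strand = sample(c("+", "-"), n_reads, replace = TRUE),
        allele = switch(sample_name,
          egg = rep("maternal", n_reads),
          sperm = rep("paternal", n_reads),
          sample(c("maternal", "paternal"), n_reads, replace = TRUE))
      )
      next_id <- next_id + n_reads
      ct <- cyt[chrom == ch]
      if (nrow(ct)) {
        lo <- findInterval(rd$start - 1L, ct$pos) + 1L
        hi <- findInterval(rd$end, ct$pos)
        n_cov <- pmax(hi - lo + 1L, 0L)
        if (sum(n_cov) > 0L) {
          ridx <- rep(seq_len(nrow(rd)), n_cov)
          sidx <- sequence(n_cov, from = pmax(lo, 1L))
          keep <- ct$strand[sidx] == rd$strand[ridx] &
            (rd$allele[ridx] == "maternal" | ct$pat_is_c[sidx])
          ridx <- ridx[keep]; sidx <- sidx[keep]
          lv_mat <- ct[[.truth_level_col(sample_name, "maternal")]][sidx]
          lv_pat <- ct[[.truth_level_col(sample_name, "paternal")]][sidx]
          lv <- fifelse(rd$allele[ridx] == "maternal", lv_mat, lv_pat)
          p_obs <- lv + (1 - lv) * config$conversion_failure
          calls_l[[ch]] <- data.table(
            read_id = rd$read_id[ridx], chrom = ch,
            pos = ct$pos[sidx], strand = ct$strand[sidx],
            meth = stats::runif(length(ridx)) < p_obs)
        }
      }
      sn <- genomes$snps[chrom == ch]
      if (nrow(sn)) {
        lo <- findInterval(rd$start - 1L, sn$pos) + 1L
        hi <- findInterval(rd$end, sn$pos)
        n_cov <- pmax(hi - lo + 1L, 0L)
        if (sum(n_cov) > 0L) {
          ridx <- rep(seq_len(nrow(rd)), n_cov)
          sidx <- sequence(n_cov, from = pmax(lo, 1L))
          ob <- fifelse(rd$allele[ridx] == "maternal",
                        sn$maternal_base[sidx], sn$paternal_base[sidx])
          if (config$convert_snp_bases) {
            # a C on a plus-strand read (or G on minus) is itself subject
            # to conversion: methylated with the truth-set probability when
            # the site exists for the allele, else essentially unmethylated
            conv_target <- (rd$strand[ridx] == "+" & ob == "C") |
              (rd$strand[ridx] == "-" & ob == "G")
            if (any(conv_target)) {
              sub <- which(conv_target)
              key <- data.table(chrom = ch, pos = sn$pos[sidx[sub]],
                                strand = rd$strand[ridx[sub]])
              idx <- cyt[key, on = c("chrom", "pos", "strand"), which = TRUE]
              mcol <- .truth_level_col(sample_name, "maternal")
              pcol <- .truth_level_col(sample_name, "paternal")
              lv <- fifelse(rd$allele[ridx[sub]] == "maternal",
                            cyt[[mcol]][idx], cyt[[pcol]][idx])
              lv[is.na(lv)] <- 0
              pat_c <- cyt$pat_is_c[idx]
              lv[rd$allele[ridx[sub]] == "paternal" &
                   (is.na(pat_c) | !pat_c)] <- 0
              p_obs <- lv + (1 - lv) * config$conversion_failure
              converted <- stats::runif(length(sub)) >= p_obs
              ob[sub][converted & ob[sub] == "C"] <- "T"
              ob[sub][converted & ob[sub] == "G"] <- "A"
            }
          }
          snp_l[[ch]] <- data.table(read_id = rd$read_id[ridx], chrom = ch,
                                    pos = sn$pos[sidx], base = ob)
        }
      }
      reads_l[[ch]] <- rd
    }
    reads <- rbindlist(reads_l)
    if (!length(reads_l)) {
      reads <- data.table(read_id = integer(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), allele = character(0))
    }
    if (nrow(reads)) {
      data.table::set(reads, j = "sample_name", value = sample_name)
      data.table::set(reads, j = "rep_id", value = as.integer(replicate))
    }
    bisreads(
      reads = reads,
      calls = if (length(calls_l)) rbindlist(calls_l) else
        data.table(read_id = integer(0), chrom = character(0),
                   pos = integer(0), strand = character(0), meth = logical(0)),
      snp_obs = if (length(snp_l)) rbindlist(snp_l) else
        data.table(read_id = integer(0), chrom = character(0),
                   pos = integer(0), base = character(0))
    )
  })
}

#' Generate allelic expression count tables for reciprocal crosses
#'
#' Gene totals are negative-binomially dispersed; background genes split
#' reads maternally at the configured global fraction, planted PEGs draw
#' almost exclusively paternal reads in both reciprocal crosses (MEGs the
#' mirror), and genotype-biased ("sequence-specific") genes favor the same
#' genomic parent regardless of its parental role.
#'
#' @param genomes [simulate_parental_genomes()] output (genes are taken
#'   from its annotation), or an integer number of genes.
#' @param config the [sim_config()].
#' @return list with `cross1`/`cross2` count tables (`gene`,
#'   `maternal_count`, `paternal_count`; cross1 has genotype A as mother,
#'   cross2 has genotype A as father) and `truth` (`pegs`, `megs`,
#'   `seq_specific` gene-id vectors).
#' @export
generate_allelic_expression_counts <- function(genomes, config) {
  stopifnot(inherits(config, "sim_config"))
  n_genes <- if (is.numeric(genomes)) {
    as.integer(genomes)
  } else {
    max(nrow(genomes$annotation[feature == "gene"]), 0L)
  }
  need <- config$n_pegs + config$n_megs + config$n_seq_specific
  if (n_genes < need) {
    stop(sprintf("need at least %d genes to plant imprinting truth, have %d",
                 need, n_genes))
  }
  .with_seed(config$seed + 7L, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    special <- sample(genes, need)
    pegs <- special[seq_len(config$n_pegs)]
    megs <- special[config$n_pegs + seq_len(config$n_megs)]
    seqsp <- special[config$n_pegs + config$n_megs +
                       seq_len(config$n_seq_specific)]
    draw_cross <- function(a_is_mother) {
      total <- stats::rnbinom(n_genes, mu = config$expr_mean,
                              size = config$expr_dispersion)
      f_mat <- rep(config$maternal_fraction, n_genes)
      f_mat[genes %in% pegs] <- 1 - config$imprint_purity
      f_mat[genes %in% megs] <- config$imprint_purity
      # genotype A favored regardless of role
      f_mat[genes %in% seqsp] <- if (a_is_mother) config$imprint_purity else
        1 - config$imprint_purity
      m <- stats::rbinom(n_genes, total, f_mat)
      data.table(gene = genes, maternal_count = m, paternal_count = total - m)
    }
    list(cross1 = draw_cross(TRUE), cross2 = draw_cross(FALSE),
         truth = list(pegs = sort(pegs), megs = sort(megs),
                      seq_specific = sort(seqsp)))
  })
}

#' Simulate a complete hybrid cross
#'
#' Convenience orchestrator: parental genomes, truth methylomes, bisulfite
#' reads for the requested cell types (all replicates), and allelic
#' expression counts, all from one configuration and seed.
#'
#' @param config a [sim_config()].
#' @param samples cell types to sequence.
#' @param expression also draw allelic expression tables (needs enough
#'   annotated genes).
#' @return list with `genomes`, `truth`, `reads` (nested list
#'   `reads[[sample]][[replicate]]`), and optionally `expression`.
#' @export
simulate_cross <- function(config,
                           samples = c("egg", "sperm", "zygote"),
                           expression = FALSE) {
  genomes <- simulate_parental_genomes(config)
  truth <- simulate_methylomes(genomes, config)
  reads <- lapply(stats::setNames(samples, samples), function(s) {
    lapply(seq_len(config$n_replicates), function(r) {
      generate_bisulfite_reads(truth, genomes, config, s, replicate = r)
    })
  })
  out <- list(genomes = genomes, truth = truth, reads = reads,
              config = config)
  if (expression) {
    out$expression <- generate_allelic_expression_counts(genomes, config)
  }
  out
}
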