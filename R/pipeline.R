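# Top-level workflow over a simulated (or equivalently structured) hybrid
# cross, and evaluation helpers that score the pipeline against the
# generator's truth. These drive both the validation suite and the
# reproducibility script.

#' Run the allele-aware methylome pipeline on a simulated cross
#'
#' End-to-end workflow: N-mask the reference, extract and pool
#' per-cytosine counts for egg and sperm, call egg-sperm DMRs, split the
#' reads of each requested hybrid stage into parental alleles, compute
#' allelic methylation at the DMRs, and estimate the remodeling
#' coefficient per context.
#'
#' @param sim a [simulate_cross()] result whose `reads` include `egg`,
#'   `sperm` and every requested stage.
#' @param stages hybrid stages to analyze (default `"zygote"`;
#'   `"globular_embryo"` adds the embryo contrast).
#' @param contexts contexts scanned for egg-sperm DMRs.
#' @param min_depth cytosine coverage floor for the gamete methylomes.
#' @param min_allelic_depth allele-specific coverage floor.
#' @param rho_contexts contexts for which rho is estimated.
#' @param ... passed to [estimate_rho()].
#' @return list with `es_dmrs`, per-stage remodeling `summaries`,
#'   `rho` (table of stage x context estimates), `profiles`
#'   (allele-specific site tables per stage) and `masked_reference`.
#' @export
run_hybrid_pipeline <- function(sim,
                                stages = "zygote",
                                contexts = c("CG", "CHG", "CHH"),
                                min_depth = 3L,
                                min_allelic_depth = 3L,
                                rho_contexts = c("CG", "CHG"),
                                ...) {
  genomes <- sim$genomes
  masked <- build_nmasked_reference(genomes$maternal, genomes$snps)
  pool <- function(sample, reference) {
    filter_coverage(
      pool_replicates(lapply(sim$reads[[sample]], extract_cytosine_counts,
                             reference = reference)),
      min_depth)
  }
  egg <- pool("egg", masked)
  sperm <- pool("sperm", masked)
  es_dmrs <- select_es_dmrs(egg, sperm, contexts = contexts)
  summaries <- list(); profiles <- list()
  for (st in stages) {
    prof <- allelic_profiles(sim$reads[[st]], genomes$snps, masked,
                             min_allelic_depth = min_allelic_depth)
    bulk <- pool(st, masked)
    summaries[[st]] <- allelic_levels_at_dmrs(
      es_dmrs, prof$maternal, prof$paternal, sample_sites = bulk,
      stage = st)
    profiles[[st]] <- prof
  }
  rho <- rbindlist(lapply(stages, function(st) {
    rbindlist(lapply(rho_contexts, function(cx) {
      est <- tryCatch(estimate_rho(summaries[[st]], context = cx, ...),
                      error = function(e) NULL)
      if (is.null(est)) return(NULL)
      data.table(stage = st, context = cx, rho = est$rho,
                 ci_lo = est$ci[1], ci_hi = est$ci[2], n = est$n)
    }))
  }))
  list(es_dmrs = es_dmrs, summaries = summaries, rho = rho,
       profiles = profiles, masked_reference = masked)
}

#' Score DMR detection against the planted truth
#'
#' Simulates a cross, calls egg-sperm DMRs for one context and scores
#' them against the planted DMR windows: recall is the fraction of
#' planted windows recovered, precision the fraction of called DMRs that
#' were planted.
#'
#' @param config a [sim_config()]; plant DMRs in the scored context.
#' @param context context to score (default `"CG"`).
#' @return list with `recall`, `precision`, `n_called`, `n_planted`.
#' @export
evaluate_dmr_detection <- function(config, context = "CG") {
  sim <- simulate_cross(config, samples = c("egg", "sperm"))
  ref <- sim$genomes$maternal
  pool <- function(s) {
    filter_coverage(pool_replicates(
      lapply(sim$reads[[s]], extract_cytosine_counts, reference = ref)))
  }
  dmrs <- select_es_dmrs(pool("egg"), pool("sperm"), contexts = context)
  cx <- context
  planted <- sim$truth$planted_dmrs[sim$truth$planted_dmrs$context == cx]
  key_p <- planted[, paste(chrom, start)]
  key_c <- dmrs[, paste(chrom, start)]
  list(recall = mean(key_p %in% key_c),
       precision = if (length(key_c)) mean(key_c %in% key_p) else NA_real_,
       n_called = nrow(dmrs), n_planted = nrow(planted))
}

#' Null calibration of the DMR caller
#'
#' Repeatedly simulates two samples from one identical methylome (no
#' planted DMRs; egg and sperm share every true level) and records, per
#' run, the fraction of tested windows with raw Fisher p below 0.05 and
#' the number of DMRs surviving the FDR and difference cutoffs.
#'
#' @param config a [sim_config()] with `n_planted_dmrs` all zero.
#' @param n_runs number of seeded runs (the config seed is advanced by
#'   one per run).
#' @param context context scored.
#' @return `data.table` with one row per run: `seed`, `frac_raw_p05`,
#'   `n_dmrs`, `n_tested`.
#' @export
evaluate_null_dmrs <- function(config, n_runs = 20L, context = "CG") {
  stopifnot(sum(config$n_planted_dmrs) == 0L)
  rbindlist(lapply(seq_len(n_runs), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    sim <- simulate_cross(cfg, samples = c("egg", "sperm"))
    ref <- sim$genomes$maternal
    pool <- function(s) {
      filter_coverage(pool_replicates(
        lapply(sim$reads[[s]], extract_cytosine_counts, reference = ref)))
    }
    tested <- test_windows(pool("egg"), pool("sperm"), contexts = context)
    n_dmr <- sum(abs(tested$delta) > .DELTA_CUTOFFS[tested$context] &
                   tested$fdr < 0.05)
    data.table(seed = cfg$seed,
               frac_raw_p05 = mean(tested$p_value < 0.05),
               n_dmrs = n_dmr, n_tested = nrow(tested))
  }))
}

#' Recover the remodeling coefficient from a full simulated analysis
#'
#' Simulates a cross at the configured true `rho`, runs the complete
#' pipeline (gamete DMR calling, hybrid allele splitting, allelic levels)
#' and returns the estimated coefficient per requested context alongside
#' the truth.
#'
#' @param config a [sim_config()].
#' @param stages stages to analyze.
#' @param contexts contexts for the egg-sperm DMR scan.
#' @param rho_contexts contexts for rho estimation.
#' @return list with `rho_true`, `rho` (estimate table from
#'   [run_hybrid_pipeline()]), `summaries` and `chh_lower_parent` (named
#'   per stage, `NA` without testable CHH DMRs).
#' @export
evaluate_rho_recovery <- function(config, stages = "zygote",
                                  contexts = "CG",
                                  rho_contexts = "CG") {
  sim <- simulate_cross(config, samples = c("egg", "sperm", stages))
  res <- run_hybrid_pipeline(sim, stages = stages, contexts = contexts,
                             rho_contexts = rho_contexts)
  chh <- vapply(stages, function(st) {
    sm <- res$summaries[[st]][testable == TRUE & context == "CHH"]
    if (!nrow(sm)) return(NA_real_)
    mean(sm$m_total - pmin(sm$m_egg, sm$m_sperm))
  }, numeric(1))
  list(rho_true = config$rho, rho = res$rho, summaries = res$summaries,
       chh_lower_parent = stats::setNames(chh, stages))
}

#' Score imprinting classification against the planted truth
#'
#' Draws reciprocal-cross allelic count tables, classifies every gene and
#' scores PEG/MEG recovery and the false-call rate among genes planted as
#' background.
#'
#' @param config a [sim_config()] (its `maternal_fraction`, `n_pegs`,
#'   `n_megs` and `n_seq_specific` define the scenario).
#' @param n_genes gene universe size.
#' @return list with `recall_peg`, `recall_meg`, `false_call_rate`
#'   (imprinted calls among testable background genes), `n_testable`,
#'   and the full `calls` table.
#' @export
evaluate_imprinting <- function(config, n_genes = 500L) {
  ex <- generate_allelic_expression_counts(n_genes, config)
  calls <- classify_imprinting(ex$cross1, ex$cross2)
  lab <- stats::setNames(calls$label, calls$gene)
  truth <- ex$truth
  background <- setdiff(calls$gene,
                        c(truth$pegs, truth$megs, truth$seq_specific))
  bg_lab <- lab[background]
  bg_testable <- bg_lab != "untestable"
  list(
    recall_peg = if (length(truth$pegs))
      mean(lab[truth$pegs] == "PEG") else NA_real_,
    recall_meg = if (length(truth$megs))
      mean(lab[truth$megs] == "MEG") else NA_real_,
    false_call_rate = if (any(bg_testable))
      mean(bg_lab[bg_testable] %in% c("PEG", "MEG")) else NA_real_,
    n_testable = sum(lab != "untestable"),
    calls = calls
  )
}
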