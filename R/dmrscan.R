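# Windowed DMR calling between two samples on a fixed 50-bp genomic grid:
# binning, the coverage/cytosine-count filter, Fisher's exact test with
# Benjamini-Hochberg FDR, context-specific difference cutoffs, feature
# annotation, the density-plot statistic, and DMR-set overlap.

#' Pool cytosine counts into fixed-grid windows
#'
#' Tiles each chromosome with non-overlapping windows on the fixed grid
#' (0, 50, 100, ...; 0-based half-open) and pools methylated/unmethylated
#' counts per window and context. The trailing sub-window chromosome
#' remainder, if any, is kept as a short window.
#'
#' @param sites cytosine site table for one sample (counts already pooled
#'   over replicates if applicable).
#' @param window window width in bases (default 50).
#' @param chrom_sizes optional named vector to cap the final window's end
#'   at the chromosome length.
#' @return `data.table` per (`chrom`, `start`, `end`, `context`):
#'   `n_sites`, `n_meth`, `n_unmeth`, `min_site_depth`.
#' @export
bin_windows <- function(sites, window = 50L, chrom_sizes = NULL) {
  window <- as.integer(window)
  stopifnot(window >= 1L)
  if (!nrow(sites)) {
    return(data.table(chrom = character(0), start = integer(0),
                      end = integer(0), context = character(0),
                      n_sites = integer(0), n_meth = integer(0),
                      n_unmeth = integer(0), min_site_depth = integer(0)))
  }
  w <- sites[, .(n_sites = .N, n_meth = sum(n_meth), n_unmeth = sum(n_unmeth),
                 min_site_depth = min(n_meth + n_unmeth)),
             by = .(chrom, start = ((pos - 1L) %/% window) * window, context)]
  w[, end := start + window]
  if (!is.null(chrom_sizes)) {
    w[, end := pmin(end, chrom_sizes[chrom])]
  }
  setorder(w, chrom, start, context)
  w[, .(chrom, start, end, context, n_sites, n_meth, n_unmeth,
        min_site_depth)]
}

#' Pair the windows of two samples
#'
#' Inner-joins the binned windows of two samples on window and context;
#' only windows observed in both samples can be tested.
#'
#' @param w1,w2 outputs of [bin_windows()] for the two samples.
#' @return paired window table with suffixed per-sample columns.
#' @export
pair_windows <- function(w1, w2) {
  merge(w1, w2, by = c("chrom", "start", "end", "context"),
        suffixes = c("1", "2"))
}

#' Filter paired windows on cytosine count and per-site coverage
#'
#' A window is testable when it contains at least `min_sites` cytosines of
#' the context and every one of those cytosines has depth at least
#' `min_site_depth`, in both samples.
#'
#' @param pairs paired window table from [pair_windows()].
#' @param min_sites minimum cytosines per window (default 5).
#' @param min_site_depth minimum per-cytosine depth (default 3).
#' @return filtered paired window table.
#' @export
filter_windows <- function(pairs, min_sites = 5L, min_site_depth = 3L) {
  pairs[n_sites1 >= min_sites & n_sites2 >= min_sites &
          min_site_depth1 >= min_site_depth &
          min_site_depth2 >= min_site_depth]
}

#' Vectorized two-sided Fisher's exact test for 2x2 tables
#'
#' For the table `[[a, b], [c, d]]` (window counts: methylated and
#' unmethylated in samples 1 and 2), the two-sided p-value sums the
#' hypergeometric probabilities, at the observed margins, of every table
#' at most as probable as the observed one (with the customary relative
#' tolerance of 1e-7 on the probability comparison). A table with an
#' all-zero margin has p = 1 by convention.
#'
#' @param a,b,c,d non-negative integer vectors of equal length.
#' @return numeric vector of two-sided p-values.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n,
            all(c(a, b, c, d) >= 0))
  vapply(seq_len(n), function(i) {
    m <- a[i] + b[i]        # row 1 total
    r <- c[i] + d[i]        # row 2 total
    k <- a[i] + c[i]        # column 1 total
    if (m + r == 0L || k == 0L || k == m + r) return(1)
    support <- max(0L, k - r):min(k, m)
    probs <- stats::dhyper(support, m, r, k)
    p_obs <- stats::dhyper(a[i], m, r, k)
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a thin, name-stable wrapper
#' around [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted values, monotone in rank order and capped at 1.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

.DELTA_CUTOFFS <- c(CG = 0.5, CHG = 0.3, CHH = 0.1)

#' Call differentially methylated regions between two samples
#'
#' The genome is divided into fixed 50-bp bins; bins with at least five
#' context cytosines, each covered at least three-fold in both samples,
#' are tested with Fisher's exact test on the pooled window counts, and
#' p-values are Benjamini-Hochberg adjusted across all tested bins of
#' each context. Bins with a methylation difference above the
#' context-specific cutoff (CG 0.5, CHG 0.3, CHH 0.1) and FDR below 0.05
#' are reported as DMRs; `direction` is `hyper` when sample 1 exceeds
#' sample 2.
#'
#' @param sites1,sites2 cytosine site tables of the two samples
#'   (replicates pooled by counts).
#' @param contexts contexts to scan.
#' @param window window width (default 50).
#' @param min_sites,min_site_depth window filter, see [filter_windows()].
#' @param delta_cutoff named vector of context difference cutoffs.
#' @param fdr_cutoff FDR threshold (default 0.05).
#' @param use_raw_p if `TRUE`, threshold the raw Fisher p-value instead of
#'   the adjusted one.
#' @param chrom_sizes optional named vector for trailing-window capping.
#' @return `data.table` of DMRs: window fields, per-sample counts, levels
#'   `m1`/`m2`, `delta = m1 - m2`, `p_value`, `fdr`, `direction`.
#' @export
call_dmrs <- function(sites1, sites2,
                      contexts = c("CG", "CHG", "CHH"),
                      window = 50L,
                      min_sites = 5L,
                      min_site_depth = 3L,
                      delta_cutoff = .DELTA_CUTOFFS,
                      fdr_cutoff = 0.05,
                      use_raw_p = FALSE,
                      chrom_sizes = NULL) {
  tested <- test_windows(sites1, sites2, contexts = contexts,
                         window = window, min_sites = min_sites,
                         min_site_depth = min_site_depth,
                         chrom_sizes = chrom_sizes)
  if (!nrow(tested)) return(.empty_dmrs())
  crit <- if (use_raw_p) tested$p_value else tested$fdr
  keep <- abs(tested$delta) > delta_cutoff[tested$context] & crit < fdr_cutoff
  out <- tested[keep]
  out[, direction := fifelse(delta > 0, "hyper", "hypo")]
  setorder(out, chrom, start, context)
  out[]
}

#' Test all filtered windows between two samples
#'
#' The testing stage of [call_dmrs()] without the DMR thresholds: bins,
#' pairs and filters the windows, then computes the pooled levels, the
#' Fisher p-value and the per-context BH-adjusted value for every tested
#' window. Useful for FDR calibration and diagnostics.
#'
#' @inheritParams call_dmrs
#' @return `data.table` of all tested windows with `m1`, `m2`, `delta`,
#'   `p_value`, `fdr`.
#' @export
test_windows <- function(sites1, sites2,
                         contexts = c("CG", "CHG", "CHH"),
                         window = 50L,
                         min_sites = 5L,
                         min_site_depth = 3L,
                         chrom_sizes = NULL) {
  w1 <- bin_windows(sites1[context %in% contexts], window, chrom_sizes)
  w2 <- bin_windows(sites2[context %in% contexts], window, chrom_sizes)
  pairs <- pair_windows(w1, w2)
  pairs <- filter_windows(pairs, min_sites, min_site_depth)
  if (!nrow(pairs)) {
    out <- .empty_dmrs()
    out[, direction := NULL]
    return(out)
  }
  pairs[, m1 := n_meth1 / (n_meth1 + n_unmeth1)]
  pairs[, m2 := n_meth2 / (n_meth2 + n_unmeth2)]
  pairs[, delta := m1 - m2]
  pairs[, p_value := fisher_exact_2x2(n_meth1, n_unmeth1, n_meth2, n_unmeth2)]
  pairs[, fdr := bh_adjust(p_value), by = context]
  setorder(pairs, chrom, start, context)
  pairs[]
}

.empty_dmrs <- function() {
  data.table(chrom = character(0), start = integer(0), end = integer(0),
             context = character(0), n_sites1 = integer(0),
             n_meth1 = integer(0), n_unmeth1 = integer(0),
             min_site_depth1 = integer(0), n_sites2 = integer(0),
             n_meth2 = integer(0), n_unmeth2 = integer(0),
             min_site_depth2 = integer(0), m1 = numeric(0), m2 = numeric(0),
             delta = numeric(0), p_value = numeric(0), fdr = numeric(0),
             direction = character(0))
}

#' Annotate DMRs by genomic feature class
#'
#' Classifies each DMR by any-overlap (at least one base) against gene and
#' TE annotation, with precedence TE-gene (overlaps both a TE and a gene)
#' over TE over gene body over intergenic.
#'
#' @param dmrs DMR table (`chrom`, `start`, `end`, 0-based half-open).
#' @param gene_intervals,te_intervals interval tables (`chrom`, `start`,
#'   `end`, 0-based half-open); either may be `NULL` or empty.
#' @return the DMR table with a `feature_class` column.
#' @export
annotate_dmrs <- function(dmrs, gene_intervals, te_intervals) {
  out <- copy(dmrs)
  if (!nrow(out)) {
    out[, feature_class := character(0)]
    return(out[])
  }
  in_gene <- if (!is.null(gene_intervals) && nrow(gene_intervals)) {
    .overlaps_any(out$chrom, out$start, out$end, gene_intervals)
  } else rep(FALSE, nrow(out))
  in_te <- if (!is.null(te_intervals) && nrow(te_intervals)) {
    .overlaps_any(out$chrom, out$start, out$end, te_intervals)
  } else rep(FALSE, nrow(out))
  out[, feature_class := fifelse(in_te & in_gene, "TE_gene",
                          fifelse(in_te, "TE",
                           fifelse(in_gene, "gene_body", "intergenic")))]
  out[]
}

#' Per-window methylation differences for density plots
#'
#' Compares the average cytosine methylation level of two samples within
#' 50-bp bins. A bin is retained when it contains at least
#' `min_informative` informative sequenced cytosines (the summed
#' sequencing depth over the bin's context cytosines) in both samples and
#' its level reaches the context ratio threshold (CG 0.5, CHG 0.3, CHH
#' 0.1) in at least one sample. The bin level is the unweighted mean of
#' per-cytosine levels, i.e. the average cytosine methylation level.
#'
#' @param sites1,sites2 cytosine site tables of the two samples.
#' @param context a single context.
#' @param window window width (default 50).
#' @param min_informative minimum summed depth per bin per sample
#'   (default 20).
#' @param ratio_threshold level threshold; default looked up per context.
#' @param informative `"depth_sum"` (default: summed per-cytosine depth)
#'   or `"depth_by_sites"` (summed depth multiplied by the number of
#'   cytosines), the two readings of the informativeness rule.
#' @param binwidth histogram bin width for the frequency table.
#' @return list with `bins` (`chrom`, `start`, `end`, `m1`, `m2`,
#'   `delta`) and `freq` (`bin_center`, `frequency`; proportions summing
#'   to 1).
#' @export
density_difference <- function(sites1, sites2, context,
                               window = 50L,
                               min_informative = 20L,
                               ratio_threshold = NULL,
                               informative = c("depth_sum", "depth_by_sites"),
                               binwidth = 0.05) {
  informative <- match.arg(informative)
  cx <- context
  if (is.null(ratio_threshold)) {
    ratio_threshold <- c(CG = 0.5, CHG = 0.3, CHH = 0.1)[[cx]]
  }
  summarize <- function(sites) {
    s <- sites[context == cx & (n_meth + n_unmeth) > 0L]
    s[, .(m = mean(n_meth / (n_meth + n_unmeth)),
          info = sum(n_meth + n_unmeth) *
            (if (informative == "depth_by_sites") .N else 1L)),
      by = .(chrom, start = ((pos - 1L) %/% window) * window)]
  }
  s1 <- summarize(sites1); s2 <- summarize(sites2)
  b <- merge(s1, s2, by = c("chrom", "start"), suffixes = c("1", "2"))
  b <- b[info1 >= min_informative & info2 >= min_informative &
           (m1 >= ratio_threshold | m2 >= ratio_threshold)]
  b[, end := start + window]
  b[, delta := m1 - m2]
  bins <- b[, .(chrom, start, end, m1, m2, delta)]
  breaks <- seq(-1 - binwidth / 2, 1 + binwidth / 2, by = binwidth)
  h <- hist(pmin(pmax(bins$delta, -1), 1), breaks = breaks, plot = FALSE)
  freq <- data.table(bin_center = h$mids,
                     frequency = if (nrow(bins)) h$counts / nrow(bins) else
                       rep(0, length(h$mids)))
  list(bins = bins[], freq = freq)
}

#' Overlap two DMR sets
#'
#' A DMR of set A is shared when it overlaps (at least one base) a DMR of
#' set B of the same context, and vice versa.
#'
#' @param set_a,set_b DMR tables from [call_dmrs()].
#' @return list with `n_a_only`, `n_shared` (shared DMRs of A),
#'   `n_b_only`, `fraction_shared` (`n_shared / nrow(set_a)`), and
#'   `jaccard` (`n_shared / (nrow(set_a) + n_b_only)`).
#' @export
overlap_dmr_sets <- function(set_a, set_b) {
  shared_flags <- function(x, y) {
    if (!nrow(x) || !nrow(y)) return(rep(FALSE, nrow(x)))
    out <- rep(FALSE, nrow(x))
    for (cx in unique(x$context)) {
      xi <- which(x$context == cx)
      yi <- y[context == cx]
      if (!nrow(yi)) next
      out[xi] <- .overlaps_any(x$chrom[xi], x$start[xi], x$end[xi], yi)
    }
    out
  }
  a_shared <- sum(shared_flags(set_a, set_b))
  b_shared <- sum(shared_flags(set_b, set_a))
  n_a <- nrow(set_a); n_b <- nrow(set_b)
  list(n_a_only = n_a - a_shared,
       n_shared = a_shared,
       n_b_only = n_b - b_shared,
       fraction_shared = if (n_a > 0L) a_shared / n_a else NA_real_,
       jaccard = if (n_a + n_b - b_shared > 0L)
         a_shared / (n_a + (n_b - b_shared)) else NA_real_)
}

#' Merge adjacent same-context DMRs
#'
#' Optional post-processing: concatenates book-ended or overlapping DMRs
#' of the same context and direction into single intervals. Off the
#' default path, since reporting is per fixed 50-bp bin.
#'
#' @param dmrs DMR table.
#' @return merged interval table (`chrom`, `start`, `end`, `context`,
#'   `direction`, `n_windows`).
#' @export
merge_adjacent_dmrs <- function(dmrs) {
  if (!nrow(dmrs)) {
    return(data.table(chrom = character(0), start = integer(0),
                      end = integer(0), context = character(0),
                      direction = character(0), n_windows = integer(0)))
  }
  d <- copy(dmrs)
  setorder(d, context, direction, chrom, start)
  d[, grp := cumsum(c(1L, as.integer(
    chrom[-1] != chrom[-.N] | context[-1] != context[-.N] |
      direction[-1] != direction[-.N] | start[-1] > end[-.N]))),
    ]
  d[, .(chrom = chrom[1], start = min(start), end = max(end),
        context = context[1], direction = direction[1], n_windows = .N),
    by = grp][, grp := NULL][]
}

utils::globalVariables(c("info1", "info2", "grp", "m"))
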