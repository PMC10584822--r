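# Imprinted-gene classification from allelic RNA read counts in
# reciprocal hybrids: an exact binomial allelic-bias test per gene and
# cross, then the reciprocal-cross decision logic separating imprinting
# (bias follows parental role) from sequence-specific expression (bias
# follows genotype).

#' Exact binomial test of allelic expression bias
#'
#' Tests the maternal read count against a binomial null with the given
#' expected maternal proportion (0.5 by default), two-sided, and reports
#' the display log2 ratio `log2((maternal + 1) / (paternal + 1))`
#' (the pseudocount enters the ratio only, never the test). Positive
#' values are maternal-biased.
#'
#' @param maternal_count,paternal_count non-negative integer vectors.
#' @param prob expected maternal proportion under the null (default 0.5).
#' @return `data.table` with `log2_ratio` and `p_value` (`NA` when both
#'   counts are zero).
#' @export
allelic_bias_test <- function(maternal_count, paternal_count, prob = 0.5) {
  stopifnot(length(maternal_count) == length(paternal_count),
            all(maternal_count >= 0), all(paternal_count >= 0))
  total <- maternal_count + paternal_count
  p <- vapply(seq_along(total), function(i) {
    if (total[i] == 0L) return(NA_real_)
    stats::binom.test(maternal_count[i], total[i], p = prob)$p.value
  }, numeric(1))
  data.table(log2_ratio = log2((maternal_count + 1) / (paternal_count + 1)),
             p_value = p)
}

#' Classify imprinted genes from reciprocal-cross allelic counts
#'
#' A gene is testable when its total allelic count reaches `min_total` in
#' both crosses. Within each cross, allelic bias is assessed with
#' [allelic_bias_test()] and Benjamini-Hochberg adjusted across testable
#' genes; a cross calls a gene maternal-biased (or paternal-biased) when
#' `|log2 ratio| > log2fc_cutoff` with adjusted p below `alpha`. A gene
#' paternal-biased in both crosses is a PEG, maternal-biased in both a
#' MEG; a gene whose bias flips with the cross so that the same genomic
#' parent is always favored is sequence-specific; any other testable gene
#' is biallelic.
#'
#' @param cross1_counts,cross2_counts count tables (`gene`,
#'   `maternal_count`, `paternal_count`) of the two reciprocal crosses
#'   (the genotypes swap parental roles between crosses).
#' @param min_total minimum total allelic count per cross (default 10).
#' @param log2fc_cutoff allelic log2 ratio cutoff (default 1).
#' @param alpha adjusted-p cutoff (default 0.01).
#' @param prob expected maternal proportion under the null; keep at 0.5
#'   unless testing for imprinting over and above a global maternal bias.
#' @return `data.table` of `ImprintCall` rows: `gene`, per-cross counts,
#'   log2 ratios, raw and adjusted p-values, and `label` in `PEG`, `MEG`,
#'   `sequence_specific`, `biallelic`, `untestable`.
#' @export
classify_imprinting <- function(cross1_counts, cross2_counts,
                                min_total = 10L,
                                log2fc_cutoff = 1,
                                alpha = 0.01,
                                prob = 0.5) {
  c1 <- as.data.table(cross1_counts)
  c2 <- as.data.table(cross2_counts)
  merged <- merge(c1, c2, by = "gene", all = TRUE, suffixes = c("_1", "_2"))
  per_cross <- function(m, p) {
    tot <- m + p
    testable <- !is.na(tot) & tot >= min_total
    bias <- allelic_bias_test(ifelse(is.na(m), 0L, m),
                              ifelse(is.na(p), 0L, p), prob = prob)
    padj <- rep(NA_real_, length(m))
    padj[testable] <- bh_adjust(bias$p_value[testable])
    list(log2 = bias$log2_ratio, p = bias$p_value, padj = padj,
         testable = testable)
  }
  b1 <- per_cross(merged$maternal_count_1, merged$paternal_count_1)
  b2 <- per_cross(merged$maternal_count_2, merged$paternal_count_2)
  testable <- b1$testable & b2$testable
  sig_mat1 <- testable & b1$log2 > log2fc_cutoff & b1$padj < alpha
  sig_pat1 <- testable & b1$log2 < -log2fc_cutoff & b1$padj < alpha
  sig_mat2 <- testable & b2$log2 > log2fc_cutoff & b2$padj < alpha
  sig_pat2 <- testable & b2$log2 < -log2fc_cutoff & b2$padj < alpha
  label <- rep("biallelic", nrow(merged))
  label[sig_pat1 & sig_pat2] <- "PEG"
  label[sig_mat1 & sig_mat2] <- "MEG"
  label[(sig_mat1 & sig_pat2) | (sig_pat1 & sig_mat2)] <- "sequence_specific"
  label[!testable] <- "untestable"
  data.table(
    gene = merged$gene,
    maternal_count_1 = merged$maternal_count_1,
    paternal_count_1 = merged$paternal_count_1,
    log2_ratio_1 = b1$log2, p_value_1 = b1$p, padj_1 = b1$padj,
    maternal_count_2 = merged$maternal_count_2,
    paternal_count_2 = merged$paternal_count_2,
    log2_ratio_2 = b2$log2, p_value_2 = b2$p, padj_2 = b2$padj,
    label = label
  )
}
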