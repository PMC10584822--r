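# Internal helpers shared across modules.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' @importFrom data.table data.table setkey setkeyv := .N .SD .I setorder
#' @importFrom data.table rbindlist fifelse setnames copy as.data.table
#' @importFrom data.table setattr fread fwrite
#' @importFrom graphics hist
#' @importFrom methods is
NULL

# silence R CMD check notes for data.table NSE column names
utils::globalVariables(c(
  ".", "chrom", "pos", "strand", "context", "trinucleotide", "n_meth",
  "n_unmeth", "depth", "level", "start", "end", "feature", "read_id",
  "meth", "allele", "base", "maternal_base", "paternal_base",
  "bisulfite_ambiguous", "usable", "match_mat", "match_pat", "n_usable",
  "n_mat", "n_pat", "n_neither", "assignment", "window_start", "n_sites",
  "min_site_depth", "m1", "m2", "delta", "p_value", "fdr", "direction",
  "feature_class", "compartment", "pat_is_c", "m_egg", "m_sperm",
  "m_zygote_mat", "m_zygote_pat", "m_ge_mat", "m_ge_pat", "gene",
  "maternal_count", "paternal_count", "label", "testable", "m_mat",
  "m_pat", "depth_mat", "depth_pat", "n_sites_mat", "n_sites_pat",
  "class_call", "i.pos", "stage", "dmr_id", "n_meth1", "n_unmeth1",
  "n_meth2", "n_unmeth2", "n_sites1", "n_sites2", "min_site_depth1",
  "min_site_depth2", "m_total", "log2_ratio", "padj", "total",
  "level_mean", "rep_id", "i.level", "i.m", "width", "sample_name",
  "i.m_egg", "i.m_sperm", "n", "pure", "n_replicates"
))

# coerce a genome (named character vector, DNAStringSet, or list) to a
# named character vector of chromosome sequences
.genome_chars <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
  } else if (is.list(genome)) {
    out <- vapply(genome, as.character, character(1))
  } else if (is.character(genome)) {
    out <- genome
  } else {
    stop("genome must be a DNAStringSet or named character vector")
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    stop("genome sequences must be named by chromosome")
  }
  out
}

.chrom_sizes <- function(genome) {
  g <- .genome_chars(genome)
  stats::setNames(nchar(g), names(g))
}

# run `expr` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name))
  }
  invisible(x)
}
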