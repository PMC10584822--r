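# SNP-based partitioning of hybrid reads into parental alleles with
# N-masking semantics, and allele-specific cytosine counts.

#' N-mask SNP positions in a reference genome
#'
#' Replaces the base at every SNP position with `N`, so that neither
#' allele is favored during alignment and so that context calling skips
#' any cytosine whose trinucleotide includes a variant position.
#'
#' @param reference named character vector or [Biostrings::DNAStringSet].
#' @param snps SNP table (`chrom`, `pos`, `maternal_base`,
#'   `paternal_base`); `maternal_base` must match the reference (the
#'   maternal genome is the alignment backbone).
#' @return named character vector with `N` at each SNP position.
#' @export
build_nmasked_reference <- function(reference, snps) {
  g <- .genome_chars(reference)
  snps <- as.data.table(snps)
  if (!nrow(snps)) return(g)
  bad <- snps[!(chrom %in% names(g))]
  if (nrow(bad)) stop("SNP chromosomes absent from reference: ",
                      paste(unique(bad$chrom), collapse = ", "))
  for (ch in unique(snps$chrom)) {
    b <- strsplit(g[[ch]], "", fixed = TRUE)[[1]]
    sn <- snps[chrom == ch]
    if (any(sn$pos < 1L | sn$pos > length(b))) {
      stop("SNP position outside reference on ", ch)
    }
    mism <- sn[b[sn$pos] != sn$maternal_base]
    if (nrow(mism)) {
      stop("SNP maternal_base inconsistent with reference at: ",
           paste(utils::head(paste0(ch, ":", mism$pos), 5L), collapse = ", "))
    }
    b[sn$pos] <- "N"
    g[[ch]] <- paste(b, collapse = "")
  }
  g
}

#' Assign hybrid reads to parental alleles from their SNP bases
#'
#' Implements the conservative sorting rule used for N-masked alignments:
#' collect the read's observed bases at overlapped, usable SNPs and
#' require unanimity. In bisulfite mode a SNP is unusable for a given read
#' when its allele pair is C/T and the read is on the plus strand, or G/A
#' on the minus strand, because bisulfite conversion on that strand makes
#' the two alleles indistinguishable; RNA mode uses every SNP. A read with
#' no usable SNP is `unassigned`; a read whose bases support both parents,
#' or match neither parent at some SNP, is `conflicting` and discarded
#' from allele-specific analyses.
#'
#' @param reads a [bisreads] object aligned to the N-masked reference.
#' @param snps SNP table with `bisulfite_ambiguous` flag.
#' @param mode `"bisulfite"` or `"rna"`.
#' @return `data.table` (`read_id`, `assignment`) with assignment one of
#'   `maternal`, `paternal`, `unassigned`, `conflicting`, one row per
#'   read.
#' @export
assign_read_allele <- function(reads, snps, mode = c("bisulfite", "rna")) {
  mode <- match.arg(mode)
  stopifnot(inherits(reads, "bisreads"))
  snps <- as.data.table(snps)
  obs <- merge(reads$snp_obs, snps, by = c("chrom", "pos"))
  obs <- merge(obs, reads$reads[, .(read_id, strand)], by = "read_id")
  if (mode == "bisulfite" && nrow(obs)) {
    pair_ct <- (obs$maternal_base %in% c("C", "T") &
                  obs$paternal_base %in% c("C", "T"))
    pair_ga <- (obs$maternal_base %in% c("G", "A") &
                  obs$paternal_base %in% c("G", "A"))
    obs[, usable := !((strand == "+" & pair_ct) | (strand == "-" & pair_ga))]
  } else {
    obs[, usable := rep(TRUE, .N)]
  }
  obs <- obs[usable == TRUE]
  per_read <- if (nrow(obs)) {
    obs[, .(n_mat = sum(base == maternal_base),
            n_pat = sum(base == paternal_base),
            n_neither = sum(base != maternal_base & base != paternal_base)),
        by = read_id]
  } else {
    data.table(read_id = integer(0), n_mat = integer(0), n_pat = integer(0),
               n_neither = integer(0))
  }
  out <- merge(reads$reads[, .(read_id)], per_read, by = "read_id",
               all.x = TRUE)
  out[, assignment := fifelse(
    is.na(n_mat) | (n_mat + n_pat + n_neither) == 0L, "unassigned",
    fifelse(n_neither > 0L | (n_mat > 0L & n_pat > 0L), "conflicting",
            fifelse(n_mat > 0L, "maternal", "paternal")))]
  out[, .(read_id, assignment)]
}

#' Allele-specific cytosine counts from assigned hybrid reads
#'
#' Restricts methylation extraction to maternal-only and paternal-only
#' reads and applies the allele-specific coverage rule: individual
#' cytosines covered by at least `min_allelic_depth` allele-assigned reads
#' (default 3) are retained per allele. Conflicting and unassigned reads
#' contribute to neither profile.
#'
#' @param reads a [bisreads] object.
#' @param assignments output of [assign_read_allele()].
#' @param reference the (N-masked) reference the reads are aligned to.
#' @param min_allelic_depth minimum allele-specific reads per cytosine.
#' @return list with elements `maternal` and `paternal`, each a cytosine
#'   site table carrying an `allele` attribute.
#' @export
allelic_cytosine_counts <- function(reads, assignments, reference,
                                    min_allelic_depth = 3L) {
  stopifnot(inherits(reads, "bisreads"))
  out <- lapply(c(maternal = "maternal", paternal = "paternal"), function(al) {
    ids <- assignments[assignment == al, read_id]
    sub <- bisreads(reads$reads[read_id %in% ids],
                    reads$calls[read_id %in% ids],
                    reads$snp_obs[read_id %in% ids])
    sites <- extract_cytosine_counts(sub, reference)
    sites <- filter_coverage(sites, min_allelic_depth)
    setattr(sites, "allele", al)
    sites
  })
  out
}

#' Pooled allele-specific methylation profiles across replicates
#'
#' Convenience wrapper: assigns alleles in each replicate, sums the
#' allele-specific counts over replicates, then applies the
#' `min_allelic_depth` filter on the pooled depth.
#'
#' @param reads_list list of [bisreads] objects (replicates of one hybrid
#'   sample).
#' @param snps SNP table.
#' @param reference N-masked reference.
#' @param min_allelic_depth minimum pooled allele-specific reads per
#'   cytosine.
#' @param mode passed to [assign_read_allele()].
#' @return list with `maternal`/`paternal` pooled site tables and
#'   `assignment_summary` (per-replicate counts of each assignment class).
#' @export
allelic_profiles <- function(reads_list, snps, reference,
                             min_allelic_depth = 3L,
                             mode = "bisulfite") {
  stopifnot(is.list(reads_list), length(reads_list) >= 1L)
  per_rep <- lapply(reads_list, function(rd) {
    asg <- assign_read_allele(rd, snps, mode = mode)
    prof <- allelic_cytosine_counts(rd, asg, reference,
                                    min_allelic_depth = 1L)
    list(profiles = prof,
         summary = asg[, .N, by = assignment])
  })
  pool_one <- function(al) {
    pooled <- pool_replicates(lapply(per_rep, function(x) x$profiles[[al]]))
    pooled <- filter_coverage(pooled, min_allelic_depth)
    setattr(pooled, "allele", al)
    pooled
  }
  summ <- rbindlist(lapply(per_rep, function(x) x$summary),
                    idcol = "rep_id")
  list(maternal = pool_one("maternal"), paternal = pool_one("paternal"),
       assignment_summary = summ)
}
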