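# Plain-text readers/writers for the formats the pipeline exchanges:
# Bismark-style CX reports, FASTA, SNP tables, BED intervals, DMR tables
# and allelic count tables.

#' Write / read a Bismark-style CX report
#'
#' Tab-separated, headerless: chromosome, 1-based position, strand,
#' methylated count, unmethylated count, context, trinucleotide.
#'
#' @param sites cytosine site table.
#' @param path file path.
#' @export
write_cx_report <- function(sites, path) {
  fwrite(sites[, .(chrom, pos, strand, n_meth, n_unmeth, context,
                   trinucleotide)],
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_cx_report
#' @export
read_cx_report <- function(path) {
  out <- fread(path, sep = "\t", header = FALSE,
               col.names = c("chrom", "pos", "strand", "n_meth", "n_unmeth",
                             "context", "trinucleotide"),
               colClasses = list(character = c(1, 3, 6, 7),
                                 integer = c(2, 4, 5)))
  setorder(out, chrom, pos, strand)
  out[, .(chrom, pos, strand, context, trinucleotide, n_meth, n_unmeth)]
}

#' Write genome sequences as FASTA
#'
#' @param genome named character vector or [Biostrings::DNAStringSet].
#' @param path file path.
#' @export
write_genome_fasta <- function(genome, path) {
  g <- .genome_chars(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(g), path)
  invisible(path)
}

#' Read genome sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  stats::setNames(as.character(x), names(x))
}

#' Write / read a biallelic SNP table
#'
#' Tab-separated with header: `chrom`, `pos` (1-based), `maternal_base`,
#' `paternal_base`, `bisulfite_ambiguous`.
#'
#' @param snps SNP table.
#' @param path file path.
#' @export
write_snp_table <- function(snps, path) {
  fwrite(snps, path, sep = "\t")
  invisible(path)
}

#' @rdname write_snp_table
#' @export
read_snp_table <- function(path) {
  out <- fread(path, sep = "\t")
  setorder(out, chrom, pos)
  out[]
}

#' Write / read annotation intervals as BED
#'
#' Three or four columns, 0-based half-open; the fourth column is the
#' feature name.
#'
#' @param intervals table with `chrom`, `start`, `end` and optionally
#'   `feature`.
#' @param path file path.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "feature"), names(intervals))
  fwrite(intervals[, cols, with = FALSE], path, sep = "\t",
         col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  out <- fread(path, sep = "\t", header = FALSE)
  setnames(out, seq_len(min(4L, ncol(out))),
           c("chrom", "start", "end", "feature")[seq_len(min(4L, ncol(out)))])
  out[]
}

#' Write a DMR table as BED-like TSV
#'
#' @param dmrs DMR table from [call_dmrs()] (optionally annotated).
#' @param path file path.
#' @export
write_dmr_table <- function(dmrs, path) {
  cols <- intersect(c("chrom", "start", "end", "context", "m1", "m2",
                      "delta", "p_value", "fdr", "direction",
                      "feature_class"), names(dmrs))
  fwrite(dmrs[, cols, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' Write / read allelic count tables
#'
#' Tab-separated with header: `gene`, `maternal_count`, `paternal_count`.
#'
#' @param counts count table.
#' @param path file path.
#' @export
write_allelic_counts <- function(counts, path) {
  fwrite(counts[, .(gene, maternal_count, paternal_count)], path,
         sep = "\t")
  invisible(path)
}

#' @rdname write_allelic_counts
#' @export
read_allelic_counts <- function(path) {
  fread(path, sep = "\t")
}
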