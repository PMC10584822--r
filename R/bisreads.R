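# Container for simplified aligned bisulfite reads: one row per read plus
# long-format tables of per-cytosine conversion calls and observed SNP
# bases. This stands in for a deduplicated, methylation-extracted BAM.

#' Construct a bisulfite read collection
#'
#' @param reads `data.table` with one row per read: `read_id`, `chrom`,
#'   `start`, `end` (1-based inclusive), `strand`, and optionally `allele`
#'   (hidden truth from the simulator) and sample bookkeeping columns.
#' @param calls `data.table` of per-covered-cytosine conversion calls:
#'   `read_id`, `chrom`, `pos`, `strand`, `meth` (`TRUE` = unconverted,
#'   i.e. methylated-looking).
#' @param snp_obs `data.table` of observed bases at covered SNPs:
#'   `read_id`, `chrom`, `pos`, `base`.
#' @return object of class `bisreads`.
#' @export
bisreads <- function(reads, calls, snp_obs) {
  reads <- as.data.table(reads)
  calls <- as.data.table(calls)
  snp_obs <- as.data.table(snp_obs)
  stopifnot(all(c("read_id", "chrom", "start", "end", "strand") %in%
                  names(reads)),
            all(c("read_id", "chrom", "pos", "strand", "meth") %in%
                  names(calls)),
            all(c("read_id", "chrom", "pos", "base") %in% names(snp_obs)))
  if (anyDuplicated(reads$read_id)) stop("read_id must be unique")
  structure(list(reads = reads, calls = calls, snp_obs = snp_obs),
            class = "bisreads")
}

#' @export
print.bisreads <- function(x, ...) {
  cat(sprintf("<bisreads> %d reads, %d cytosine calls, %d SNP observations\n",
              nrow(x$reads), nrow(x$calls), nrow(x$snp_obs)))
  invisible(x)
}

#' Number of reads in a bisulfite read collection
#' @param x a [bisreads] object.
#' @export
n_reads <- function(x) nrow(x$reads)

#' Write / read simplified bisulfite read records as tab-delimited text
#'
#' One line per read: `chrom`, `start`, `end`, `strand`, `read_id`,
#' semicolon-separated `pos:state` cytosine calls (state `M` unconverted /
#' `U` converted), and semicolon-separated `pos:base` SNP observations
#' (`.` when empty). The hidden `allele` column is preserved when present.
#'
#' @param x a [bisreads] object.
#' @param path output file.
#' @export
write_bisreads <- function(x, path) {
  stopifnot(inherits(x, "bisreads"))
  enc <- function(tab, fmt) {
    if (!nrow(tab)) return(data.table(read_id = integer(0), s = character(0)))
    tab[, .(s = paste(fmt(.SD), collapse = ";")), by = read_id]
  }
  cl <- enc(x$calls, function(sd) paste0(sd$pos, ":",
                                         ifelse(sd$meth, "M", "U")))
  sp <- enc(x$snp_obs, function(sd) paste0(sd$pos, ":", sd$base))
  out <- copy(x$reads)
  out <- merge(out, setnames(cl, "s", "calls"), by = "read_id", all.x = TRUE)
  out <- merge(out, setnames(sp, "s", "snps"), by = "read_id", all.x = TRUE)
  out[is.na(calls), calls := "."]
  out[is.na(snps), snps := "."]
  keep <- intersect(c("chrom", "start", "end", "strand", "read_id", "allele",
                      "calls", "snps"), names(out))
  fwrite(out[, keep, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' @rdname write_bisreads
#' @export
read_bisreads <- function(path) {
  tab <- fread(path, sep = "\t")
  dec <- function(col, parse_val) {
    keep <- which(col != "." & !is.na(col))
    if (!length(keep)) return(NULL)
    parts <- strsplit(col[keep], ";", fixed = TRUE)
    nper <- lengths(parts)
    flat <- unlist(parts)
    kv <- strsplit(flat, ":", fixed = TRUE)
    data.table(row = rep(keep, nper),
               pos = as.integer(vapply(kv, `[`, "", 1L)),
               val = vapply(kv, `[`, "", 2L))
  }
  cl <- dec(tab$calls, identity)
  sp <- dec(tab$snps, identity)
  calls <- if (is.null(cl)) {
    data.table(read_id = integer(0), chrom = character(0), pos = integer(0),
               strand = character(0), meth = logical(0))
  } else {
    data.table(read_id = tab$read_id[cl$row], chrom = tab$chrom[cl$row],
               pos = cl$pos, strand = tab$strand[cl$row], meth = cl$val == "M")
  }
  snp_obs <- if (is.null(sp)) {
    data.table(read_id = integer(0), chrom = character(0), pos = integer(0),
               base = character(0))
  } else {
    data.table(read_id = tab$read_id[sp$row], chrom = tab$chrom[sp$row],
               pos = sp$pos, base = sp$val)
  }
  rd_cols <- intersect(c("read_id", "chrom", "start", "end", "strand",
                         "allele"), names(tab))
  bisreads(tab[, rd_cols, with = FALSE], calls, snp_obs)
}

utils::globalVariables(c("calls", "snps", "s"))
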