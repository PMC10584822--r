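# Per-cytosine methylation calling: context assignment on the reference,
# aggregation of read-level conversion calls into counts, coverage
# filtering, and replicate pooling.

#' Assign the methylation sequence context of a cytosine
#'
#' Plant cytosine methylation is classified by the reference trinucleotide
#' starting at the cytosine on its own strand: `CG` when the next base is a
#' G, `CHG` when the pattern is C-H-G, and `CHH` when it is C-H-H, with
#' H = A, C or T. Minus-strand cytosines are evaluated on the reverse
#' complement, i.e. a plus-strand G whose two preceding bases are read
#' rightwards-complemented.
#'
#' @param sequence a single chromosome sequence (character scalar or
#'   [Biostrings::DNAString]).
#' @param pos integer vector of 1-based positions; each must carry a
#'   cytosine on the requested strand (a C on `+`, a G on `-`).
#' @param strand `"+"` or `"-"`, recycled along `pos`.
#' @return character vector with values `"CG"`, `"CHG"`, `"CHH"`, or `NA`
#'   when the trinucleotide runs off the sequence end or contains a
#'   non-ACGT base (e.g. an N-masked SNP).
#' @examples
#' call_context("ACGTA", 2, "+")  # "CG"
#' call_context("ACAGT", 2, "+")  # "CHG"
#' @export
call_context <- function(sequence, pos, strand = "+") {
  seq_chr <- as.character(sequence)
  stopifnot(length(seq_chr) == 1L)
  n <- nchar(seq_chr)
  if (any(pos < 1L | pos > n)) stop("position outside sequence")
  strand <- rep_len(strand, length(pos))
  b <- strsplit(toupper(seq_chr), "", fixed = TRUE)[[1]]

  b1 <- character(length(pos)); b2 <- b1; b3 <- b1
  plus <- strand == "+"
  if (any(plus)) {
    p <- pos[plus]
    b1[plus] <- b[p]
    b2[plus] <- ifelse(p + 1L <= n, b[pmin(p + 1L, n)], "")
    b3[plus] <- ifelse(p + 2L <= n, b[pmin(p + 2L, n)], "")
  }
  if (any(!plus)) {
    p <- pos[!plus]
    b1[!plus] <- unname(.COMPLEMENT[b[p]])
    b2[!plus] <- ifelse(p - 1L >= 1L, unname(.COMPLEMENT[b[pmax(p - 1L, 1L)]]), "")
    b3[!plus] <- ifelse(p - 2L >= 1L, unname(.COMPLEMENT[b[pmax(p - 2L, 1L)]]), "")
  }
  if (any(b1 != "C", na.rm = TRUE) || anyNA(b1)) {
    stop("base at requested position/strand is not a cytosine")
  }
  .context_from_bases(b2, b3)
}

# classify from the two bases following the cytosine (5'->3' on its strand);
# empty or non-ACGT bases yield NA
.context_from_bases <- function(b2, b3) {
  h <- c("A", "C", "T")
  out <- rep(NA_character_, length(b2))
  out[b2 == "G"] <- "CG"
  chg <- b2 %in% h & b3 == "G"
  out[chg] <- "CHG"
  chh <- b2 %in% h & b3 %in% h
  out[chh] <- "CHH"
  out
}

#' Enumerate all reference cytosines with strand, context and trinucleotide
#'
#' Scans every chromosome of a reference on both strands and returns one
#' row per cytosine whose trinucleotide context is complete and free of
#' ambiguous bases. This is the site scaffold that read-level calls are
#' aggregated onto; on an N-masked reference, cytosines whose trinucleotide
#' includes a masked SNP are absent, so no methylation is reported at them.
#'
#' @param genome named character vector or [Biostrings::DNAStringSet] of
#'   chromosome sequences.
#' @return `data.table` with columns `chrom`, `pos` (1-based), `strand`,
#'   `context`, `trinucleotide`, ordered by chromosome and position.
#' @export
cytosine_sites <- function(genome) {
  g <- .genome_chars(genome)
  per_chrom <- lapply(names(g), function(ch) {
    b <- strsplit(toupper(g[[ch]]), "", fixed = TRUE)[[1]]
    n <- length(b)
    # plus strand: C at pos, context from pos+1, pos+2
    ip <- which(b == "C")
    ip <- ip[ip + 2L <= n]
    tp <- if (length(ip)) paste0(b[ip], b[ip + 1L], b[ip + 2L]) else character(0)
    cxp <- .context_from_bases(b[ip + 1L], b[ip + 2L])
    # minus strand: G at pos, context from complemented pos-1, pos-2
    im <- which(b == "G")
    im <- im[im - 2L >= 1L]
    cm2 <- unname(.COMPLEMENT[b[pmax(im - 1L, 1L)]])
    cm3 <- unname(.COMPLEMENT[b[pmax(im - 2L, 1L)]])
    tm <- if (length(im)) paste0("C", cm2, cm3) else character(0)
    cxm <- .context_from_bases(cm2, cm3)
    dt <- data.table(
      chrom = ch,
      pos = c(ip, im),
      strand = rep(c("+", "-"), c(length(ip), length(im))),
      context = c(cxp, cxm),
      trinucleotide = c(tp, tm)
    )
    dt[!is.na(context)]
  })
  out <- rbindlist(per_chrom)
  setorder(out, chrom, pos, strand)
  out[]
}

#' Aggregate read-level conversion calls into per-cytosine counts
#'
#' Each bisulfite read reports, for every cytosine it covers on its own
#' strand, whether the base was unconverted (methylated-looking) or
#' converted. This tallies those calls per reference cytosine: `n_meth`
#' counts unconverted observations and `n_unmeth` converted ones. Calls at
#' positions that are not context-complete cytosines of the supplied
#' reference (for instance inside an N-masked trinucleotide) are dropped.
#' Reads whose interval falls outside the reference are rejected; their
#' number is recorded in the `n_rejected` attribute of the result.
#'
#' @param reads a [bisreads] object.
#' @param reference reference genome the reads are aligned to (the
#'   N-masked genome in allele-aware workflows).
#' @param keep_zero if `TRUE`, emit zero-count rows for covered-context
#'   cytosines with no observations; default drops them.
#' @return `data.table` of cytosine sites with columns `chrom`, `pos`,
#'   `strand`, `context`, `trinucleotide`, `n_meth`, `n_unmeth`.
#' @export
extract_cytosine_counts <- function(reads, reference, keep_zero = FALSE) {
  stopifnot(inherits(reads, "bisreads"))
  sizes <- .chrom_sizes(reference)
  rd <- reads$reads
  ok <- rd$chrom %in% names(sizes) &
    rd$start >= 1L & rd$end <= sizes[rd$chrom]
  n_rejected <- sum(!ok)
  calls <- reads$calls[read_id %in% rd$read_id[ok]]

  template <- cytosine_sites(reference)
  if (nrow(calls) == 0L) {
    out <- template[0L]
    out[, c("n_meth", "n_unmeth") := list(integer(0), integer(0))]
  } else {
    counts <- calls[, .(n_meth = sum(meth), n_unmeth = sum(!meth)),
                    by = .(chrom, pos, strand)]
    out <- merge(template, counts, by = c("chrom", "pos", "strand"),
                 all.x = keep_zero, all.y = FALSE)
    if (keep_zero) {
      out[is.na(n_meth), c("n_meth", "n_unmeth") := list(0L, 0L)]
    }
  }
  setorder(out, chrom, pos, strand)
  setattr(out, "n_rejected", n_rejected)
  out[]
}

#' Retain cytosines with sufficient sequencing depth
#'
#' Individual cytosines covered by at least `min_depth` reads are retained
#' for methylation-level calculation; the default of 3 is the conventional
#' coverage floor for low-input bisulfite libraries.
#'
#' @param sites cytosine site table from [extract_cytosine_counts()].
#' @param min_depth minimum `n_meth + n_unmeth` (default 3).
#' @return the filtered site table.
#' @export
filter_coverage <- function(sites, min_depth = 3L) {
  stopifnot(min_depth >= 1L)
  sites[(n_meth + n_unmeth) >= min_depth]
}

#' Pool cytosine counts across biological replicates
#'
#' In `"sum"` mode (the default, used by all downstream testing) the
#' methylated/unmethylated counts are summed per site. In `"mean_level"`
#' mode the per-replicate methylation levels are averaged over replicates
#' with positive depth, which is the quantity typically displayed in
#' figure-style summaries; the result carries a `level` column instead of
#' counts.
#'
#' @param site_list list of cytosine site tables, one per replicate, all
#'   from the same reference.
#' @param mode `"sum"` or `"mean_level"`.
#' @return pooled site table.
#' @export
pool_replicates <- function(site_list, mode = c("sum", "mean_level")) {
  mode <- match.arg(mode)
  stopifnot(is.list(site_list), length(site_list) >= 1L)
  if (length(site_list) == 1L && mode == "sum") return(copy(site_list[[1L]]))
  all_sites <- rbindlist(site_list, idcol = "rep_id")
  if (mode == "sum") {
    out <- all_sites[, .(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
                     by = .(chrom, pos, strand, context, trinucleotide)]
  } else {
    out <- all_sites[(n_meth + n_unmeth) > 0L,
                     .(level = mean(n_meth / (n_meth + n_unmeth)),
                       n_replicates = .N),
                     by = .(chrom, pos, strand, context, trinucleotide)]
  }
  setorder(out, chrom, pos, strand)
  out[]
}

#' Add a methylation-level column
#'
#' @param sites cytosine site table with `n_meth`/`n_unmeth` columns.
#' @return the same table with a `level = n_meth / (n_meth + n_unmeth)`
#'   column (`NA` at zero depth).
#' @export
meth_level <- function(sites) {
  out <- copy(sites)
  out[, level := fifelse(n_meth + n_unmeth > 0L,
                         n_meth / (n_meth + n_unmeth), NA_real_)]
  out[]
}
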