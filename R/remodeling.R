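# Tracking egg-sperm DMRs into the hybrid zygote / embryo: allelic
# methylation at those DMRs, per-DMR remodeling classification, the
# least-squares remodeling-coefficient estimator, and stage contrasts.

#' Call egg-versus-sperm DMRs
#'
#' Thin delegation to [call_dmrs()] with the egg as sample 1, so that
#' `hyper` means egg methylation exceeds sperm methylation.
#'
#' @param egg_sites,sperm_sites gamete cytosine site tables (replicates
#'   pooled by counts).
#' @param ... passed to [call_dmrs()].
#' @return DMR table; `m1` is the egg level, `m2` the sperm level.
#' @export
select_es_dmrs <- function(egg_sites, sperm_sites, ...) {
  call_dmrs(egg_sites, sperm_sites, ...)
}

#' Allelic methylation of a hybrid sample at egg-sperm DMRs
#'
#' For every egg-sperm DMR, pools the maternal-allele and paternal-allele
#' counts of the hybrid sample over the DMR's context cytosines (each
#' cytosine already passed the allele-specific coverage rule) and reports
#' the allelic levels next to the egg and sperm levels. A DMR with fewer
#' than `min_sites_allelic` testable cytosines on either allele is
#' `untestable`. Each testable DMR is classified by where the paternal
#' allele sits: `maternal_match` when it lies within `match_tol` of the
#' egg level while at least `mismatch_gap` from the sperm level,
#' `paternal_match` mirrored, otherwise `intermediate`.
#'
#' @param dmrs egg-sperm DMR table from [select_es_dmrs()].
#' @param maternal_profile,paternal_profile allele-specific site tables
#'   of the hybrid sample (see [allelic_profiles()]).
#' @param sample_sites optional bulk (non-allelic) site table of the same
#'   hybrid sample; adds an `m_total` column.
#' @param min_sites_allelic minimum testable cytosines per allele per DMR
#'   (default 3).
#' @param match_tol,mismatch_gap classification thresholds (defaults 0.1
#'   and 0.2).
#' @param stage label stored on the output (`zygote`, `two_cell`,
#'   `globular_embryo`, ...).
#' @return `data.table` of remodeling-summary rows: DMR fields, `m_egg`,
#'   `m_sperm`, `m_mat`, `m_pat`, allelic depths and site counts,
#'   `testable`, `class_call`, `stage`.
#' @export
allelic_levels_at_dmrs <- function(dmrs, maternal_profile, paternal_profile,
                                   sample_sites = NULL,
                                   min_sites_allelic = 3L,
                                   match_tol = 0.1,
                                   mismatch_gap = 0.2,
                                   stage = "zygote") {
  out <- dmrs[, .(chrom, start, end, context, direction,
                  m_egg = m1, m_sperm = m2)]
  out[, dmr_id := .I]
  pool_over_dmrs <- function(profile, prefix) {
    cols <- c(sprintf("m_%s", prefix), sprintf("depth_%s", prefix),
              sprintf("n_sites_%s", prefix))
    if (is.null(profile) || !nrow(profile)) {
      out[, (cols) := list(NA_real_, 0L, 0L)]
      return(invisible(NULL))
    }
    p <- profile[, .(chrom, pos, context, n_meth, n_unmeth)]
    hits <- p[out, on = c("chrom", "context", "pos>=start", "pos<=end"),
              nomatch = NULL,
              .(dmr_id, n_meth = x.n_meth, n_unmeth = x.n_unmeth)]
    agg <- hits[, .(m = sum(n_meth) / sum(n_meth + n_unmeth),
                    d = sum(n_meth + n_unmeth), ns = .N), by = dmr_id]
    out[, (cols) := list(NA_real_, 0L, 0L)]
    out[agg, on = "dmr_id", (cols) := list(i.m, i.d, i.ns)]
    invisible(NULL)
  }
  # join columns pos>=start use 1-based positions against 0-based
  # half-open windows: a site at pos p (1-based) is inside [start, end)
  # iff start < p <= end, handled by shifting start below
  out[, start := start + 1L]  # temporarily 1-based inclusive for the join
  pool_over_dmrs(maternal_profile, "mat")
  pool_over_dmrs(paternal_profile, "pat")
  if (!is.null(sample_sites)) pool_over_dmrs(sample_sites, "total")
  out[, start := start - 1L]
  out[, testable := n_sites_mat >= min_sites_allelic &
        n_sites_pat >= min_sites_allelic]
  out[, class_call := fifelse(!testable, "untestable",
    fifelse(abs(m_pat - m_egg) < match_tol &
              abs(m_pat - m_sperm) >= mismatch_gap, "maternal_match",
     fifelse(abs(m_pat - m_sperm) < match_tol &
               abs(m_pat - m_egg) >= mismatch_gap, "paternal_match",
             "intermediate")))]
  out[, stage := stage]
  out[, dmr_id := NULL]
  out[]
}

#' Estimate the paternal remodeling coefficient
#'
#' The remodeling coefficient rho is the fraction by which the paternal
#' allele's methylation has moved from the sperm level toward the egg
#' level (`m_pat = rho * m_egg + (1 - rho) * m_sperm`; 1 = full maternal
#' match, 0 = no remodeling). It is estimated by depth-weighted least
#' squares over testable DMRs with an egg-sperm gap of at least
#' `min_gap`:
#' `rho_hat = sum(w (m_pat - m_sperm)(m_egg - m_sperm)) /
#'            sum(w (m_egg - m_sperm)^2)`,
#' with weights `w` the paternal allelic depth, clipped to `[0, 1]`.
#' A percentile bootstrap over DMRs provides the confidence interval.
#'
#' @param summary_rows output of [allelic_levels_at_dmrs()].
#' @param context restrict to one context (`NULL` uses all rows; the
#'   estimator is intended for CG and CHG).
#' @param min_dmrs minimum testable, sufficiently-contrasted DMRs
#'   (default 20); fewer is an error.
#' @param min_gap minimum `|m_egg - m_sperm|` for a DMR to enter the
#'   estimator (default 0.2).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return list with `rho` (point estimate), `ci` (length-2 vector),
#'   `n` (DMRs used), `context`.
#' @export
estimate_rho <- function(summary_rows, context = NULL,
                         min_dmrs = 20L, min_gap = 0.2,
                         n_boot = 1000L, seed = 1L, conf = 0.95) {
  rows <- summary_rows[testable == TRUE]
  if (!is.null(context)) {
    cx <- context
    rows <- rows[rows$context == cx]
  }
  rows <- rows[abs(m_egg - m_sperm) >= min_gap]
  if (nrow(rows) < min_dmrs) {
    stop(sprintf(
      "insufficient testable DMRs for rho estimation: %d < %d",
      nrow(rows), min_dmrs))
  }
  x <- rows$m_egg - rows$m_sperm
  y <- rows$m_pat - rows$m_sperm
  w <- pmax(rows$depth_pat, 1L)
  point <- function(idx) {
    r <- sum(w[idx] * y[idx] * x[idx]) / sum(w[idx] * x[idx]^2)
    min(max(r, 0), 1)
  }
  rho_hat <- point(seq_along(x))
  boot <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      point(sample.int(length(x), replace = TRUE))
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  ci[1] <- min(ci[1], rho_hat)
  ci[2] <- max(ci[2], rho_hat)
  list(rho = rho_hat, ci = ci, n = nrow(rows),
       context = if (is.null(context)) NA_character_ else context)
}

#' Contrast remodeling between developmental stages
#'
#' Estimates rho per context for each stage's remodeling summary (e.g.
#' zygote versus globular embryo) and reports the CHH lower-parent
#' statistic, `mean(m_sample - min(m_egg, m_sperm))` over CHH DMRs, where
#' `m_sample` is the bulk sample level (`m_total` when available,
#' otherwise the depth-weighted mean of the two allelic levels).
#'
#' @param summaries named list of remodeling summaries, one per stage
#'   (names are the stage labels).
#' @param contexts contexts for rho estimation (default CG and CHG).
#' @param ... passed to [estimate_rho()].
#' @return list with `rho_table` (`stage`, `context`, `rho`, `ci_lo`,
#'   `ci_hi`, `n`) and `chh_lower_parent` (named numeric, one per stage;
#'   `NA` when the stage has no testable CHH DMRs).
#' @export
compare_stages <- function(summaries, contexts = c("CG", "CHG"), ...) {
  stopifnot(is.list(summaries), !is.null(names(summaries)))
  rows <- list()
  chh <- stats::setNames(rep(NA_real_, length(summaries)), names(summaries))
  for (st in names(summaries)) {
    sm <- summaries[[st]]
    for (cx in contexts) {
      est <- estimate_rho(sm, context = cx, ...)
      rows[[paste(st, cx)]] <- data.table(
        stage = st, context = cx, rho = est$rho,
        ci_lo = est$ci[1], ci_hi = est$ci[2], n = est$n)
    }
    ch <- sm[testable == TRUE & context == "CHH"]
    if (nrow(ch)) {
      m_sample <- if ("m_total" %in% names(ch) && !anyNA(ch$m_total)) {
        ch$m_total
      } else {
        (ch$m_mat * ch$depth_mat + ch$m_pat * ch$depth_pat) /
          (ch$depth_mat + ch$depth_pat)
      }
      chh[[st]] <- mean(m_sample - pmin(ch$m_egg, ch$m_sperm))
    }
  }
  list(rho_table = rbindlist(rows), chh_lower_parent = chh)
}

utils::globalVariables(c("x.n_meth", "x.n_unmeth", "i.d", "i.ns",
                         "depth_total", "n_sites_total", "ci_lo", "ci_hi"))
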