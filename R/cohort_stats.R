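# Cohort-level aggregation and the study's statistical comparisons.
#
# Proportion metrics (percent of clones with large deletions, insertions,
# microhomology, MMEJ) are compared with the pooled two-proportion z
# statistic -- the "two-sample t-test between percents" of desktop
# calculators is exactly this pooled z. Size metrics (mean deletion and
# insertion sizes) use the classical pooled-variance unpaired t test.

#' Summarise a cohort of repair events
#'
#' @param events events table from [batch_analyze()] (or the list it
#'   returns). Killer-exon-retention events are excluded before summarising.
#' @param params the [call_params()] used to call the events (supplies the
#'   MMEJ range).
#' @param large_del_threshold deletions are categorised small
#'   (1..threshold) versus large (> threshold); default 500 bp, so a 500-bp
#'   deletion is small and 501 bp is large.
#' @param mh_cap upper microhomology length counted in the percent-with-MH
#'   and percent-MMEJ metrics; defaults to the longest microhomology the
#'   construct offers (`Inf` = no cap).
#' @param include_zeros if TRUE, `mean_del`/`mean_ins` average over all
#'   junctions; default FALSE averages only over junctions exhibiting the
#'   feature (zero-feature cohorts report `NA`, not 0).
#' @param cohort label carried into the summary.
#' @return object of class `cohort_summary`: `cohort`, `n_junctions`,
#'   `mean_del`, `pct_large_del`, `mean_ins`, `pct_with_ins`, `pct_mh`,
#'   `pct_mmej` (percents in 0..100).
#' @export
summarize_cohort <- function(events, params = call_params(),
                             large_del_threshold = 500L, mh_cap = Inf,
                             include_zeros = FALSE, cohort = "cohort") {
  if (is.list(events) && !is.data.frame(events) && !is.null(events$events)) {
    events <- events$events
  }
  stopifnot(is.data.frame(events))
  events <- events[!events$ad_retained, , drop = FALSE]
  n <- nrow(events)
  if (n < 1L) .stop_nhej("no events to summarise", "nhej_stats_error")

  del <- events$del_total
  ins <- events$insertion_len
  mh <- events$mh_len

  mean_of <- function(x, has) {
    if (include_zeros) return(mean(x))
    if (!any(has)) NA_real_ else mean(x[has])
  }

  structure(
    list(cohort = cohort, n_junctions = n,
         mean_del = mean_of(del, del >= 1L),
         pct_large_del = 100 * mean(del > large_del_threshold),
         mean_ins = mean_of(ins, ins >= 1L),
         pct_with_ins = 100 * mean(ins >= 1L),
         pct_mh = 100 * mean(mh >= 1L & mh <= mh_cap),
         pct_mmej = 100 * mean(mh >= params$mmej_min & mh <= mh_cap),
         large_del_threshold = large_del_threshold,
         mmej_min = params$mmej_min, mh_cap = mh_cap,
         include_zeros = include_zeros),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort '%s': %d junctions\n", x$cohort, x$n_junctions))
  cat(sprintf("  mean deletion %s bp; %.1f%% with deletions > %d bp\n",
              if (is.na(x$mean_del)) "NA" else sprintf("%.1f", x$mean_del),
              x$pct_large_del, x$large_del_threshold))
  cat(sprintf("  mean insertion %s bp; %.1f%% with insertions\n",
              if (is.na(x$mean_ins)) "NA" else sprintf("%.1f", x$mean_ins),
              x$pct_with_ins))
  cat(sprintf("  %.1f%% with microhomology; %.1f%% MMEJ (MH >= %d bp)\n",
              x$pct_mh, x$pct_mmej, x$mmej_min))
  invisible(x)
}

#' @export
as.data.frame.cohort_summary <- function(x, ...) {
  data.frame(cohort = x$cohort, n_junctions = x$n_junctions,
             mean_del = x$mean_del, pct_large_del = x$pct_large_del,
             mean_ins = x$mean_ins, pct_with_ins = x$pct_with_ins,
             pct_mh = x$pct_mh, pct_mmej = x$pct_mmej,
             stringsAsFactors = FALSE)
}

.new_test <- function(statistic, p_value, n1, n2, estimate1, estimate2,
                      method, degenerate = FALSE) {
  structure(list(statistic = statistic, p_value = p_value, n1 = n1, n2 = n2,
                 estimate1 = estimate1, estimate2 = estimate2,
                 method = method, degenerate = degenerate),
            class = "nhej_test")
}

#' Pooled two-proportion z test ("t test between percents")
#'
#' `z = (p1 - p2) / sqrt(phat (1 - phat) (1/n1 + 1/n2))` with
#' `phat = (x1 + x2) / (n1 + n2)`; two-sided p from the normal reference
#' distribution. Antisymmetric in group order. When the pooled proportion is
#' 0 or 1 the statistic degenerates to 0 with p = 1 (flagged).
#'
#' @param x1,n1 successes and size in group 1.
#' @param x2,n2 successes and size in group 2.
#' @return object of class `nhej_test`.
#' @export
two_proportion_test <- function(x1, n1, x2, n2) {
  if (n1 < 1L || n2 < 1L || x1 < 0L || x2 < 0L || x1 > n1 || x2 > n2) {
    .stop_nhej("require 0 <= x <= n and n >= 1 in both groups",
               "nhej_stats_error")
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  phat <- (x1 + x2) / (n1 + n2)
  if (phat <= 0 || phat >= 1) {
    return(.new_test(0, 1, n1, n2, p1, p2, "two_proportion",
                     degenerate = TRUE))
  }
  z <- (p1 - p2) / sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  .new_test(z, 2 * stats::pnorm(-abs(z)), n1, n2, p1, p2, "two_proportion")
}

#' Classical pooled-variance unpaired t test
#'
#' Two-sample t with `n1 + n2 - 2` degrees of freedom, two-sided p. With zero
#' pooled variance: equal means give t = 0, p = 1; unequal means are flagged
#' degenerate (infinite statistic, p = 0).
#'
#' @param sample1,sample2 numeric vectors, each of length >= 2.
#' @return object of class `nhej_test`.
#' @export
unpaired_t_test <- function(sample1, sample2) {
  sample1 <- as.numeric(sample1)
  sample2 <- as.numeric(sample2)
  n1 <- length(sample1)
  n2 <- length(sample2)
  if (n1 < 2L || n2 < 2L) {
    .stop_nhej("each sample needs >= 2 values", "nhej_stats_error")
  }
  m1 <- mean(sample1)
  m2 <- mean(sample2)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1L) * stats::var(sample1) +
          (n2 - 1L) * stats::var(sample2)) / df
  if (sp2 <= 0) {
    if (m1 == m2) return(.new_test(0, 1, n1, n2, m1, m2, "unpaired_t"))
    return(.new_test(sign(m1 - m2) * Inf, 0, n1, n2, m1, m2, "unpaired_t",
                     degenerate = TRUE))
  }
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  .new_test(t, 2 * stats::pt(-abs(t), df), n1, n2, m1, m2, "unpaired_t")
}

#' @export
print.nhej_test <- function(x, ...) {
  lab <- c(two_proportion = "pooled two-proportion z test",
           one_proportion = "one-proportion z test vs fixed null",
           unpaired_t = "pooled-variance unpaired t test")[x$method]
  cat(sprintf("%s\n  statistic = %.4g, p = %.4g (n = %s%s)\n", lab,
              x$statistic, x$p_value, x$n1,
              if (is.na(x$n2)) "" else paste0("/", x$n2)))
  cat(sprintf("  estimates: %.4g vs %.4g%s\n", x$estimate1, x$estimate2,
              if (isTRUE(x$degenerate)) "  [degenerate]" else ""))
  invisible(x)
}

#' Read a FACS count table
#'
#' TSV with columns `sample`, `n_total`, `n_gfp`, `n_dsred` (one row per
#' transfection).
#'
#' @param path path to the TSV.
#' @return validated data.frame of class `facs_counts`.
#' @export
read_facs <- function(path) {
  if (!file.exists(path)) {
    .stop_nhej(sprintf("FACS table not found: %s", path), "nhej_facs_error")
  }
  df <- .read_tsv(path)
  validate_facs(df)
}

#' Validate a FACS count table
#'
#' @param df data.frame with columns `sample`, `n_total`, `n_gfp`,
#'   `n_dsred`.
#' @return the data.frame, classed `facs_counts`.
#' @export
validate_facs <- function(df) {
  need <- c("sample", "n_total", "n_gfp", "n_dsred")
  if (!all(need %in% names(df))) {
    .stop_nhej(sprintf("FACS table needs columns: %s",
                       paste(need, collapse = ", ")), "nhej_facs_error")
  }
  if (any(df$n_gfp > df$n_total) || any(df$n_dsred > df$n_total) ||
      any(df$n_gfp < 0) || any(df$n_dsred < 0)) {
    .stop_nhej("FACS counts must satisfy 0 <= n_gfp, n_dsred <= n_total",
               "nhej_facs_error")
  }
  class(df) <- c("facs_counts", "data.frame")
  df
}

#' NHEJ efficiency from FACS counts
#'
#' Efficiency of each transfection is the ratio of GFP-positive to
#' DsRed-positive cells (DsRed normalises for transfection efficiency).
#'
#' @param counts a `facs_counts` data.frame (see [read_facs()]), or a list
#'   with `n_gfp` and `n_dsred`.
#' @return numeric vector of per-transfection ratios (named by sample when
#'   available).
#' @export
nhej_efficiency <- function(counts) {
  if (is.data.frame(counts)) counts <- validate_facs(counts)
  if (any(counts$n_dsred <= 0)) {
    .stop_nhej("n_dsred must be > 0: efficiency is undefined without transfected cells",
               "nhej_facs_error")
  }
  r <- counts$n_gfp / counts$n_dsred
  if (!is.null(counts$sample)) names(r) <- counts$sample
  r
}

#' Mean and standard error of replicate efficiencies
#'
#' @param ratios numeric vector of per-transfection efficiencies.
#' @return list with `mean`, `sem`, `n`.
#' @export
efficiency_summary <- function(ratios) {
  n <- length(ratios)
  list(mean = mean(ratios),
       sem = if (n > 1L) stats::sd(ratios) / sqrt(n) else NA_real_,
       n = n)
}

#' Fold change of NHEJ efficiency between two cohorts
#'
#' @param young,old numeric vectors of replicate efficiencies.
#' @return `mean(young) / mean(old)`.
#' @export
fold_change <- function(young, old) {
  if (length(young) < 1L || length(old) < 1L) {
    .stop_nhej("both cohorts must be non-empty", "nhej_stats_error")
  }
  m_old <- mean(old)
  if (m_old <= 0) {
    .stop_nhej("mean(old) must be > 0 for a fold change", "nhej_stats_error")
  }
  mean(young) / m_old
}

#' Compare two cohorts metric by metric
#'
#' Emits, for each of the six panel metrics, the young and old values, the
#' test statistic and p value, and a significance mark at alpha = 0.05.
#' Proportion metrics use [two_proportion_test()]; size metrics use
#' [unpaired_t_test()] on per-junction sizes among feature-bearing
#' junctions. No multiple-testing correction is applied (per-metric alpha,
#' matching the assay's reporting convention); pass `p_adjust = "BH"` for
#' Benjamini-Hochberg.
#'
#' @param young_events,old_events events tables from [batch_analyze()],
#'   called with the same parameters.
#' @param params the shared [call_params()].
#' @param large_del_threshold,mh_cap,include_zeros as in
#'   [summarize_cohort()].
#' @param alpha significance level for the `significant` mark.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame with columns `metric`, `young`, `old`, `statistic`,
#'   `p_value`, `method`, `significant`.
#' @export
compare_cohorts <- function(young_events, old_events, params = call_params(),
                            large_del_threshold = 500L, mh_cap = Inf,
                            include_zeros = FALSE, alpha = 0.05,
                            p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  get_ev <- function(x) {
    if (is.list(x) && !is.data.frame(x) && !is.null(x$events)) x <- x$events
    x[!x$ad_retained, , drop = FALSE]
  }
  ye <- get_ev(young_events)
  oe <- get_ev(old_events)
  ys <- summarize_cohort(ye, params, large_del_threshold, mh_cap,
                         include_zeros, cohort = "young")
  os <- summarize_cohort(oe, params, large_del_threshold, mh_cap,
                         include_zeros, cohort = "old")
  n1 <- nrow(ye)
  n2 <- nrow(oe)

  prop_row <- function(metric, flag_y, flag_o, vy, vo) {
    tt <- two_proportion_test(sum(flag_y), n1, sum(flag_o), n2)
    data.frame(metric = metric, young = vy, old = vo,
               statistic = tt$statistic, p_value = tt$p_value,
               method = tt$method, stringsAsFactors = FALSE)
  }
  size_row <- function(metric, x_y, x_o, vy, vo) {
    if (length(x_y) >= 2L && length(x_o) >= 2L) {
      tt <- unpaired_t_test(x_y, x_o)
      data.frame(metric = metric, young = vy, old = vo,
                 statistic = tt$statistic, p_value = tt$p_value,
                 method = tt$method, stringsAsFactors = FALSE)
    } else {
      data.frame(metric = metric, young = vy, old = vo,
                 statistic = NA_real_, p_value = NA_real_,
                 method = "unpaired_t", stringsAsFactors = FALSE)
    }
  }
  del_y <- ye$del_total[if (include_zeros) TRUE else ye$del_total >= 1L]
  del_o <- oe$del_total[if (include_zeros) TRUE else oe$del_total >= 1L]
  ins_y <- ye$insertion_len[if (include_zeros) TRUE else ye$insertion_len >= 1L]
  ins_o <- oe$insertion_len[if (include_zeros) TRUE else oe$insertion_len >= 1L]

  out <- rbind(
    size_row("mean_del", del_y, del_o, ys$mean_del, os$mean_del),
    prop_row("pct_large_del",
             ye$del_total > large_del_threshold,
             oe$del_total > large_del_threshold,
             ys$pct_large_del, os$pct_large_del),
    size_row("mean_ins", ins_y, ins_o, ys$mean_ins, os$mean_ins),
    prop_row("pct_with_ins", ye$insertion_len >= 1L, oe$insertion_len >= 1L,
             ys$pct_with_ins, os$pct_with_ins),
    prop_row("pct_mh", ye$mh_len >= 1L & ye$mh_len <= mh_cap,
             oe$mh_len >= 1L & oe$mh_len <= mh_cap,
             ys$pct_mh, os$pct_mh),
    prop_row("pct_mmej",
             ye$mh_len >= params$mmej_min & ye$mh_len <= mh_cap,
             oe$mh_len >= params$mmej_min & oe$mh_len <= mh_cap,
             ys$pct_mmej, os$pct_mmej))
  if (p_adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  rownames(out) <- NULL
  out
}
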