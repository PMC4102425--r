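# Random-joining null model.
#
# If broken ends are joined at random within the intron, how often does the
# resulting junction *look* microhomology-mediated? We enumerate every
# breakpoint pair (i on the left flank within the 5' detection window, j on
# the right flank within the 3' window), score the apparent microhomology of
# each joint, and tabulate the uniform-over-pairs distribution. This is the
# "expected by chance" baseline against which observed cohorts are tested.

#' Apparent microhomology at a deletion junction (one-sided primitive)
#'
#' The junction retains `ref[1..i]` and `ref[j..n]`. Returns the largest k
#' (0 <= k <= j - i - 1) with `ref[(i-k+1)..i] == ref[(j-k)..(j-1)]`: the
#' homology tract ending at the retained left end, bounded by the deleted
#' span so microhomology never exceeds deletion size.
#'
#' Note this scores one fixed breakpoint representation. A junction *product*
#' is invariant under sliding the breakpoints across the homology tract; the
#' caller ([call_junction()]) and the null tabulation
#' ([random_joining_distribution()] with `two_sided = TRUE`, the default)
#' therefore score the full tract (backward plus forward extension).
#'
#' @param i left breakpoint: last retained base of `ref` on the left.
#' @param j right start: first retained base on the right; requires `j > i`
#'   with `j - i - 1` the deleted span.
#' @param ref DNA string.
#' @return microhomology length in bp.
#' @export
apparent_mh <- function(i, j, ref) {
  .check_dna(ref, "ref")
  i <- as.integer(i); j <- as.integer(j)
  n <- nchar(ref)
  if (j <= i) {
    .stop_nhej("j <= i: not a deletion junction", "nhej_null_error")
  }
  if (i < 1L || j > n + 1L) {
    .stop_nhej("breakpoints outside 1 <= i < j <= len(ref) + 1",
               "nhej_null_error")
  }
  rw <- charToRaw(ref)
  kmax <- min(j - i - 1L, i)
  k <- 0L
  while (k < kmax) {
    x <- rw[i - k]
    if (x != rw[j - 1L - k] || x == .N_BYTE) break
    k <- k + 1L
  }
  k
}

# Enumerate the per-pair microhomology matrix over the detection window.
# Rows: i = (c - w5)..c (retained left end), cols: j = (c+1)..(c+1+w3)
# (retained right start) on ref = left_flank + right_flank, c = cut
# coordinate. Backward extension is capped at the right flank (t <= j-c-1)
# and forward extension at the left flank (t <= c-i), exactly as the caller's
# flank-anchored matches are; together these enforce mh <= deleted span.
.mh_pair_matrix <- function(cutref, window, two_sided = TRUE) {
  stopifnot(inherits(cutref, "cut_reference"),
            inherits(window, "detection_window"))
  cc <- cutref$cut_coordinate
  ref <- paste0(cutref$left_flank, cutref$right_flank)
  n <- nchar(ref)
  w5 <- window$max_del_5prime
  w3 <- window$max_del_3prime
  if (w5 >= cc || w3 >= n - cc) {
    .stop_nhej("detection window exceeds the flanks", "nhej_null_error")
  }
  code <- as.integer(charToRaw(ref))
  a_enc <- ifelse(code == 78L, -1L, code) # N on one side ...
  b_enc <- ifelse(code == 78L, -2L, code) # ... never equals N on the other

  I <- (cc - w5):cc
  J <- (cc + 1L):(cc + 1L + w3)
  ni <- length(I)
  nj <- length(J)

  extend <- function(backward) {
    acc <- matrix(0L, ni, nj)
    alive <- matrix(TRUE, ni, nj)
    t <- 1L
    repeat {
      if (backward) {
        li <- I - t + 1L
        rj <- J - t
        okr <- li >= 1L
        okc <- rj >= cc + 1L
      } else {
        li <- I + t
        rj <- J + t - 1L
        okr <- li <= cc
        okc <- rj <= n
      }
      if (!any(okr) || !any(okc)) break
      eq <- matrix(FALSE, ni, nj)
      eq[okr, okc] <- outer(a_enc[li[okr]], b_enc[rj[okc]], "==")
      alive <- alive & eq
      if (!any(alive)) break
      acc <- acc + alive
      t <- t + 1L
    }
    acc
  }

  mh <- extend(backward = TRUE)
  if (two_sided) mh <- mh + extend(backward = FALSE)
  list(I = I, J = J, mh = mh, cut = cc, ref = ref)
}

#' Exhaustive random-joining microhomology distribution
#'
#' Enumerates every breakpoint pair within the primer-rescuable window
#' (only such junctions are observable; pass a full-flank window for a
#' whole-intron null) and tabulates apparent microhomology uniformly over
#' pairs. Deterministic.
#'
#' @param cutref a [derive_cut_reference()] result.
#' @param window a [detection_window()].
#' @param include_blunt include the single zero-deletion (blunt re-ligation)
#'   pair. Default FALSE: apparent microhomology is undefined without a
#'   deleted span, so the null enumerates deletion junctions only.
#' @param two_sided score the full homology tract of each junction product
#'   (what the caller reports). `FALSE` scores only the backward extension at
#'   the enumerated representation ([apparent_mh()] literally).
#' @return object of class `mh_null`: `probs` (named vector over m = 0,1,...,
#'   summing to 1), `n_pairs`, `p_mh_ge` (named, P(MH >= k) for k = 1..max),
#'   `max_mh`.
#' @export
random_joining_distribution <- function(cutref, window,
                                        include_blunt = FALSE,
                                        two_sided = TRUE) {
  pm <- .mh_pair_matrix(cutref, window, two_sided = two_sided)
  vals <- as.vector(pm$mh)
  if (!include_blunt) {
    # blunt pair: i = cut (last row), j = cut + 1 (first column)
    blunt_idx <- (1L - 1L) * length(pm$I) + length(pm$I)
    vals <- vals[-blunt_idx]
  }
  n_pairs <- length(vals)
  if (n_pairs == 0L) {
    .stop_nhej("empty detection window: no breakpoint pairs to enumerate",
               "nhej_null_error")
  }
  max_mh <- max(vals)
  counts <- tabulate(vals + 1L, nbins = max_mh + 1L)
  probs <- counts / n_pairs
  names(probs) <- 0:max_mh
  p_ge <- if (max_mh >= 1L) rev(cumsum(rev(probs[-1L]))) else numeric(0)
  structure(
    list(probs = probs, n_pairs = n_pairs, p_mh_ge = p_ge, max_mh = max_mh,
         window = window, two_sided = two_sided,
         include_blunt = include_blunt),
    class = "mh_null")
}

#' Longest microhomology achievable in the construct
#'
#' @inheritParams random_joining_distribution
#' @return bp; the longest apparent microhomology over all enumerated
#'   breakpoint pairs.
#' @export
longest_mh <- function(cutref, window, two_sided = TRUE) {
  random_joining_distribution(cutref, window, two_sided = two_sided)$max_mh
}

#' Per-pair enumeration table
#'
#' The raw enumeration behind [random_joining_distribution()]: one row per
#' breakpoint pair with its deleted span and apparent microhomology. The
#' simulator samples MMEJ junctions from this table.
#'
#' @inheritParams random_joining_distribution
#' @return data.frame with columns `i`, `j`, `span`, `mh`.
#' @export
mh_pair_table <- function(cutref, window, include_blunt = FALSE,
                          two_sided = TRUE) {
  pm <- .mh_pair_matrix(cutref, window, two_sided = two_sided)
  df <- data.frame(
    i = rep(pm$I, times = length(pm$J)),
    j = rep(pm$J, each = length(pm$I)),
    mh = as.vector(pm$mh))
  df$span <- df$j - df$i - 1L
  if (!include_blunt) df <- df[df$span > 0L, , drop = FALSE]
  rownames(df) <- NULL
  df[, c("i", "j", "span", "mh")]
}

#' Test observed microhomology usage against the random-joining null
#'
#' One-sample test on a percent: compares the observed fraction of junctions
#' with `mh_len >= k_min` against the null expectation `p_mh_ge[k_min]`,
#' using the normal-reference statistic
#' `z = (p_obs - p0) / sqrt(p0 (1 - p0) / n)`.
#'
#' @param events events table from [batch_analyze()] (killer-exon-retention
#'   events are excluded).
#' @param null an `mh_null` from [random_joining_distribution()].
#' @param k_min minimum microhomology length counted (default 1: any
#'   microhomology).
#' @return object of class `nhej_test`.
#' @export
mh_excess_test <- function(events, null, k_min = 1L) {
  stopifnot(inherits(null, "mh_null"))
  if (is.list(events) && !is.data.frame(events) && !is.null(events$events)) {
    events <- events$events
  }
  events <- events[!events$ad_retained, , drop = FALSE]
  n <- nrow(events)
  if (n < 1L) .stop_nhej("no observed events", "nhej_stats_error")
  k_min <- as.integer(k_min)
  p0 <- if (k_min <= null$max_mh && k_min >= 1L) {
    unname(null$p_mh_ge[as.character(k_min)])
  } else if (k_min < 1L) 1 else 0
  obs <- mean(events$mh_len >= k_min)
  degenerate <- p0 <= 0 || p0 >= 1
  if (degenerate) {
    stat <- NA_real_
    p <- NA_real_
  } else {
    stat <- (obs - p0) / sqrt(p0 * (1 - p0) / n)
    p <- 2 * stats::pnorm(-abs(stat))
  }
  structure(list(statistic = stat, p_value = p, n1 = n, n2 = NA_integer_,
                 estimate1 = obs, estimate2 = p0, method = "one_proportion",
                 degenerate = degenerate, k_min = k_min),
            class = "nhej_test")
}

#' @export
print.mh_null <- function(x, ...) {
  cat(sprintf("Random-joining microhomology null (%s, %s blunt pair)\n",
              if (x$two_sided) "full-tract scoring" else "one-sided scoring",
              if (x$include_blunt) "with" else "without"))
  cat(sprintf("  %d breakpoint pairs enumerated; window %d x %d bp\n",
              x$n_pairs, x$window$max_del_5prime, x$window$max_del_3prime))
  cat(sprintf("  P(MH >= 1) = %.4f; longest microhomology = %d bp\n",
              if (x$max_mh >= 1L) x$p_mh_ge[["1"]] else 0, x$max_mh))
  invisible(x)
}

#' @export
plot.mh_null <- function(x, ...) {
  graphics::barplot(x$probs, xlab = "apparent microhomology (bp)",
                    ylab = "probability under random joining",
                    main = "Random-joining null", ...)
  invisible(x)
}
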