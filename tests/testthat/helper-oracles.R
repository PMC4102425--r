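# Independent oracles and fixture builders shared across the suite. Every
# oracle is deliberately naive (plain string loops), coded without reference
# to the package internals it checks.

# does `read[1..a]` equal `left[1..a]` with no N on either side?
.ok_prefix <- function(read, left, a) {
  if (a == 0) return(TRUE)
  if (a > nchar(read) || a > nchar(left)) return(FALSE)
  x <- substr(read, 1, a)
  x == substr(left, 1, a) && !grepl("N", x, fixed = TRUE)
}

.ok_suffix <- function(read, right, b) {
  if (b == 0) return(TRUE)
  n <- nchar(read)
  R <- nchar(right)
  if (b > n || b > R) return(FALSE)
  x <- substr(read, n - b + 1, n)
  x == substr(right, R - b + 1, R) && !grepl("N", x, fixed = TRUE)
}

# Exhaustive-decomposition oracle: over all read = left-prefix(a) + ins +
# right-suffix(b), minimise insertion length, break ties left-greedy
# (maximal a). Reports the caller's convention: a/b are the *maximal* flank
# matches and mh their overlap beyond the read.
oracle_decompose <- function(read, left, right) {
  n <- nchar(read)
  a_valid <- Filter(function(a) .ok_prefix(read, left, a), 0:min(n, nchar(left)))
  b_valid <- Filter(function(b) .ok_suffix(read, right, b), 0:min(n, nchar(right)))
  amax <- max(unlist(a_valid))
  bmax <- max(unlist(b_valid))
  if (amax == 0 && bmax == 0) return(NULL) # unalignable
  best <- NULL
  for (a in unlist(a_valid)) {
    for (b in unlist(b_valid)) {
      if (a + b > n) next
      ins <- if (a + b == n) "" else substr(read, a + 1, n - b)
      cand <- list(a = a, b = b, ins = ins)
      if (is.null(best) ||
          nchar(cand$ins) < nchar(best$ins) ||
          (nchar(cand$ins) == nchar(best$ins) && cand$a > best$a)) {
        best <- cand
      }
    }
  }
  mh <- if (nchar(best$ins) == 0) amax + bmax - n else 0
  if (mh < 0) mh <- 0
  list(a = amax, b = if (mh > 0) best$b + mh else bmax,
       mh = mh, ins = best$ins,
       del_total = (nchar(left) - amax) + (nchar(right) - bmax) + max(0, amax + bmax - n))
}

# naive k-loop oracle for one-sided apparent microhomology
oracle_apparent_mh <- function(i, j, ref) {
  k <- 0L
  repeat {
    kk <- k + 1L
    if (kk > j - i - 1 || i - kk + 1 < 1) break
    lhs <- substr(ref, i - kk + 1, i)
    rhs <- substr(ref, j - kk, j - 1)
    if (lhs != rhs || grepl("N", lhs, fixed = TRUE)) break
    k <- kk
  }
  k
}

# independent per-pair enumeration of the null: plain nested loops over
# (i, j), scoring backward and (optionally) forward homology with character
# comparisons capped at the flanks
oracle_null_counts <- function(left, right, w5, w3, two_sided = TRUE,
                               include_blunt = FALSE) {
  cc <- nchar(left)
  ref <- paste0(left, right)
  n <- nchar(ref)
  ch <- strsplit(ref, "", fixed = TRUE)[[1]]
  eq <- function(x, y) ch[x] == ch[y] && ch[x] != "N"
  out <- integer(0)
  for (i in (cc - w5):cc) {
    for (j in (cc + 1):(cc + 1 + w3)) {
      if (!include_blunt && j == i + 1) next
      q <- 0
      while (i - q >= 1 && j - 1 - q >= cc + 1 && eq(i - q, j - 1 - q)) q <- q + 1
      r <- 0
      if (two_sided) {
        while (i + r + 1 <= cc && j + r <= n && eq(i + r + 1, j + r)) r <- r + 1
      }
      out <- c(out, q + r)
    }
  }
  out
}

# small valid reporter construct: primers flush with configurable offsets
toy_construct <- function(left, excised, right, primer_len = 4,
                          fwd_start = 1, rev_end = nchar(right)) {
  L <- nchar(left)
  sequence <- paste0(left, excised, right)
  reporter_construct(
    sequence = sequence,
    cut_sites = list(
      list(position = L, overhang_length = 4, orientation = "forward"),
      list(position = L + nchar(excised), overhang_length = 4,
           orientation = "reverse")),
    excised_interval = c(L + 1, L + nchar(excised)),
    primer_fwd = substr(left, fwd_start, fwd_start + primer_len - 1),
    primer_rev = revcomp(substr(right, rev_end - primer_len + 1, rev_end)),
    name = "toy")
}

# random DNA string (test-side; independent of package internals)
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# a bare cut_reference plus matching full-flank window
toy_window <- function(cutref, w5 = nchar(cutref$left_flank) - 1,
                       w3 = nchar(cutref$right_flank) - 1) {
  structure(list(max_del_5prime = as.integer(w5),
                 max_del_3prime = as.integer(w3)),
            class = "detection_window")
}

default_params <- function(...) {
  call_params(trim_primers = FALSE, flag_ad_retained = FALSE, ...)
}
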