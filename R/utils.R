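# Internal low-level helpers. All sequence handling is on uppercase A/C/G/T/N
# character strings; hot paths work on raw byte vectors. 'N' matches nothing,
# including another 'N' (conservative ambiguity handling).

.N_BYTE <- as.raw(78L) # "N"

.stop_nhej <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "nhej_error"), call = call))
}

.check_dna <- function(x, what = "sequence", allow_empty = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    .stop_nhej(sprintf("%s must be a single character string", what),
               "nhej_dna_error")
  }
  if (!allow_empty && !nzchar(x)) {
    .stop_nhej(sprintf("%s must be non-empty", what), "nhej_dna_error")
  }
  if (grepl("[^ACGTN]", x)) {
    .stop_nhej(sprintf("%s contains characters outside A/C/G/T/N", what),
               "nhej_dna_error")
  }
  invisible(x)
}

# longest common prefix of two raw vectors; N never matches
.lcp_raw <- function(x, y) {
  m <- min(length(x), length(y))
  if (m == 0L) return(0L)
  xs <- x[seq_len(m)]
  ys <- y[seq_len(m)]
  ok <- (xs == ys) & (xs != .N_BYTE)
  bad <- which(!ok)
  if (length(bad)) bad[1L] - 1L else m
}

# longest common prefix allowing up to k mismatches; a trailing run of
# mismatches never extends the match (the match must end on an agreement)
.lcp_raw_k <- function(x, y, k) {
  m <- min(length(x), length(y))
  if (m == 0L) return(0L)
  used <- 0L
  last_match <- 0L
  for (i in seq_len(m)) {
    if (x[i] == y[i] && x[i] != .N_BYTE) {
      last_match <- i
    } else {
      used <- used + 1L
      if (used > k) break
    }
  }
  last_match
}

.reverse_raw <- function(x) x[rev(seq_along(x))]

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement (A/C/G/T/N alphabet). Used to match
#' reverse PCR primers, which are written 5'->3' on the bottom strand.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# run expr with a locally seeded RNG, restoring the caller's RNG state;
# seed = NULL means "use the current stream"
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    .stop_nhej("seed must be a single number or NULL", "nhej_seed_error")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# exact fixed-pattern match positions of pat in subject
.find_all <- function(pat, subject) {
  if (!nzchar(pat)) return(integer(0))
  hits <- gregexpr(pat, subject, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
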