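# Junction caller: infer each read's repair signature against the cut
# reference.
#
# Model: an NHEJ product is read = left_flank[1..a] + insertion +
# right_flank[(R-b'+1)..R]. We take a = the maximal exact prefix match of the
# read against the left flank and b = the maximal exact suffix match against
# the right flank. If a + b exceeds the read length the overlap is apparent
# microhomology (the breakpoint cannot be placed within it); if it falls
# short, the interior is an insertion. This equals exhaustive search over all
# decompositions minimising insertion length, ties broken left-greedy
# (microhomology bases attributed to the left flank).

#' Junction-calling parameters
#'
#' @param mmej_min,mmej_max microhomology length range (bp) classified as
#'   MMEJ. MMEJ characteristically uses 5-25 bp of homology; the effective
#'   upper bound in any construct is the longest microhomology its intron
#'   offers (see [longest_mh()]).
#' @param max_mismatch mismatches tolerated while extending flank matches.
#'   Default 0: inputs are Sanger-sequenced clones, so exact matching is
#'   appropriate; a tolerant mode is available for noisy reads.
#' @param window optional [detection_window()]; events whose inferred
#'   deletion exceeds it are flagged `outside_window`.
#' @param trim_primers if TRUE, reads that start at the forward primer or end
#'   at the reverse-primer site are anchored to the primer's known flank
#'   position before matching (amplicons carry primer sequence).
#' @param flag_ad_retained if TRUE, long insertions matching the excised
#'   segment are flagged as killer-exon retention (single-cut events); such
#'   events are excluded from cohort statistics by default.
#' @param ad_retained_min minimum insertion length checked against the
#'   excised segment.
#' @return object of class `call_params`.
#' @export
call_params <- function(mmej_min = 5L, mmej_max = 25L, max_mismatch = 0L,
                        window = NULL, trim_primers = TRUE,
                        flag_ad_retained = TRUE, ad_retained_min = 15L) {
  mmej_min <- as.integer(mmej_min)
  mmej_max <- as.integer(mmej_max)
  if (mmej_min < 1L || mmej_min > mmej_max) {
    .stop_nhej("require 1 <= mmej_min <= mmej_max", "nhej_params_error")
  }
  if (!is.null(window)) stopifnot(inherits(window, "detection_window"))
  structure(list(mmej_min = mmej_min, mmej_max = mmej_max,
                 max_mismatch = as.integer(max_mismatch), window = window,
                 trim_primers = isTRUE(trim_primers),
                 flag_ad_retained = isTRUE(flag_ad_retained),
                 ad_retained_min = as.integer(ad_retained_min)),
            class = "call_params")
}

# anchor amplicon-style reads: a read beginning exactly with the forward
# primer is extended leftwards with the flank bases 5' of the primer site
# (those bases are absent by PCR design, not by deletion); symmetrically at
# the reverse-primer end
.anchor_primers <- function(seq, cutref) {
  fwd_at <- attr(cutref, "primer_fwd_at")
  rev_at <- attr(cutref, "primer_rev_at")
  fwd <- attr(cutref, "primer_fwd")
  rev_rc <- attr(cutref, "primer_rev_rc")
  if (!is.null(fwd_at) && fwd_at[1L] > 1L && startsWith(seq, fwd)) {
    seq <- paste0(substr(cutref$left_flank, 1L, fwd_at[1L] - 1L), seq)
  }
  R <- nchar(cutref$right_flank)
  if (!is.null(rev_at) && rev_at[2L] < R && endsWith(seq, rev_rc)) {
    seq <- paste0(seq, substr(cutref$right_flank, rev_at[2L] + 1L, R))
  }
  seq
}

#' Call the repair signature of one junction read
#'
#' @param read a junction read: either a DNA string or a list/row with `id`,
#'   `sequence` and optional `source_reaction`.
#' @param cutref a [derive_cut_reference()] result.
#' @param params a [call_params()] object.
#' @return an object of class `repair_event`: a list with `read_id`,
#'   `left_match` (a), `right_match` (b), `del_5prime`, `del_3prime`,
#'   `del_total` (total reference bp absent from the read), `insertion_seq`,
#'   `insertion_len`, `mh_len`, `ambiguity` (= `mh_len`: the span over which
#'   the breakpoint cannot be placed), `is_mmej`, `event_class` (one of
#'   `exact`, `deletion`, `insertion`, `deletion+insertion`), and the flags
#'   `ad_retained` and `outside_window`.
#'
#' @details Deletion sizes follow the left-greedy canonicalisation: `a` is
#'   maximised first, so microhomology bases are attributed to the left
#'   flank. The attribution shifts `del_5prime`/`del_3prime` by at most
#'   `mh_len` but never changes `del_total` or `mh_len`; the `ambiguity`
#'   field makes the convention explicit.
#' @export
call_junction <- function(read, cutref, params = call_params()) {
  stopifnot(inherits(cutref, "cut_reference"))
  if (is.character(read)) read <- list(id = NA_character_, sequence = read)
  seq <- toupper(read$sequence)
  .check_dna(seq, "junction read")

  if (params$trim_primers) seq <- .anchor_primers(seq, cutref)

  left_raw <- attr(cutref, "left_raw")
  if (is.null(left_raw)) left_raw <- charToRaw(cutref$left_flank)
  right_rev <- attr(cutref, "right_raw_rev")
  if (is.null(right_rev)) right_rev <- .reverse_raw(charToRaw(cutref$right_flank))
  L <- length(left_raw)
  R <- length(right_rev)
  rw <- charToRaw(seq)
  n <- length(rw)

  if (params$max_mismatch > 0L) {
    a <- .lcp_raw_k(rw, left_raw, params$max_mismatch)
    b <- .lcp_raw_k(.reverse_raw(rw), right_rev, params$max_mismatch)
  } else {
    a <- .lcp_raw(rw, left_raw)
    b <- .lcp_raw(.reverse_raw(rw), right_rev)
  }

  if (a == 0L && b == 0L) {
    .stop_nhej(sprintf("unalignable junction%s: read matches neither flank at >= 1 bp",
                       if (is.na(read$id)) "" else paste0(" '", read$id, "'")),
               "nhej_unalignable_error")
  }

  if (a + b >= n) {
    mh <- a + b - n
    ins <- ""
  } else {
    mh <- 0L
    ins <- substr(seq, a + 1L, n - b)
  }
  ins_len <- nchar(ins)
  del5 <- L - a
  del3 <- R - b + mh
  del_total <- del5 + del3

  event_class <-
    if (del_total == 0L && ins_len == 0L) "exact"
    else if (ins_len == 0L) "deletion"
    else if (del_total == 0L) "insertion"
    else "deletion+insertion"

  ad_retained <- FALSE
  if (params$flag_ad_retained && ins_len >= params$ad_retained_min) {
    excised <- attr(cutref, "excised_seq")
    if (!is.null(excised) &&
        (grepl(ins, excised, fixed = TRUE) ||
         grepl(revcomp(ins), excised, fixed = TRUE))) {
      ad_retained <- TRUE
    }
  }

  outside_window <- FALSE
  if (!is.null(params$window)) {
    outside_window <- del5 > params$window$max_del_5prime ||
      del3 > params$window$max_del_3prime
  }

  structure(
    list(read_id = read$id,
         source_reaction = if (is.null(read$source_reaction)) NA_character_
                           else read$source_reaction,
         left_match = a, right_match = b,
         del_5prime = del5, del_3prime = del3, del_total = del_total,
         insertion_seq = ins, insertion_len = ins_len,
         mh_len = mh, ambiguity = mh,
         is_mmej = mh >= params$mmej_min && mh <= params$mmej_max,
         event_class = event_class,
         ad_retained = ad_retained, outside_window = outside_window),
    class = "repair_event")
}

#' Reconstruct a read from its repair signature (round-trip oracle)
#'
#' Returns `left_flank[1..a] + insertion + right_flank` suffix of length
#' `b - mh_len` (microhomology bases are attributed to the left flank, so
#' they must not be emitted twice). For every event produced by
#' [call_junction()] the output equals the input read exactly.
#'
#' @param event a `repair_event` (or one-row slice of an events table).
#' @param cutref the [derive_cut_reference()] the event was called against.
#' @return DNA string.
#' @export
reconstruct_read <- function(event, cutref) {
  stopifnot(inherits(cutref, "cut_reference"))
  if (is.data.frame(event)) event <- as.list(event[1L, ])
  if (event$mh_len > 0L && event$insertion_len > 0L) {
    .stop_nhej("inconsistent event: microhomology and insertion are mutually exclusive",
               "nhej_event_error")
  }
  if (event$left_match < 0L || event$right_match < 0L ||
      event$mh_len > event$left_match + event$right_match) {
    .stop_nhej("inconsistent event: matches shorter than microhomology",
               "nhej_event_error")
  }
  R <- nchar(cutref$right_flank)
  keep_right <- event$right_match - event$mh_len
  paste0(substr(cutref$left_flank, 1L, event$left_match),
         event$insertion_seq,
         substr(cutref$right_flank, R - keep_right + 1L, R))
}

#' Read junction FASTA
#'
#' Read ids follow `cohort|mouse|reaction|clone`; fields after the first `|`
#' are optional. `source_reaction` is `cohort|mouse|reaction` when a reaction
#' field is present, so the uniqueness rule is applied within a PCR reaction.
#'
#' @param fasta_path path to a junction FASTA file.
#' @return data.frame with columns `id`, `sequence`, `cohort`, `mouse`,
#'   `reaction`, `clone`, `source_reaction`.
#' @export
read_junctions <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    .stop_nhej(sprintf("reads FASTA not found: %s", fasta_path),
               "nhej_fasta_error")
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- names(seqs)
  parts <- strsplit(ids, "|", fixed = TRUE)
  field <- function(k) vapply(parts, function(p)
    if (length(p) >= k) p[k] else NA_character_, character(1))
  cohort <- field(1L); mouse <- field(2L); reaction <- field(3L)
  df <- data.frame(
    id = ids,
    sequence = toupper(as.character(seqs)),
    cohort = cohort, mouse = mouse, reaction = reaction, clone = field(4L),
    source_reaction = ifelse(is.na(reaction), NA_character_,
                             paste(cohort, mouse, reaction, sep = "|")),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

# canonical junction signature used for the per-reaction uniqueness rule
.event_signature <- function(ev) {
  paste(ev$del_5prime, ev$del_3prime, ev$mh_len, ev$insertion_seq, sep = ":")
}

#' Call every read in a cohort and apply the per-reaction uniqueness rule
#'
#' Mirrors the cloning protocol in which multiple parallel PCR reactions are
#' set up and only one junction with a unique sequence per reaction enters
#' the analysis: with `dedupe = TRUE`, at most one event per
#' (source_reaction, junction signature) pair is retained. Reads without a
#' `source_reaction` are always retained.
#'
#' @param reads data.frame as returned by [read_junctions()] (columns `id`,
#'   `sequence`, optional `source_reaction`), or a character vector of
#'   sequences.
#' @param cutref a [derive_cut_reference()] result.
#' @param params a [call_params()] object.
#' @param dedupe apply the uniqueness rule (default TRUE).
#' @return list with `events` (data.frame, one row per retained
#'   `repair_event`), `rejects` (data.frame `read_id`, `reason`) and `log`
#'   (counts of called, duplicate and unalignable reads).
#' @export
batch_analyze <- function(reads, cutref, params = call_params(),
                          dedupe = TRUE) {
  if (is.character(reads)) {
    reads <- data.frame(id = sprintf("read%04d", seq_along(reads)),
                        sequence = reads, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  if (is.null(reads$source_reaction)) reads$source_reaction <- NA_character_

  events <- vector("list", nrow(reads))
  rej_id <- character(0)
  rej_why <- character(0)
  seen <- new.env(parent = emptyenv())
  n_dup <- 0L

  for (i in seq_len(nrow(reads))) {
    ev <- tryCatch(
      call_junction(list(id = reads$id[i], sequence = reads$sequence[i],
                         source_reaction = reads$source_reaction[i]),
                    cutref, params),
      nhej_unalignable_error = function(e) e,
      nhej_dna_error = function(e) e)
    if (inherits(ev, "error")) {
      rej_id <- c(rej_id, reads$id[i])
      rej_why <- c(rej_why, conditionMessage(ev))
      next
    }
    if (dedupe && !is.na(ev$source_reaction)) {
      key <- paste(ev$source_reaction, .event_signature(ev), sep = "::")
      if (!is.null(seen[[key]])) {
        n_dup <- n_dup + 1L
        next
      }
      seen[[key]] <- TRUE
    }
    events[[i]] <- ev
  }

  events <- events[!vapply(events, is.null, logical(1))]
  ev_df <- if (length(events)) {
    do.call(rbind, lapply(events, function(e)
      as.data.frame(unclass(e), stringsAsFactors = FALSE)))
  } else {
    data.frame(read_id = character(0), source_reaction = character(0),
               left_match = integer(0), right_match = integer(0),
               del_5prime = integer(0), del_3prime = integer(0),
               del_total = integer(0), insertion_seq = character(0),
               insertion_len = integer(0), mh_len = integer(0),
               ambiguity = integer(0), is_mmej = logical(0),
               event_class = character(0), ad_retained = logical(0),
               outside_window = logical(0), stringsAsFactors = FALSE)
  }
  rownames(ev_df) <- NULL
  list(events = ev_df,
       rejects = data.frame(read_id = rej_id, reason = rej_why,
                            stringsAsFactors = FALSE),
       log = c(n_reads = nrow(reads), n_events = nrow(ev_df),
               n_duplicates = n_dup, n_unalignable = length(rej_id)))
}

#' @export
print.repair_event <- function(x, ...) {
  cat(sprintf("Repair event%s: %s\n",
              if (is.na(x$read_id)) "" else paste0(" ", x$read_id),
              x$event_class))
  cat(sprintf("  del 5'/3'/total: %d/%d/%d bp (left-greedy; ambiguity %d bp)\n",
              x$del_5prime, x$del_3prime, x$del_total, x$ambiguity))
  if (x$insertion_len > 0L) {
    cat(sprintf("  insertion: %d bp (%s)\n", x$insertion_len,
                if (x$insertion_len <= 40L) x$insertion_seq
                else paste0(substr(x$insertion_seq, 1L, 37L), "...")))
  }
  cat(sprintf("  microhomology: %d bp%s\n", x$mh_len,
              if (x$is_mmej) " -> MMEJ" else ""))
  if (x$ad_retained) cat("  flag: killer-exon sequence retained\n")
  if (x$outside_window) cat("  flag: deletion outside the rescue window\n")
  invisible(x)
}
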