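# Reporter construct model.
#
# The assay: a GFP gene split by a large intron that carries a "killer" exon
# flanked by two inverted I-SceI sites. Double digestion excises the killer
# exon; NHEJ rejoining of the intron ends restores GFP. Junctions are rescued
# by PCR with primers annealing inside the intron on either side of the cut.
#
# Coordinate convention, used throughout the package: 1-based, closed
# intervals, top strand. A cut-site `position` is the index of the base
# immediately 5' of the top-strand scission.

#' Construct a validated reporter-construct object
#'
#' @param sequence uppercase DNA string (A/C/G/T/N) of the full construct.
#' @param cut_sites list of exactly two cut sites, each a list with elements
#'   `position` (1-based index of the base 5' of the scission),
#'   `overhang_length` (nt, I-SceI leaves 4-nt 3' overhangs) and
#'   `orientation` (`"forward"` or `"reverse"`).
#' @param excised_interval integer vector `c(start, end)`: the 1-based closed
#'   interval removed by double digestion (killer exon plus inter-site DNA).
#'   Any retained overhang bases are simply part of the flank strings; which
#'   flank they sit on is fixed by this interval (default annotation keeps
#'   overhangs distal to the excised segment).
#' @param primer_fwd,primer_rev rescue-primer sequences. The forward primer is
#'   matched as printed; the reverse primer is matched as its reverse
#'   complement (standard PCR convention). Each must occur exactly once in the
#'   construct, outside the excised interval.
#' @param name identifier for the construct.
#' @return an object of class `reporter_construct`.
#' @seealso [load_construct()], [derive_cut_reference()], [detection_window()]
#' @export
reporter_construct <- function(sequence, cut_sites, excised_interval,
                               primer_fwd, primer_rev, name = "construct") {
  .check_dna(sequence, "construct sequence")
  .check_dna(primer_fwd, "primer_fwd")
  .check_dna(primer_rev, "primer_rev")
  n <- nchar(sequence)

  if (!is.list(cut_sites) || length(cut_sites) != 2L) {
    .stop_nhej("exactly two cut sites are required for the two-cut assay",
               "nhej_annotation_error")
  }
  cut_sites <- lapply(cut_sites, function(cs) {
    cs <- as.list(cs)
    if (is.null(cs$position) || is.null(cs$orientation)) {
      .stop_nhej("each cut site needs `position` and `orientation`",
                 "nhej_annotation_error")
    }
    if (is.null(cs$overhang_length)) cs$overhang_length <- 4L
    cs$position <- as.integer(cs$position)
    cs$overhang_length <- as.integer(cs$overhang_length)
    if (cs$overhang_length < 0L) {
      .stop_nhej("overhang_length must be >= 0", "nhej_annotation_error")
    }
    if (cs$position < 1L || cs$position > n) {
      .stop_nhej(sprintf("cut site position %d outside sequence [1, %d]",
                         cs$position, n), "nhej_annotation_error")
    }
    if (!cs$orientation %in% c("forward", "reverse")) {
      .stop_nhej("cut site orientation must be 'forward' or 'reverse'",
                 "nhej_annotation_error")
    }
    cs
  })
  if (cut_sites[[1L]]$position >= cut_sites[[2L]]$position) {
    .stop_nhej("cut sites must be strictly ordered and non-overlapping",
               "nhej_annotation_error")
  }

  excised_interval <- as.integer(excised_interval)
  if (length(excised_interval) != 2L || anyNA(excised_interval)) {
    .stop_nhej("excised_interval must be c(start, end)",
               "nhej_annotation_error")
  }
  es <- excised_interval[1L]
  ee <- excised_interval[2L]
  if (es > ee) {
    .stop_nhej(sprintf("excised_interval [%d, %d] is inverted", es, ee),
               "nhej_annotation_error")
  }
  # strictly inside: both flanks must be non-empty
  if (es <= 1L || ee >= n) {
    .stop_nhej("excised_interval must lie strictly inside the sequence",
               "nhej_annotation_error")
  }

  .check_primer_once <- function(pat, label) {
    hits <- .find_all(pat, sequence)
    if (length(hits) == 0L) {
      .stop_nhej(sprintf("%s not found in construct sequence", label),
                 "nhej_primer_error")
    }
    if (length(hits) > 1L) {
      .stop_nhej(sprintf("%s found %d times; must be unique", label,
                         length(hits)), "nhej_primer_error")
    }
    c(hits, hits + nchar(pat) - 1L)
  }
  fwd_span <- .check_primer_once(primer_fwd, "forward primer")
  rev_span <- .check_primer_once(revcomp(primer_rev), "reverse primer")
  overlaps <- function(span) span[1L] <= ee && span[2L] >= es
  if (overlaps(fwd_span) || overlaps(rev_span)) {
    .stop_nhej("a rescue primer anneals inside the excised interval",
               "nhej_primer_error")
  }

  structure(
    list(name = name, sequence = sequence, cut_sites = cut_sites,
         excised_interval = c(start = es, end = ee),
         primer_fwd = primer_fwd, primer_rev = primer_rev),
    class = "reporter_construct")
}

#' Load a reporter construct from FASTA plus a structured annotation
#'
#' The annotation is a JSON file with keys `cut_sites` (array of objects with
#' `position`, `overhang_length`, `orientation`), `excised_interval`
#' (`[start, end]`), `primer_fwd` and `primer_rev`.
#'
#' @param fasta_path path to a single-record FASTA file.
#' @param annotation_path path to the JSON annotation.
#' @return a validated [reporter_construct()].
#' @export
load_construct <- function(fasta_path, annotation_path) {
  if (!file.exists(fasta_path)) {
    .stop_nhej(sprintf("FASTA file not found: %s", fasta_path),
               "nhej_fasta_error")
  }
  if (!file.exists(annotation_path)) {
    .stop_nhej(sprintf("annotation file not found: %s", annotation_path),
               "nhej_annotation_error")
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) {
    .stop_nhej("FASTA contains no records", "nhej_fasta_error")
  }
  if (length(seqs) > 1L) {
    .stop_nhej(sprintf("FASTA must contain exactly one record, found %d",
                       length(seqs)), "nhej_fasta_error")
  }
  ann <- jsonlite::fromJSON(annotation_path, simplifyVector = TRUE)
  for (key in c("cut_sites", "excised_interval", "primer_fwd", "primer_rev")) {
    if (is.null(ann[[key]])) {
      .stop_nhej(sprintf("annotation is missing key '%s'", key),
                 "nhej_annotation_error")
    }
  }
  cs <- ann$cut_sites
  if (is.data.frame(cs)) {
    cs <- lapply(seq_len(nrow(cs)), function(i) as.list(cs[i, , drop = FALSE]))
  }
  reporter_construct(
    sequence = toupper(as.character(seqs[[1L]])),
    cut_sites = cs,
    excised_interval = ann$excised_interval,
    primer_fwd = toupper(ann$primer_fwd),
    primer_rev = toupper(ann$primer_rev),
    name = names(seqs)[1L])
}

#' Construct a cut reference directly from flank sequences
#'
#' Lightweight constructor for working with bare flanks (no primer or
#' excised-segment metadata); [derive_cut_reference()] is the usual route.
#'
#' @param left_flank,right_flank DNA strings retained left/right of the cut.
#' @return object of class `cut_reference`.
#' @export
cut_reference <- function(left_flank, right_flank) {
  .check_dna(left_flank, "left_flank")
  .check_dna(right_flank, "right_flank")
  ref <- structure(
    list(left_flank = left_flank, right_flank = right_flank,
         cut_coordinate = nchar(left_flank)),
    class = "cut_reference")
  attr(ref, "left_raw") <- charToRaw(left_flank)
  attr(ref, "right_raw_rev") <- .reverse_raw(charToRaw(right_flank))
  ref
}

#' Derive the post-double-cut reference flanks
#'
#' After digestion at both sites the excised interval is gone; the retained
#' left and right flanks, concatenated, form the precise-excision product
#' against which junction reads are interpreted. Overhang bases are carried
#' on whichever flank the annotated excised interval leaves them on; fill-in
#' versus chew-back of the 3' overhangs is not modelled structurally because
#' sequenced clones are double-stranded.
#'
#' @param construct a [reporter_construct()].
#' @return an object of class `cut_reference` with elements `left_flank`,
#'   `right_flank` and `cut_coordinate` (index such that the precise-excision
#'   product is `left_flank` followed by `right_flank`). Primer locations and
#'   the excised sequence are attached as attributes for primer anchoring and
#'   killer-exon-retention flagging during junction calling.
#' @export
derive_cut_reference <- function(construct) {
  stopifnot(inherits(construct, "reporter_construct"))
  seq <- construct$sequence
  es <- construct$excised_interval[["start"]]
  ee <- construct$excised_interval[["end"]]
  left <- substr(seq, 1L, es - 1L)
  right <- substr(seq, ee + 1L, nchar(seq))

  ref <- structure(
    list(left_flank = left, right_flank = right,
         cut_coordinate = nchar(left)),
    class = "cut_reference")

  # cached raw forms for the junction caller's hot path
  attr(ref, "left_raw") <- charToRaw(left)
  attr(ref, "right_raw_rev") <- .reverse_raw(charToRaw(right))
  attr(ref, "excised_seq") <- substr(seq, es, ee)
  fwd <- .find_all(construct$primer_fwd, left)
  rc_rev <- .find_all(revcomp(construct$primer_rev), right)
  attr(ref, "primer_fwd") <- construct$primer_fwd
  attr(ref, "primer_rev_rc") <- revcomp(construct$primer_rev)
  attr(ref, "primer_fwd_at") <-
    if (length(fwd) == 1L) c(fwd, fwd + nchar(construct$primer_fwd) - 1L)
    else NULL
  attr(ref, "primer_rev_at") <-
    if (length(rc_rev) == 1L)
      c(rc_rev, rc_rev + nchar(construct$primer_rev) - 1L)
    else NULL
  ref
}

#' Primer-bounded deletion detection window
#'
#' Junctions are only observable while both rescue primers still anneal, so
#' the largest detectable deletion on each side is the distance from the cut
#' edge to the primer's proximal annealing boundary: on the 5' side, from the
#' left cut edge to the 3' end of the forward-primer site; on the 3' side,
#' from the right cut edge to the start of the reverse-primer annealing site.
#'
#' @param construct a [reporter_construct()].
#' @param cutref the matching [derive_cut_reference()] result (derived from
#'   `construct` if omitted).
#' @return object of class `detection_window`: list with `max_del_5prime` and
#'   `max_del_3prime` (bp).
#' @export
detection_window <- function(construct, cutref = derive_cut_reference(construct)) {
  stopifnot(inherits(construct, "reporter_construct"),
            inherits(cutref, "cut_reference"))
  fwd_at <- attr(cutref, "primer_fwd_at")
  rev_at <- attr(cutref, "primer_rev_at")
  if (is.null(fwd_at) || is.null(rev_at)) {
    .stop_nhej("rescue primers are not locatable on the retained flanks (do they anneal inside the excised interval?)",
               "nhej_window_error")
  }
  w5 <- nchar(cutref$left_flank) - fwd_at[2L]
  w3 <- rev_at[1L] - 1L
  if (w5 < 0L || w3 < 0L) {
    .stop_nhej("primer annealing sites overlap the cut edges",
               "nhej_window_error")
  }
  structure(list(max_del_5prime = w5, max_del_3prime = w3),
            class = "detection_window")
}

#' @export
print.reporter_construct <- function(x, ...) {
  cat(sprintf("Reporter construct '%s': %d bp\n", x$name, nchar(x$sequence)))
  cat(sprintf("  excised interval: [%d, %d] (%d bp)\n",
              x$excised_interval[["start"]], x$excised_interval[["end"]],
              x$excised_interval[["end"]] - x$excised_interval[["start"]] + 1L))
  for (cs in x$cut_sites) {
    cat(sprintf("  cut site: position %d, %d-nt overhang, %s\n",
                cs$position, cs$overhang_length, cs$orientation))
  }
  cat(sprintf("  primers: fwd %d nt, rev %d nt\n",
              nchar(x$primer_fwd), nchar(x$primer_rev)))
  invisible(x)
}

#' @export
print.cut_reference <- function(x, ...) {
  cat(sprintf("Cut reference: left flank %d bp + right flank %d bp (cut coordinate %d)\n",
              nchar(x$left_flank), nchar(x$right_flank), x$cut_coordinate))
  invisible(x)
}

#' @export
print.detection_window <- function(x, ...) {
  cat(sprintf("Detection window: up to %d bp deleted 5' and %d bp 3' of the break\n",
              x$max_del_5prime, x$max_del_3prime))
  invisible(x)
}

#' Write a construct to FASTA plus JSON annotation
#'
#' Inverse of [load_construct()]; used by the simulator and pipeline so that
#' generated constructs are consumable by every other entry point unchanged.
#'
#' @param construct a [reporter_construct()].
#' @param fasta_path,annotation_path output paths.
#' @return invisibly, the two paths.
#' @export
write_construct <- function(construct, fasta_path, annotation_path) {
  stopifnot(inherits(construct, "reporter_construct"))
  dna <- Biostrings::DNAStringSet(construct$sequence)
  names(dna) <- construct$name
  Biostrings::writeXStringSet(dna, fasta_path)
  ann <- list(
    cut_sites = lapply(construct$cut_sites, function(cs)
      list(position = cs$position, overhang_length = cs$overhang_length,
           orientation = cs$orientation)),
    excised_interval = unname(construct$excised_interval),
    primer_fwd = construct$primer_fwd,
    primer_rev = construct$primer_rev)
  jsonlite::write_json(ann, annotation_path, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta_path, annotation_path))
}
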