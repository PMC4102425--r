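# Synthetic-data generator.
#
# Emulates the study's stated world: 60 junctions per cell type (30 young +
# 30 old) across 5 tissue analogs; deletions spanning 1 up to ~990 bp inside
# an 886 x 750 bp primer-rescue window; insertions of 1 to ~138 bp with
# 33-67% of junctions insertion-bearing; microhomologies up to 16 bp (the
# default construct plants a 16-bp maximal repeat). Repair channels: c-NHEJ
# samples independent geometric 5'/3' resections plus an optional insertion;
# MMEJ joins at a microhomology pair (>= mmej_min bp) drawn from the
# exhaustive enumeration, deleting the intervening sequence. Chance
# microhomology at c-NHEJ junctions is *not* suppressed -- random flank
# sequence creating apparent MH is exactly what the random-joining null
# describes.

#' Simulation parameters for repair events
#'
#' @param n_events junctions per cohort; default 30, the per-age cohort size
#'   of the study design (60 per cell type = 30 young + 30 old).
#' @param p_mmej probability a junction uses a microhomology pair of at
#'   least `mmej_min` bp.
#' @param resection_mean_5p,resection_mean_3p mean resection (bp) on each
#'   side at c-NHEJ junctions; geometric law (single-parameter; the assay
#'   reports only ranges), truncated to the detection window so every read
#'   is rescuable.
#' @param p_insertion probability of an insertion at c-NHEJ junctions.
#' @param insertion_mean mean insertion length (bp); lengths are
#'   1 + geometric.
#' @param seq_error_rate per-base substitution probability (default 0;
#'   Sanger clone consensus is essentially error-free, and no indel errors
#'   are modelled).
#' @param mmej_min minimum microhomology (bp) used by the MMEJ channel.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_events = 30L, p_mmej = 0.25,
                       resection_mean_5p = 150, resection_mean_3p = 120,
                       p_insertion = 0.5, insertion_mean = 12,
                       seq_error_rate = 0, mmej_min = 5L, seed = NULL) {
  stopifnot(n_events >= 1L,
            p_mmej >= 0, p_mmej <= 1,
            p_insertion >= 0, p_insertion <= 1,
            seq_error_rate >= 0, seq_error_rate <= 1,
            resection_mean_5p > 0, resection_mean_3p > 0,
            insertion_mean > 0, mmej_min >= 1L)
  structure(list(n_events = as.integer(n_events), p_mmej = p_mmej,
                 resection_mean_5p = resection_mean_5p,
                 resection_mean_3p = resection_mean_3p,
                 p_insertion = p_insertion, insertion_mean = insertion_mean,
                 seq_error_rate = seq_error_rate,
                 mmej_min = as.integer(mmej_min), seed = seed),
            class = "sim_params")
}

ISCEI_SITE <- "TAGGGATAACAGGGTAAT" # 18-bp I-SceI recognition sequence

# geometric with given mean, truncated at max (resampling keeps the law's
# shape within the window)
.rgeom_trunc <- function(n, mean, max) {
  p <- 1 / (mean + 1)
  x <- stats::rgeom(n, p)
  bad <- which(x > max)
  while (length(bad)) {
    x[bad] <- stats::rgeom(length(bad), p)
    bad <- bad[x[bad] > max]
  }
  x
}

#' Generate a synthetic reporter construct with known microhomology content
#'
#' Background sequence is uniform-random A/C/G/T; each planted repeat is
#' written at a stated offset on both flanks so a known MMEJ channel exists.
#' The bases adjacent to the two copies of a planted repeat are forced to
#' differ, so the planted microhomology length is exact (no chance
#' extension). The default geometry mirrors the assay: an 886 x 750 bp
#' primer-rescue window and a 16-bp longest planted microhomology.
#'
#' @param seed optional seed (`NULL` = current RNG stream).
#' @param intron_len_5p,intron_len_3p flank lengths (bp) retained left and
#'   right of the excised segment.
#' @param excised_len length of the excised segment (killer exon plus the
#'   two inverted I-SceI sites, which are embedded at its ends).
#' @param planted_repeats list of `c(length, offset_left, offset_right)`:
#'   a repeat of `length` bp ending `offset_left` bp before the left cut
#'   edge and starting `offset_right` bp after the right cut edge.
#' @param window target detection window `c(w5, w3)`; the primers are placed
#'   to realise it.
#' @param primer_len rescue-primer length.
#' @param max_background_mh if non-NULL, background flanks are resampled
#'   until no *chance* microhomology exceeds this length, making planted
#'   repeats the construct's maximal homology by construction.
#' @return list with `construct` ([reporter_construct()]), `cutref`
#'   ([derive_cut_reference()]) and `window` ([detection_window()]).
#' @export
make_construct <- function(seed = NULL, intron_len_5p = 920L,
                           intron_len_3p = 780L, excised_len = 240L,
                           planted_repeats = list(c(6L, 30L, 25L),
                                                  c(9L, 100L, 80L),
                                                  c(16L, 300L, 260L)),
                           window = c(886L, 750L), primer_len = 25L,
                           max_background_mh = NULL) {
  .with_seed(seed, {
    w5 <- as.integer(window[1L])
    w3 <- as.integer(window[2L])
    L <- as.integer(intron_len_5p)
    R <- as.integer(intron_len_3p)
    if (L < w5 + primer_len || R < w3 + primer_len) {
      .stop_nhej("flanks too short for the requested window plus primers",
                 "nhej_sim_error")
    }
    if (excised_len < 2L * nchar(ISCEI_SITE)) {
      .stop_nhej("excised segment too short to carry both I-SceI sites",
                 "nhej_sim_error")
    }

    # reserved spans on each flank (primers; planted repeats, with a 1-bp
    # guard base on each side)
    occupied_left <- list(c(L - w5 - primer_len + 1L, L - w5))
    occupied_right <- list(c(w3 + 1L, w3 + primer_len))
    for (pr in planted_repeats) {
      len <- as.integer(pr[1L])
      off5 <- as.integer(pr[2L])
      off3 <- as.integer(pr[3L])
      lspan <- c(L - off5 - len + 1L, L - off5)
      rspan <- c(off3 + 1L, off3 + len)
      if (lspan[1L] < 2L || rspan[2L] > R - 1L || off5 > w5 || off3 > w3) {
        .stop_nhej("planted repeat does not fit inside the flank/window",
                   "nhej_sim_error")
      }
      grow <- function(s) c(s[1L] - 1L, s[2L] + 1L)
      for (s in occupied_left) {
        if (max(lspan[1L], grow(s)[1L]) <= min(lspan[2L], grow(s)[2L])) {
          .stop_nhej("planted repeat collides with another reserved region on the left flank",
                     "nhej_sim_error")
        }
      }
      for (s in occupied_right) {
        if (max(rspan[1L], grow(s)[1L]) <= min(rspan[2L], grow(s)[2L])) {
          .stop_nhej("planted repeat collides with another reserved region on the right flank",
                     "nhej_sim_error")
        }
      }
      occupied_left <- c(occupied_left, list(lspan))
      occupied_right <- c(occupied_right, list(rspan))
    }

    build_flanks <- function() {
      left <- strsplit(.random_dna(L), "", fixed = TRUE)[[1L]]
      right <- strsplit(.random_dna(R), "", fixed = TRUE)[[1L]]
      for (pr in planted_repeats) {
        len <- as.integer(pr[1L])
        off5 <- as.integer(pr[2L])
        off3 <- as.integer(pr[3L])
        motif <- strsplit(.random_dna(len), "", fixed = TRUE)[[1L]]
        li <- (L - off5 - len + 1L):(L - off5)
        ri <- (off3 + 1L):(off3 + len)
        left[li] <- motif
        right[ri] <- motif
        # guard bases: the copies must not extend each other
        pick_diff <- function(base) sample(setdiff(c("A", "C", "G", "T"),
                                                   base), 1L)
        left[li[1L] - 1L] <- pick_diff(right[ri[1L] - 1L])
        if (ri[length(ri)] + 1L <= R && li[length(li)] + 1L <= L) {
          right[ri[length(ri)] + 1L] <- pick_diff(left[li[length(li)] + 1L])
        }
      }
      list(left = paste(left, collapse = ""),
           right = paste(right, collapse = ""))
    }

    planted_max <- if (length(planted_repeats)) {
      max(vapply(planted_repeats, function(p) as.integer(p[1L]), integer(1)))
    } else 0L
    repeat {
      fl <- build_flanks()
      if (is.null(max_background_mh)) break
      # reject backgrounds whose chance homology exceeds the stated cap
      probe <- structure(list(left_flank = fl$left, right_flank = fl$right,
                              cut_coordinate = L), class = "cut_reference")
      dist <- random_joining_distribution(
        probe, structure(list(max_del_5prime = w5, max_del_3prime = w3),
                         class = "detection_window"))
      if (dist$max_mh <= max(max_background_mh, planted_max)) break
    }

    excised_core <- .random_dna(excised_len - 2L * nchar(ISCEI_SITE))
    excised <- paste0(ISCEI_SITE, excised_core, revcomp(ISCEI_SITE))
    sequence <- paste0(fl$left, excised, fl$right)

    construct <- reporter_construct(
      sequence = sequence,
      cut_sites = list(
        list(position = L, overhang_length = 4L, orientation = "forward"),
        list(position = L + excised_len, overhang_length = 4L,
             orientation = "reverse")),
      excised_interval = c(L + 1L, L + excised_len),
      primer_fwd = substr(fl$left, L - w5 - primer_len + 1L, L - w5),
      primer_rev = revcomp(substr(fl$right, w3 + 1L, w3 + primer_len)),
      name = "synthetic_reporter")
    cutref <- derive_cut_reference(construct)
    list(construct = construct, cutref = cutref,
         window = detection_window(construct, cutref))
  })
}

# draw an insertion whose terminal bases cannot be absorbed into the flank
# matches, so the emitted signature is the canonical one
.draw_insertion <- function(len, left_next, right_prev) {
  bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (!is.na(left_next) && bases[1L] == left_next) {
    bases[1L] <- sample(setdiff(c("A", "C", "G", "T"), left_next), 1L)
  }
  if (!is.na(right_prev) && bases[len] == right_prev) {
    alt <- setdiff(c("A", "C", "G", "T"), right_prev)
    if (len == 1L && !is.na(left_next)) alt <- setdiff(alt, left_next)
    bases[len] <- sample(alt, 1L)
  }
  paste(bases, collapse = "")
}

.apply_seq_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  paste(bases, collapse = "")
}

#' Simulate repair-junction reads with ground truth
#'
#' @param construct a list from [make_construct()], or a
#'   [reporter_construct()] (cut reference and window are derived).
#' @param params a [sim_params()] object.
#' @param cohort cohort label used in read ids (`cohort|mouse|reaction|clone`;
#'   each read gets its own PCR reaction, as in the cloning protocol).
#' @param n_mice mice the cohort's reads are attributed to.
#' @param pair_matrix optional precomputed enumeration from
#'   `nhejscan:::.mh_pair_matrix(cutref, window)`; avoids re-enumerating the
#'   window when simulating many cohorts on one construct.
#' @return list with `reads` (data.frame `id`, `sequence`, `source_reaction`)
#'   and `truth` (data.frame `read_id`, `channel` (`cNHEJ`/`MMEJ`),
#'   `del_5prime`, `del_3prime`, `del_total`, `insertion_seq`,
#'   `insertion_len`, `mh_len`), plus `n_resampled` (MMEJ draws that had to
#'   be resampled).
#' @export
simulate_events <- function(construct, params = sim_params(),
                            cohort = "cohort", n_mice = 5L,
                            pair_matrix = NULL) {
  if (inherits(construct, "reporter_construct")) {
    cutref <- derive_cut_reference(construct)
    window <- detection_window(construct, cutref)
  } else {
    cutref <- construct$cutref
    window <- construct$window
  }
  stopifnot(inherits(cutref, "cut_reference"),
            inherits(window, "detection_window"),
            inherits(params, "sim_params"))

  .with_seed(params$seed, {
    cc <- cutref$cut_coordinate
    left <- cutref$left_flank
    right <- cutref$right_flank
    ref <- paste0(left, right)
    nref <- nchar(ref)

    pm <- if (is.null(pair_matrix)) .mh_pair_matrix(cutref, window)
          else pair_matrix
    mh_at <- function(i, j) pm$mh[i - pm$I[1L] + 1L, j - pm$J[1L] + 1L]
    cand_idx <- which(pm$mh >= params$mmej_min &
                        outer(pm$I, pm$J, function(i, j) j - i - 1L > 0L),
                      arr.ind = TRUE)

    n <- params$n_events
    ids <- sprintf("%s|m%02d|r%03d|c%03d", cohort,
                   rep_len(seq_len(n_mice), n), seq_len(n), seq_len(n))
    reads <- character(n)
    truth <- vector("list", n)
    n_resampled <- 0L

    for (e in seq_len(n)) {
      use_mmej <- stats::runif(1L) < params$p_mmej
      if (use_mmej && nrow(cand_idx) == 0L) {
        .stop_nhej("MMEJ channel requested but the construct offers no microhomology pair >= mmej_min inside the window",
                   "nhej_sim_error")
      }
      if (use_mmej) {
        k <- sample.int(nrow(cand_idx), 1L)
        i <- pm$I[cand_idx[k, 1L]]
        j <- pm$J[cand_idx[k, 2L]]
        ins <- ""
        true_mh <- pm$mh[cand_idx[k, 1L], cand_idx[k, 2L]]
      } else {
        d5 <- .rgeom_trunc(1L, params$resection_mean_5p,
                           window$max_del_5prime)
        d3 <- .rgeom_trunc(1L, params$resection_mean_3p,
                           window$max_del_3prime)
        i <- cc - d5
        j <- cc + 1L + d3
        if (stats::runif(1L) < params$p_insertion) {
          len <- 1L + stats::rgeom(1L, 1 / params$insertion_mean)
          left_next <- if (i < nchar(left)) substr(ref, i + 1L, i + 1L)
                       else NA_character_
          right_prev <- if (j > cc + 1L) substr(ref, j - 1L, j - 1L)
                        else NA_character_
          ins <- .draw_insertion(len, left_next, right_prev)
          true_mh <- 0L
        } else {
          ins <- ""
          # chance microhomology of the emitted junction, from the same
          # enumeration the caller's scoring reproduces
          true_mh <- mh_at(i, j)
        }
      }
      read <- paste0(substr(ref, 1L, i), ins, substr(ref, j, nref))
      reads[e] <- .apply_seq_errors(read, params$seq_error_rate)
      truth[[e]] <- data.frame(
        read_id = ids[e], channel = if (use_mmej) "MMEJ" else "cNHEJ",
        del_5prime = cc - i, del_3prime = j - cc - 1L,
        del_total = j - i - 1L, insertion_seq = ins,
        insertion_len = nchar(ins), mh_len = true_mh,
        stringsAsFactors = FALSE)
    }

    list(reads = data.frame(id = ids, sequence = reads,
                            source_reaction = sprintf("%s|m%02d|r%03d", cohort,
                                                      rep_len(seq_len(n_mice), n),
                                                      seq_len(n)),
                            stringsAsFactors = FALSE),
         truth = do.call(rbind, truth),
         n_resampled = n_resampled)
  })
}

#' Write simulated reads to FASTA
#'
#' @param reads data.frame with `id` and `sequence`.
#' @param path output FASTA path.
#' @return invisibly, the path.
#' @export
write_reads_fasta <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$sequence)
  names(dna) <- reads$id
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Simulate a FACS count table
#'
#' Draws `n_dsred ~ Binom(n_total, dsred_rate)` and
#' `n_gfp ~ Binom(n_total, dsred_rate * true_efficiency)` independently, so
#' the expected GFP/DsRed ratio equals `true_efficiency`.
#'
#' @param true_efficiency expected GFP+/DsRed+ ratio (>= 0; 0 models the
#'   non-leaky mock-transfection baseline with no GFP+ cells).
#' @param n_total cells counted per transfection (default 20000, the assay's
#'   acquisition depth).
#' @param n_replicates transfections (default 4, the per-mouse minimum).
#' @param dsred_rate transfection efficiency (fraction DsRed+).
#' @param sample_prefix sample labels are `prefix_1..n`.
#' @param seed optional seed.
#' @return `facs_counts` data.frame.
#' @export
simulate_facs <- function(true_efficiency, n_total = 20000L,
                          n_replicates = 4L, dsred_rate = 0.15,
                          sample_prefix = "sample", seed = NULL) {
  stopifnot(true_efficiency >= 0, dsred_rate > 0,
            dsred_rate * true_efficiency <= 1)
  .with_seed(seed, {
    n_dsred <- stats::rbinom(n_replicates, n_total, dsred_rate)
    n_gfp <- stats::rbinom(n_replicates, n_total,
                           dsred_rate * true_efficiency)
    validate_facs(data.frame(
      sample = sprintf("%s_%d", sample_prefix, seq_len(n_replicates)),
      n_total = n_total, n_gfp = n_gfp, n_dsred = n_dsred,
      stringsAsFactors = FALSE))
  })
}

#' Per-field recovery of simulated ground truth
#'
#' @param truth ground-truth table from [simulate_events()].
#' @param events called events table from [batch_analyze()].
#' @return object of class `recovery_report`: exact-recovery rates for
#'   `del_total`, `insertion_len` and `mh_len`, the rate of called
#'   `mh_len >= true` (chance extension can only lengthen apparent
#'   microhomology), and the channel-classification confusion table
#'   (true channel versus called MMEJ flag).
#' @export
recovery_report <- function(truth, events) {
  if (is.list(events) && !is.data.frame(events) && !is.null(events$events)) {
    events <- events$events
  }
  if (nrow(truth) == 0L && nrow(events) == 0L) {
    return(structure(list(n = 0L, del_exact = NA_real_, ins_exact = NA_real_,
                          mh_exact = NA_real_, mh_ge = NA_real_,
                          confusion = table(character(0), character(0))),
                     class = "recovery_report"))
  }
  if (!setequal(truth$read_id, events$read_id)) {
    .stop_nhej("truth and called events carry different read ids",
               "nhej_sim_error")
  }
  m <- merge(truth, events, by = "read_id", suffixes = c(".true", ".called"))
  called_channel <- ifelse(m$is_mmej, "MMEJ", "cNHEJ")
  structure(
    list(n = nrow(m),
         del_exact = mean(m$del_total.called == m$del_total.true),
         ins_exact = mean(m$insertion_len.called == m$insertion_len.true),
         mh_exact = mean(m$mh_len.called == m$mh_len.true),
         mh_ge = mean(m$mh_len.called >= m$mh_len.true),
         confusion = table(true = m$channel, called = called_channel)),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery over %d reads:\n", x$n))
  if (x$n > 0L) {
    cat(sprintf("  del_total exact: %.1f%%  insertion_len exact: %.1f%%\n",
                100 * x$del_exact, 100 * x$ins_exact))
    cat(sprintf("  mh_len exact: %.1f%%  (called >= true: %.1f%%)\n",
                100 * x$mh_exact, 100 * x$mh_ge))
    cat("  channel confusion:\n")
    print(x$confusion)
  }
  invisible(x)
}

#' Simulate the full study design
#'
#' Five tissue analogs, two ages, 30 junctions per tissue-by-age cohort
#' (the study's 300-junction design), plus replicate FACS tables realising
#' tissue-specific efficiencies that decline 1.8- to 3.8-fold with age
#' (strongest in skin). Old cohorts use more microhomology, resect more and
#' insert less -- the qualitative aging phenotype the assay reports.
#'
#' @param seed single seed driving construct, junctions and FACS.
#' @param tissues tissue labels.
#' @param n_per_cohort junctions per tissue-by-age cohort.
#' @param young,old `sim_params` templates for the two ages (`n_events` is
#'   overridden by `n_per_cohort`).
#' @param young_efficiency named per-tissue true efficiencies (young).
#' @param fold_decline named per-tissue fold declines with age.
#' @param facs_replicates transfections per tissue-by-age cohort.
#' @return list with `construct`, `cutref`, `window`, `reads`, `truth`
#'   (both carrying `tissue`/`age` columns) and `facs`.
#' @export
simulate_study <- function(seed = 1L,
                           tissues = c("astrocyte", "heart", "kidney",
                                       "lung", "skin"),
                           n_per_cohort = 30L,
                           young = sim_params(p_mmej = 0.15,
                                              resection_mean_5p = 120,
                                              resection_mean_3p = 100,
                                              p_insertion = 0.55,
                                              insertion_mean = 15),
                           old = sim_params(p_mmej = 0.35,
                                            resection_mean_5p = 180,
                                            resection_mean_3p = 150,
                                            p_insertion = 0.40,
                                            insertion_mean = 8),
                           young_efficiency = c(astrocyte = 0.12,
                                                heart = 0.10, kidney = 0.30,
                                                lung = 0.28, skin = 0.32),
                           fold_decline = c(astrocyte = 2.0, heart = 1.8,
                                            kidney = 2.5, lung = 3.0,
                                            skin = 3.8),
                           facs_replicates = 20L) {
  .with_seed(seed, {
    cons <- make_construct()
    pm <- .mh_pair_matrix(cons$cutref, cons$window)
    reads <- list()
    truth <- list()
    facs <- list()
    for (tissue in tissues) {
      for (age in c("young", "old")) {
        par <- if (age == "young") young else old
        par$n_events <- as.integer(n_per_cohort)
        par$seed <- NULL # stay on the study-level stream
        cohort <- paste(tissue, age, sep = "_")
        sim <- simulate_events(cons, par, cohort = cohort, pair_matrix = pm)
        sim$reads$tissue <- tissue
        sim$reads$age <- age
        sim$truth$tissue <- tissue
        sim$truth$age <- age
        reads[[cohort]] <- sim$reads
        truth[[cohort]] <- sim$truth

        eff_y <- young_efficiency[[tissue]]
        eff <- if (age == "young") eff_y else eff_y / fold_decline[[tissue]]
        fc <- simulate_facs(eff, n_replicates = facs_replicates,
                            sample_prefix = cohort)
        fc$tissue <- tissue
        fc$age <- age
        facs[[cohort]] <- fc
      }
    }
    list(construct = cons$construct, cutref = cons$cutref,
         window = cons$window,
         reads = do.call(rbind, c(reads, list(make.row.names = FALSE))),
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
         facs = do.call(rbind, c(facs, list(make.row.names = FALSE))))
  })
}
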