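# junction caller: signature inference, canonicalisation, round-trip,
# dedupe and robustness

test_that("worked examples: microhomology, insertion and exact junctions", {
  cr <- cut_reference("ACGTCAT", "CATGGA")
  p <- default_params()

  ev <- call_junction("ACGTCATGGA", cr, p)
  expect_equal(ev$left_match, 7L)
  expect_equal(ev$right_match, 6L)
  expect_equal(ev$mh_len, 3L)
  expect_equal(ev$insertion_len, 0L)
  expect_equal(ev$del_total, 3L)
  expect_equal(ev$event_class, "deletion")

  ev2 <- call_junction("ACGTCATTTCATGGA", cr, p)
  expect_equal(ev2$left_match, 7L)
  expect_equal(ev2$right_match, 6L)
  expect_identical(ev2$insertion_seq, "TT")
  expect_equal(ev2$mh_len, 0L)
  expect_equal(ev2$del_total, 0L)
  expect_equal(ev2$event_class, "insertion")

  ev3 <- call_junction(paste0("ACGTCAT", "CATGGA"), cr, p)
  expect_equal(ev3$event_class, "exact")
  expect_equal(ev3$del_total, 0L)
  expect_equal(ev3$mh_len, 0L)
  expect_equal(ev3$insertion_len, 0L)

  # reconstruction of the worked examples
  expect_identical(reconstruct_read(ev, cr), "ACGTCATGGA")
  expect_identical(reconstruct_read(ev2, cr), "ACGTCATTTCATGGA")
  expect_identical(reconstruct_read(ev3, cr), "ACGTCATCATGGA")
})

test_that("MMEJ classification boundary sits between 4 and 5 bp", {
  p <- default_params() # mmej_min = 5
  # flanks share a planted k-mer so we can dial the called MH exactly
  for (k in c(4L, 5L, 16L)) {
    motif <- strrep("AC", 8) # 16 bp, no self-extension at junction
    motif <- substr(motif, 1, k)
    left <- paste0("GGGGTTTT", motif)
    right <- paste0(motif, "TTTTGGGG")
    cr <- cut_reference(left, right)
    # junction annealed at the motif: keep left up to motif end, drop the
    # motif copy on the right
    read <- paste0(left, substr(right, k + 1, nchar(right)))
    ev <- call_junction(read, cr, p)
    expect_equal(ev$mh_len, k)
    expect_identical(ev$is_mmej, k >= 5L)
  }
})

test_that("caller equals the exhaustive-decomposition oracle on small flanks", {
  set.seed(201)
  p <- default_params()
  # complete enumeration over random small constructs: every breakpoint
  # pair, with and without insertions
  for (rep in 1:6) {
    left <- rand_dna(sample(5:12, 1))
    right <- rand_dna(sample(5:12, 1))
    cr <- cut_reference(left, right)
    L <- nchar(left)
    R <- nchar(right)
    for (i in 0:L) {
      for (b in 0:R) {
        for (ins in c("", "T", "GAC")) {
          read <- paste0(substr(left, 1, i), ins,
                         substr(right, R - b + 1, R))
          if (!nzchar(read)) next
          orc <- oracle_decompose(read, left, right)
          if (is.null(orc)) {
            expect_error(call_junction(read, cr, p),
                         class = "nhej_unalignable_error")
            next
          }
          ev <- call_junction(read, cr, p)
          expect_equal(ev$left_match, orc$a)
          expect_equal(ev$right_match, orc$b)
          expect_equal(ev$mh_len, orc$mh)
          expect_identical(ev$insertion_seq, orc$ins)
          expect_equal(ev$del_total, orc$del_total)
        }
      }
    }
  }
})

test_that("round-trip and mh <= del_total hold over random larger cases", {
  set.seed(202)
  p <- default_params()
  for (rep in 1:300) {
    left <- rand_dna(sample(20:120, 1))
    right <- rand_dna(sample(20:120, 1))
    cr <- cut_reference(left, right)
    L <- nchar(left)
    R <- nchar(right)
    i <- sample(1:L, 1)
    b <- sample(1:R, 1)
    ins <- if (runif(1) < 0.4) rand_dna(sample(1:20, 1)) else ""
    read <- paste0(substr(left, 1, i), ins, substr(right, R - b + 1, R))
    ev <- call_junction(read, cr, p)
    expect_lte(ev$mh_len, ev$del_total)
    expect_identical(reconstruct_read(ev, cr), read)
  }
})

test_that("appending bases inside an insertion never shrinks it and keeps mh at 0", {
  set.seed(203)
  p <- default_params()
  left <- rand_dna(40)
  right <- rand_dna(40)
  cr <- cut_reference(left, right)
  read <- paste0(substr(left, 1, 30), "GATTACA", substr(right, 11, 40))
  ev <- call_junction(read, cr, p)
  expect_gte(ev$insertion_len, 7L)
  for (extra in c("A", "C", "GG", "TTT")) {
    # grow the insertion from its interior
    read2 <- paste0(substr(left, 1, 30), "GATT", extra, "ACA",
                    substr(right, 11, 40))
    ev2 <- call_junction(read2, cr, p)
    expect_gte(ev2$insertion_len, ev$insertion_len)
    expect_equal(ev2$mh_len, 0L)
  }
})

test_that("N bases terminate match extension", {
  cr <- cut_reference("ACGTACGT", "TTGGCCAA")
  p <- default_params()
  ev <- call_junction("ACGNACGTTTGGCCAA", cr, p)
  expect_equal(ev$left_match, 3L) # stops at the N
  expect_equal(ev$right_match, 8L)
  # N in the flank likewise
  crn <- cut_reference("ACGNACGT", "TTGGCCAA")
  evn <- call_junction("ACGTACGTTTGGCCAA", crn, p)
  expect_equal(evn$left_match, 3L)
})

test_that("inconsistent events are rejected by reconstruct_read", {
  cr <- cut_reference("ACGTCAT", "CATGGA")
  bad <- structure(list(left_match = 5L, right_match = 4L, mh_len = 2L,
                        insertion_seq = "AA", insertion_len = 2L),
                   class = "repair_event")
  expect_error(reconstruct_read(bad, cr), class = "nhej_event_error")
})

test_that("per-reaction uniqueness rule dedupes within but not across reactions", {
  set.seed(204)
  left <- rand_dna(30)
  right <- rand_dna(30)
  cr <- cut_reference(left, right)
  read <- paste0(substr(left, 1, 25), substr(right, 6, 30))
  reads <- data.frame(
    id = c("a", "b", "c", "d"),
    sequence = c(read, read, read, paste0(left, right)),
    source_reaction = c("r1", "r1", "r2", "r1"),
    stringsAsFactors = FALSE)
  res <- batch_analyze(reads, cr, default_params(), dedupe = TRUE)
  # identical junction from r1 kept once; same junction from r2 kept;
  # distinct junction from r1 kept
  expect_equal(nrow(res$events), 3L)
  expect_setequal(res$events$read_id, c("a", "c", "d"))
  expect_equal(unname(res$log["n_duplicates"]), 1L)

  res2 <- batch_analyze(reads, cr, default_params(), dedupe = FALSE)
  expect_equal(nrow(res2$events), 4L)
})

test_that("unalignable reads land in the rejects table, not the events", {
  set.seed(205)
  cr <- cut_reference(rand_dna(30), rand_dna(30))
  reads <- data.frame(
    id = c("good", "junk"),
    sequence = c(paste0(cr$left_flank, cr$right_flank), strrep("N", 40)),
    stringsAsFactors = FALSE)
  res <- batch_analyze(reads, cr, default_params())
  expect_equal(nrow(res$events), 1L)
  expect_equal(res$rejects$read_id, "junk")
  expect_equal(unname(res$log["n_unalignable"]), 1L)
})

test_that("amplicon reads starting at the forward primer are anchored, not penalised", {
  set.seed(206)
  cons <- toy_construct(rand_dna(50), rand_dna(20), rand_dna(50),
                        primer_len = 10, fwd_start = 11, rev_end = 40)
  cr <- derive_cut_reference(cons)
  p <- call_params(trim_primers = TRUE, flag_ad_retained = FALSE)
  # full-flank read and primer-to-primer amplicon of the same exact junction
  full <- paste0(cr$left_flank, cr$right_flank)
  amplicon <- paste0(substr(cr$left_flank, 11, 50), substr(cr$right_flank, 1, 40))
  ev_full <- call_junction(full, cr, p)
  ev_amp <- call_junction(amplicon, cr, p)
  expect_equal(ev_full$event_class, "exact")
  expect_equal(ev_amp$event_class, "exact")
  expect_equal(ev_amp$del_total, 0L)
})

test_that("deletions beyond the rescue window are flagged", {
  set.seed(207)
  left <- rand_dna(60)
  right <- rand_dna(60)
  cr <- cut_reference(left, right)
  w <- structure(list(max_del_5prime = 10L, max_del_3prime = 10L),
                 class = "detection_window")
  p <- call_params(window = w, trim_primers = FALSE,
                   flag_ad_retained = FALSE)
  ok <- call_junction(paste0(substr(left, 1, 55), substr(right, 6, 60)), cr, p)
  expect_false(ok$outside_window)
  far <- call_junction(paste0(substr(left, 1, 20), substr(right, 6, 60)), cr, p)
  expect_true(far$outside_window)
})

test_that("killer-exon retention is flagged and excluded from summaries", {
  set.seed(208)
  cons <- toy_construct(rand_dna(40), rand_dna(60), rand_dna(40),
                        primer_len = 6)
  cr <- derive_cut_reference(cons)
  p <- call_params(trim_primers = FALSE, flag_ad_retained = TRUE)
  # read retaining 30 bp of the excised segment looks like an insertion
  excised <- attr(cr, "excised_seq")
  read <- paste0(cr$left_flank, substr(excised, 1, 30), cr$right_flank)
  ev <- call_junction(read, cr, p)
  expect_true(ev$ad_retained)
  normal <- call_junction(paste0(cr$left_flank, cr$right_flank), cr, p)
  events <- rbind(as.data.frame(unclass(ev), stringsAsFactors = FALSE),
                  as.data.frame(unclass(normal), stringsAsFactors = FALSE))
  s <- summarize_cohort(events, default_params())
  expect_equal(s$n_junctions, 1L)
})

test_that("mismatch-tolerant mode recovers noisy flank matches", {
  set.seed(209)
  left <- rand_dna(50)
  right <- rand_dna(50)
  cr <- cut_reference(left, right)
  read <- paste0(substr(left, 1, 45), substr(right, 6, 50))
  # corrupt one base mid-left-match
  bases <- strsplit(read, "", fixed = TRUE)[[1]]
  bases[20] <- setdiff(c("A", "C", "G", "T"), bases[20])[1]
  noisy <- paste(bases, collapse = "")
  strict <- call_junction(noisy, cr, default_params())
  tolerant <- call_junction(noisy, cr, default_params(max_mismatch = 1L))
  expect_lt(strict$left_match, tolerant$left_match)
  expect_gte(tolerant$left_match, 45L)
})
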