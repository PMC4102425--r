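# synthetic-data generator: determinism, ground-truth consistency,
# planted-repeat behaviour, FACS sampling

test_that("construct generation is deterministic under a fixed seed", {
  a <- make_construct(seed = 11, intron_len_5p = 120, intron_len_3p = 120,
                      excised_len = 40, planted_repeats = list(c(6, 20, 20)),
                      window = c(80, 80), primer_len = 10)
  b <- make_construct(seed = 11, intron_len_5p = 120, intron_len_3p = 120,
                      excised_len = 40, planted_repeats = list(c(6, 20, 20)),
                      window = c(80, 80), primer_len = 10)
  expect_identical(a$construct$sequence, b$construct$sequence)
  expect_identical(a$construct$primer_fwd, b$construct$primer_fwd)

  r1 <- simulate_events(a, sim_params(n_events = 25, seed = 7))
  r2 <- simulate_events(a, sim_params(n_events = 25, seed = 7))
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$truth, r2$truth)
})

test_that("default construct realises the assay geometry", {
  mc <- make_construct(seed = 12)
  expect_equal(mc$window$max_del_5prime, 886L)
  expect_equal(mc$window$max_del_3prime, 750L)
  # planted 16-bp repeat is the longest microhomology, exactly
  expect_equal(longest_mh(mc$cutref, mc$window), 16)
  # I-SceI recognition sites sit inverted at the excised-segment ends
  excised <- attr(mc$cutref, "excised_seq")
  expect_true(startsWith(excised, "TAGGGATAACAGGGTAAT"))
  expect_true(endsWith(excised, revcomp("TAGGGATAACAGGGTAAT")))
})

test_that("colliding planted repeats are rejected", {
  expect_error(
    make_construct(seed = 13, intron_len_5p = 120, intron_len_3p = 120,
                   excised_len = 40,
                   planted_repeats = list(c(8, 20, 20), c(8, 22, 40)),
                   window = c(80, 80), primer_len = 10),
    class = "nhej_sim_error")
  expect_error(
    make_construct(seed = 13, intron_len_5p = 120, intron_len_3p = 120,
                   excised_len = 40, planted_repeats = list(c(8, 200, 20)),
                   window = c(80, 80), primer_len = 10),
    class = "nhej_sim_error")
})

test_that("ground truth is consistent with the emitted reads", {
  mc <- make_construct(seed = 14, intron_len_5p = 200, intron_len_3p = 200,
                       excised_len = 60,
                       planted_repeats = list(c(7, 30, 25)),
                       window = c(150, 150), primer_len = 12)
  sim <- simulate_events(mc, sim_params(n_events = 150, p_mmej = 0.3,
                                        resection_mean_5p = 25,
                                        resection_mean_3p = 20, seed = 15))
  ref <- paste0(mc$cutref$left_flank, mc$cutref$right_flank)
  cc <- mc$cutref$cut_coordinate
  for (k in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[k, ]
    expected <- paste0(substr(ref, 1, cc - tr$del_5prime), tr$insertion_seq,
                       substr(ref, cc + 1 + tr$del_3prime, nchar(ref)))
    expect_identical(sim$reads$sequence[k], expected)
    expect_equal(tr$del_total, tr$del_5prime + tr$del_3prime)
  }
  # deletions respect the detection window (truncated sampling)
  expect_lte(max(sim$truth$del_5prime), 150)
  expect_lte(max(sim$truth$del_3prime), 150)
  # MMEJ-channel events carry >= mmej_min of true homology
  expect_true(all(sim$truth$mh_len[sim$truth$channel == "MMEJ"] >= 5))
})

test_that("p_mmej = 1 with a single planted repeat yields called mh >= planted", {
  mc <- make_construct(seed = 16, intron_len_5p = 100, intron_len_3p = 100,
                       excised_len = 40, planted_repeats = list(c(6, 25, 20)),
                       window = c(60, 60), primer_len = 12,
                       max_background_mh = 4)
  sim <- simulate_events(mc, sim_params(n_events = 40, p_mmej = 1, seed = 17))
  res <- batch_analyze(sim$reads, mc$cutref, default_params(), dedupe = FALSE)
  expect_equal(nrow(res$events), 40L)
  expect_true(all(res$events$mh_len >= 5))
})

test_that("error-free simulation recovers truth exactly; errors degrade it", {
  mc <- make_construct(seed = 18)
  pm <- nhejscan:::.mh_pair_matrix(mc$cutref, mc$window)
  sim <- simulate_events(mc, sim_params(n_events = 200, seed = 19),
                         pair_matrix = pm)
  res <- batch_analyze(sim$reads, mc$cutref,
                       call_params(window = mc$window), dedupe = FALSE)
  rec <- recovery_report(sim$truth, res$events)
  expect_equal(rec$del_exact, 1)
  expect_equal(rec$ins_exact, 1)
  expect_equal(rec$mh_ge, 1)

  noisy <- simulate_events(mc, sim_params(n_events = 200,
                                          seq_error_rate = 0.01, seed = 19),
                           pair_matrix = pm)
  res_n <- batch_analyze(noisy$reads, mc$cutref,
                         call_params(window = mc$window), dedupe = FALSE)
  # reads are ~1.6 kb, so at 1% error essentially every read is hit
  keep <- intersect(noisy$truth$read_id, res_n$events$read_id)
  rec_n <- recovery_report(noisy$truth[noisy$truth$read_id %in% keep, ],
                           res_n$events[res_n$events$read_id %in% keep, ])
  expect_lt(rec_n$del_exact, rec$del_exact)
})

test_that("empty truth against empty calls gives an empty report", {
  rec <- recovery_report(data.frame(read_id = character(0)),
                         data.frame(read_id = character(0)))
  expect_equal(rec$n, 0L)
})

test_that("mismatched read ids are an error", {
  expect_error(
    recovery_report(data.frame(read_id = "x"),
                    data.frame(read_id = "y", is_mmej = FALSE,
                               del_total = 0L, insertion_len = 0L,
                               mh_len = 0L)),
    class = "nhej_sim_error")
})

test_that("FACS simulation: concentration, zero efficiency, determinism", {
  # zero efficiency -> no GFP+ cells (non-leaky baseline)
  f0 <- simulate_facs(0, n_replicates = 6, seed = 21)
  expect_true(all(f0$n_gfp == 0))

  # large counts: estimated efficiency within 3 binomial sd of truth
  eff <- 0.3
  f <- simulate_facs(eff, n_total = 20000, n_replicates = 8,
                     dsred_rate = 0.2, seed = 22)
  est <- mean(nhej_efficiency(f))
  sd3 <- 3 * sqrt(eff * 0.2 * (1 - eff * 0.2) / 20000) / 0.2 / sqrt(8)
  expect_lt(abs(est - eff), max(3 * sd3, 0.02))

  expect_identical(simulate_facs(0.25, seed = 23),
                   simulate_facs(0.25, seed = 23))
})

test_that("study-level simulation is deterministic and carries the full design", {
  s1 <- simulate_study(seed = 24, n_per_cohort = 5, facs_replicates = 4)
  s2 <- simulate_study(seed = 24, n_per_cohort = 5, facs_replicates = 4)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$facs, s2$facs)
  expect_equal(nrow(s1$reads), 5 * 2 * 5)
  expect_setequal(unique(s1$reads$age), c("young", "old"))
  expect_equal(length(unique(s1$reads$tissue)), 5L)
})

test_that("reads FASTA round-trips through Biostrings with parseable ids", {
  mc <- make_construct(seed = 25, intron_len_5p = 100, intron_len_3p = 100,
                       excised_len = 40, planted_repeats = list(),
                       window = c(60, 60), primer_len = 12)
  sim <- simulate_events(mc, sim_params(n_events = 10, p_mmej = 0, seed = 26),
                         cohort = "lung_young")
  fa <- tempfile(fileext = ".fa")
  write_reads_fasta(sim$reads, fa)
  back <- read_junctions(fa)
  expect_identical(back$sequence, sim$reads$sequence)
  expect_identical(back$id, sim$reads$id)
  expect_true(all(back$cohort == "lung_young"))
  expect_false(anyNA(back$source_reaction))
})
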