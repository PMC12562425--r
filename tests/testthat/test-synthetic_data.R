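test_that("cohort generation is deterministic given the seed", {
  m <- cdh1_model()
  prof <- cdh1_event_profile(m)
  s1 <- generate_cohort(prof, sim_config(n_samples = 4, depth = 5000,
                                         seed = 9), m)
  s2 <- generate_cohort(prof, sim_config(n_samples = 4, depth = 5000,
                                         seed = 9), m)
  expect_identical(s1$cohort$junctions, s2$cohort$junctions)
  expect_identical(s1$truth, s2$truth)
  # and the emitted files are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(s1$cohort, d1); write_cohort(s2$cohort, d2)
  f <- "LCL01.junctions.bed"
  expect_identical(readLines(file.path(d1, f)),
                   readLines(file.path(d2, f)))
  s3 <- generate_cohort(prof, sim_config(n_samples = 4, depth = 5000,
                                         seed = 10), m)
  expect_false(identical(s1$cohort$junctions, s3$cohort$junctions))
})

test_that("the packaged profile carries the 11 published events", {
  prof <- cdh1_event_profile()
  expect_equal(nrow(prof$events), 11)
  expect_equal(sum(grepl("AFE", prof$events$name)), 6)
  expect_equal(prof$events$true_ratio_pct[prof$events$name == "D11"], 14.1)
  expect_equal(prof$events$true_ratio_pct[prof$events$name == "D6"], 4.4)
  expect_equal(prof$events$recurrence_pct[prof$events$name == "D13q"], 50)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_event_profile(prof, p)
  prof2 <- read_event_profile(p)
  expect_equal(prof2$events$true_ratio_pct, prof$events$true_ratio_pct)
  expect_equal(prof2$depth, prof$depth)
})

test_that("the NMD suppression factor scales untreated cohorts", {
  m <- cdh1_model()
  prof <- cdh1_event_profile(m)
  skip11 <- event_profile(prof$events[prof$events$name == "D11", ],
                          depth = 10000, chrom = prof$chrom)
  ratios <- vapply(1:4, function(seed) {
    sim <- generate_cohort(skip11,
                           sim_config(n_samples = 20, depth = 10000,
                                      puromycin = FALSE, nmd_factor = 0.2,
                                      seed = seed), m)
    ev <- annotate_cohort(sim$cohort, m)
    q <- quantify_cohort(ev, m)
    mean(q$ratio_pct[q$kind == "exon_skip"])
  }, 0)
  expect_equal(mean(ratios), 0.2 * 14.1, tolerance = 0.05)
  # treated cohorts sit at the full ratio
  sim_t <- generate_cohort(skip11, sim_config(n_samples = 20,
                                              depth = 10000, seed = 1), m)
  q_t <- quantify_cohort(annotate_cohort(sim_t$cohort, m), m)
  expect_gt(mean(q_t$ratio_pct[q_t$kind == "exon_skip"]),
            3 * mean(ratios))
})

test_that("observed recurrence stays within binomial bounds of the target", {
  m <- cdh1_model()
  prof <- cdh1_event_profile(m)
  sim <- generate_cohort(prof, sim_config(n_samples = 20, seed = 77), m)
  ev <- annotate_cohort(sim$cohort, m, cdh1_known_junctions())
  q <- quantify_cohort(ev, m)
  cp <- cohort_profile(q, n_samples = 20, reported_only = FALSE)
  for (i in seq_len(nrow(prof$events))) {
    row <- cp[cp$g_start == prof$events$g_start[i] &
                cp$g_end == prof$events$g_end[i], ]
    n_pass <- row$n_pass
    p <- prof$events$recurrence_pct[i] / 100
    # exact binomial 95% interval around the configured recurrence
    lo <- stats::qbinom(0.025, 20, p)
    hi <- stats::qbinom(0.975, 20, p)
    expect_true(n_pass >= lo && n_pass <= hi,
                info = prof$events$name[i])
  }
})

test_that("ground truth is separate from the pipeline's inputs", {
  m <- cdh1_model()
  sim <- generate_cohort(cdh1_event_profile(m), sim_config(n_samples = 3), m)
  # the cohort object exposes only junction observations
  expect_false(any(c("true_ratio_pct", "expected_ratio_pct", "present")
                   %in% names(sim$cohort$junctions)))
  expect_s3_class(sim$cohort, "cohort_table")
  expect_true(all(c("expected_ratio_pct", "present") %in% names(sim$truth)))
})

test_that("undetectable events at low depth raise a warning", {
  m <- cdh1_model()
  prof <- cdh1_event_profile(m)
  expect_warning(generate_cohort(prof, sim_config(n_samples = 2,
                                                  depth = 50, seed = 1), m),
                 "too low")
})

test_that("spikes reject conflicting spans and honour target ratios", {
  m <- cdh1_model()
  sj <- canonical_sample(m, depth = 10000)
  cj <- canonical_junctions(m)
  i7 <- cj[cj$intron_index == 7, ]
  expect_error(spike_variant_carrier(sj, m,
                                     data.frame(g_start = i7$g_start,
                                                g_end = i7$g_end,
                                                target_ratio_pct = 50)),
               "conflicts")
  spiked <- spike_variant_carrier(sj, m,
                                  data.frame(g_start = 68846529,
                                             g_end = 68847521,
                                             target_ratio_pct = 135))
  new <- spiked[spiked$g_start == 68846529, ]
  expect_equal(new$reads, round(1.35 * 10000))
  # imbalance factor scales the counterpart before the spike is computed
  spiked2 <- spike_variant_carrier(sj, m,
                                   data.frame(g_start = 68846529,
                                              g_end = 68847521,
                                              target_ratio_pct = 100),
                                   imbalance_factor = 0.2)
  expect_equal(spiked2$reads[spiked2$g_start == i7$g_start &
                               spiked2$g_end == i7$g_end], 2000)
  expect_equal(spiked2$reads[spiked2$g_start == 68846529], 2000)
})
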