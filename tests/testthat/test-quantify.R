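test_that("expression ratio uses the physiological counterpart junction", {
  m <- cdh1_model()
  sj <- canonical_sample(m, depth = 1000)
  # intron-7 canonical at 1759 reads, +7 retention at 2373 reads -> 134.9%
  cj <- canonical_junctions(m)
  sj$reads[cj$intron_index == 7] <- 1759
  sj <- add_junction(sj, 68846529, 68847521, 2373)
  ev <- annotate_sample(sj, m)
  q <- quantify_cohort(transform(ev, sample_id = "S1"), m)
  alt <- q[q$kind == "intronic_donor_shift", ]
  expect_equal(alt$ratio_pct, 100 * 2373 / 1759, tolerance = 1e-10)
  expect_equal(round(alt$ratio_pct, 1), 134.9)

  # exon skip: denominator is the mean of the two flanking canonicals
  sj2 <- canonical_sample(m, depth = 1000)
  sj2 <- add_junction(sj2, 68849679, 68856499, 141)  # exon-11 skip
  ev2 <- annotate_sample(sj2, m)
  q2 <- quantify_cohort(transform(ev2, sample_id = "S1"), m)
  expect_equal(q2$ratio_pct[q2$kind == "exon_skip"], 14.1)

  # upstream-only denominator switch
  sj3 <- sj2
  sj3$reads[cj$intron_index == 10] <- 500
  ev3 <- annotate_sample(sj3, m)
  q3m <- quantify_cohort(transform(ev3, sample_id = "S1"), m,
                         denominator = "mean")
  q3u <- quantify_cohort(transform(ev3, sample_id = "S1"), m,
                         denominator = "upstream")
  expect_equal(q3m$ratio_pct[q3m$kind == "exon_skip"], 100 * 141 / 750)
  expect_equal(q3u$ratio_pct[q3u$kind == "exon_skip"], 100 * 141 / 500)

  # zero alternative reads -> 0%; zero counterpart -> flagged NA, not Inf
  sj4 <- canonical_sample(m, depth = 1000)
  sj4 <- add_junction(sj4, 68846529, 68847521, 0)
  q4 <- quantify_cohort(transform(annotate_sample(sj4, m), sample_id = "S1"), m)
  expect_equal(q4$ratio_pct[q4$kind == "intronic_donor_shift"], 0)
  sj5 <- canonical_sample(m, depth = 0)
  sj5 <- add_junction(sj5, 68846529, 68847521, 50)
  q5 <- quantify_cohort(transform(annotate_sample(sj5, m), sample_id = "S1"), m)
  alt5 <- q5[q5$kind == "intronic_donor_shift", ]
  expect_true(is.na(alt5$ratio_pct))
  expect_match(alt5$fail_reason, "zero counterpart")
})

test_that("reporting filters apply the read and ratio cutoffs", {
  m <- cdh1_model()
  cj <- canonical_junctions(m)
  sj <- canonical_sample(m, depth = 1000)
  sj$reads[cj$intron_index == 7] <- 1759
  sj <- add_junction(sj, 68846529, 68847521, 228)     # 13.0%, 228 reads
  sj <- add_junction(sj, 68846547, 68847521, 99)      # +25: below min_reads
  sj <- add_junction(sj, 68849679, 68856499, 5000)    # skip, high reads
  cj11 <- cj$intron_index %in% c(10, 11)
  sj$reads[cj11] <- 5000 / 0.0005                     # ratio 0.05%
  ev <- transform(annotate_sample(sj, m), sample_id = "S1")
  q <- quantify_cohort(ev, m)
  ret7 <- q[q$g_start == 68846529, ]
  expect_true(ret7$pass)
  expect_equal(round(ret7$ratio_pct, 1), 13)
  ret25 <- q[q$g_start == 68846547, ]
  expect_false(ret25$pass)
  expect_equal(ret25$fail_reason, "min_reads")
  skip <- q[q$kind == "exon_skip", ]
  expect_false(skip$pass)
  expect_equal(skip$fail_reason, "min_ratio")

  # strictness of the ratio cutoff is configurable
  sj6 <- canonical_sample(m, depth = 100000)
  sj6 <- add_junction(sj6, 68846529, 68847521, 100)   # exactly 0.1%
  ev6 <- transform(annotate_sample(sj6, m), sample_id = "S1")
  q_strict <- quantify_cohort(ev6, m, filter_config(strict_ratio = TRUE))
  q_incl <- quantify_cohort(ev6, m, filter_config(strict_ratio = FALSE))
  expect_false(q_strict$pass[q_strict$g_start == 68846529])
  expect_true(q_incl$pass[q_incl$g_start == 68846529])
})

test_that("recurrence is the filter-passing fraction of the cohort", {
  expect_equal(recurrence(17, 20), 85)
  expect_equal(recurrence(0, 20), 0)
  expect_equal(recurrence(10, 20), 50)
  expect_error(recurrence(1, 0), "empty cohort")
})

test_that("confidence tiers follow depth and overhang rules", {
  cfg <- confidence_config()
  expect_equal(confidence_tier(60, 35, 40, cfg), "high")
  expect_equal(confidence_tier(40, 31, 33, cfg), "moderate")
  expect_equal(confidence_tier(400, 12, 45, cfg), "low")
  expect_equal(confidence_tier(30, 30, 30, cfg), "moderate")
  expect_equal(confidence_tier(29, 40, 40, cfg), "low")
  expect_equal(confidence_tier(51, 30, 30, cfg), "high")
})

test_that("ratios are scale-invariant and monotone in alternative reads", {
  m <- cdh1_model()
  sj <- canonical_sample(m, depth = 1200)
  sj <- add_junction(sj, 68849679, 68856499, 170)
  sj <- add_junction(sj, 68846529, 68847521, 333)
  q1 <- quantify_cohort(transform(annotate_sample(sj, m), sample_id = "S"), m)
  sjx <- sj; sjx$reads <- sjx$reads * 7L
  q7 <- quantify_cohort(transform(annotate_sample(sjx, m), sample_id = "S"), m)
  expect_equal(q7$ratio_pct, q1$ratio_pct)

  ratios <- vapply(c(100, 200, 400, 800), function(r) {
    s <- canonical_sample(m, depth = 1000)
    s <- add_junction(s, 68849679, 68856499, r)
    q <- quantify_cohort(transform(annotate_sample(s, m), sample_id = "S"), m)
    q$ratio_pct[q$kind == "exon_skip"]
  }, 0)
  expect_true(all(diff(ratios) > 0))
})

test_that("cohort mean ratios recover the simulated truth", {
  m <- cdh1_model()
  prof <- cdh1_event_profile(m)
  skip11 <- prof$events[prof$events$name == "D11", ]
  p <- event_profile(skip11, depth = 10000, chrom = prof$chrom)
  means <- vapply(1:3, function(seed) {
    sim <- generate_cohort(p, sim_config(n_samples = 20, depth = 10000,
                                         seed = seed), m)
    ev <- annotate_cohort(sim$cohort, m)
    q <- quantify_cohort(ev, m)
    mean(q$ratio_pct[q$kind == "exon_skip"])
  }, 0)
  expect_equal(mean(means), 14.1, tolerance = 0.03 * 14.1)
})
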