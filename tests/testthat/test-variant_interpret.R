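# Build a CDH1-like control cohort once per file; carriers are spiked
# copies of a control sample.
local_cdh1_cohort <- function(n = 8, depth = 10000, seed = 301) {
  m <- cdh1_model()
  prof <- cdh1_event_profile(m)
  sim <- generate_cohort(prof, sim_config(n_samples = n, depth = depth,
                                          seed = seed), m)
  list(model = m, cohort = sim$cohort)
}

with_carrier <- function(base, carrier_junctions, id = "CARRIER") {
  carrier_junctions$sample_id <- id
  samples <- rbind(base$cohort$samples,
                   data.frame(sample_id = id, puromycin = TRUE,
                              provenance = "synthetic junction counts"))
  cohort_table(samples, rbind(base$cohort$junctions, carrier_junctions))
}

test_that("a dominant truncating intron-7 retention pair is pathogenic-supporting", {
  base <- local_cdh1_cohort()
  m <- base$model
  donor_sample <- base$cohort$junctions[
    base$cohort$junctions$sample_id == "LCL01", ]
  spikes <- data.frame(g_start = c(68846529, 68846547),
                       g_end = c(68847521, 68847521),
                       target_ratio_pct = c(135, 13))
  carrier <- spike_variant_carrier(donor_sample, m, spikes)
  cohort <- with_carrier(base, carrier)
  a <- assess_variant("CARRIER", cohort, "c.1008+1", m,
                      cdh1_known_junctions())
  expect_equal(a$evidence, "splicing_altering_pathogenic_supporting")
  expect_equal(nrow(a$aberrant_events), 2)
  expect_setequal(a$aberrant_events$shorthand, c("▼7p", "▼7p"))
  expect_true(all(a$aberrant_events$frame == "frameshift"))
  expect_false(a$allelic_imbalance)
})

test_that("a dominant exon-12 donor shift with allele depletion flags imbalance", {
  base <- local_cdh1_cohort()
  m <- base$model
  donor_sample <- base$cohort$junctions[
    base$cohort$junctions$sample_id == "LCL02", ]
  spikes <- data.frame(g_start = cdna_to_genomic(m, "c.1831"),
                       g_end = m$exons$g_start[13] - 1,
                       target_ratio_pct = 248)
  carrier <- spike_variant_carrier(donor_sample, m, spikes,
                                   imbalance_factor = 0.2)
  cohort <- with_carrier(base, carrier)
  a <- assess_variant("CARRIER", cohort, "c.1936+5", m,
                      cdh1_known_junctions())
  expect_equal(a$evidence, "splicing_altering_pathogenic_supporting")
  expect_equal(a$aberrant_events$shorthand, "Δ12q")
  expect_equal(a$aberrant_events$r_description, "r.1831_1936del")
  expect_true(a$allelic_imbalance)
})

test_that("a carrier identical to the controls shows no splicing effect", {
  base <- local_cdh1_cohort()
  m <- base$model
  carrier <- base$cohort$junctions[
    base$cohort$junctions$sample_id == "LCL03", ]
  carrier$sample_id <- NULL
  cohort <- with_carrier(base, carrier)
  a <- assess_variant("CARRIER", cohort, "c.1566-10", m,
                      cdh1_known_junctions())
  expect_equal(a$evidence, "no_splicing_effect_detected")
  expect_equal(nrow(a$aberrant_events), 0)
})

test_that("leave-one-out on the null cohort produces no pathogenic calls", {
  base <- local_cdh1_cohort(n = 10, seed = 902)
  m <- base$model
  for (id in base$cohort$samples$sample_id) {
    a <- assess_variant(id, base$cohort, "c.1566-10", m,
                        cdh1_known_junctions())
    expect_false(a$evidence == "splicing_altering_pathogenic_supporting",
                 info = id)
  }
})

test_that("spiked truncating carriers are detected in at least 95% of seeds", {
  m <- cdh1_model()
  prof <- cdh1_event_profile(m)
  hits <- vapply(1:20, function(seed) {
    sim <- generate_cohort(prof, sim_config(n_samples = 6, depth = 10000,
                                            seed = 1000 + seed), m)
    donor <- sim$cohort$junctions[sim$cohort$junctions$sample_id == "LCL01", ]
    spikes <- data.frame(g_start = 68846529, g_end = 68847521,
                         target_ratio_pct = 60)
    carrier <- spike_variant_carrier(donor, m, spikes)
    carrier$sample_id <- "CARRIER"
    cohort <- cohort_table(
      rbind(sim$cohort$samples,
            data.frame(sample_id = "CARRIER", puromycin = TRUE,
                       provenance = "synthetic junction counts")),
      rbind(sim$cohort$junctions, carrier))
    a <- assess_variant("CARRIER", cohort, "c.1008+1", m)
    a$evidence == "splicing_altering_pathogenic_supporting"
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("variant assessment validates its inputs and serialises", {
  base <- local_cdh1_cohort(n = 4)
  m <- base$model
  expect_error(assess_variant("NOPE", base$cohort, "c.1008+1", m),
               "not found")
  expect_error(assess_variant("LCL01", base$cohort, "c.99999", m),
               "outside")
  a <- assess_variant("LCL01", base$cohort, "c.1566-10", m,
                      scores = c(spip = "98.41% [91.47-99.96]",
                                 spliceai = "0.95"))
  p <- withr::local_tempfile(fileext = ".json")
  write_assessment(a, p)
  j <- jsonlite::fromJSON(p)
  expect_equal(j$evidence, a$evidence)
  expect_equal(j$scores$spip, "98.41% [91.47-99.96]")
})
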