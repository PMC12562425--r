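test_that("worked examples type to the expected kinds", {
  m <- cdh1_model()
  cj <- canonical_junctions(m)
  ctx <- cj[, c("g_start", "g_end")]

  # gap spanning intron 10 + exon 11 + intron 11 -> skip of exon 11
  ev <- classify_junction(m, 68849679, 68856499, ctx)
  expect_equal(ev$kind, "exon_skip")
  expect_equal(ev$skipped, 11L)
  expect_equal(ev$shorthand, "Δ11")

  # gap equal to canonical intron 5
  i5 <- cj[cj$intron_index == 5, ]
  expect_equal(classify_junction(m, i5$g_start, i5$g_end, ctx)$kind,
               "canonical")

  # donor 7 bases into intron 7, acceptor at exon 8 start, canonical
  # exon-7 donor junction present in context -> intronic donor shift
  ev2 <- classify_junction(m, 68846529, 68847521, ctx)
  expect_equal(ev2$kind, "intronic_donor_shift")
  expect_equal(ev2$r_description, "r.1008_1009ins1008+1_1008+7")

  # donor deep in intron 2, acceptor at exon 3 start, no cryptic partner
  ev3 <- classify_junction(m, 68825358, 68836615, ctx)
  expect_equal(ev3$kind, "alt_first_exon")

  # same deep donor but a cryptic-exon partner junction from exon 2's end
  # into intron 2 upstream of the donor -> retention interpretation
  ctx2 <- rbind(ctx, data.frame(g_start = 68773358, g_end = 68800000))
  ev4 <- classify_junction(m, 68825358, 68836615, ctx2)
  expect_equal(ev4$kind, "intronic_donor_shift")

  # junction outside the gene span
  ev5 <- classify_junction(m, 100, 200)
  expect_equal(ev5$kind, "unresolved")
  expect_match(ev5$reason, "outside")
  expect_error(classify_junction(m, 200, 100), "gap")
})

test_that("alt-first-exon inference requires sufficient sample depth", {
  m <- cdh1_model()
  ctx <- canonical_junctions(m)[, c("g_start", "g_end")]
  deep <- classify_junction(m, 68825358, 68836615, ctx, context_depth = 10)
  expect_equal(deep$kind, "unresolved")
  expect_match(deep$reason, "depth")
  ok <- classify_junction(m, 68825358, 68836615, ctx, context_depth = 1e5)
  expect_equal(ok$kind, "alt_first_exon")
})

test_that("multi-exon skips report the full skipped set and length", {
  m <- cdh1_model()
  # canonical donor of intron 3, canonical acceptor of intron 11: skip 4-11
  gap <- c(m$exons$g_end[3] + 1, m$exons$g_start[12] - 1)
  ev <- classify_junction(m, gap[1], gap[2])
  expect_equal(ev$kind, "exon_skip")
  expect_equal(ev$skipped, 4:11)
  r <- parse_r_description(ev$r_description)
  expect_equal(r$length,
               sum(m$exons$g_end[4:11] - m$exons$g_start[4:11] + 1))
})

test_that("classification agrees with the brute-force oracle on toy models", {
  set.seed(11)
  opts <- classify_opts(max_shift_offset = 2000, afe_min_depth = 0)
  for (rep in 1:6) {
    m <- random_toy_model()
    span <- range(m$exons$g_start, m$exons$g_end)
    # coarse grid: all exon/intron boundaries +/- 1 plus interior points
    bounds <- sort(unique(c(m$exons$g_start, m$exons$g_end,
                            m$exons$g_start - 1, m$exons$g_end + 1,
                            m$exons$g_start + 2, m$exons$g_end - 2)))
    bounds <- bounds[bounds >= span[1] & bounds <= span[2]]
    grid <- expand.grid(s = bounds, e = bounds)
    grid <- grid[grid$s < grid$e, ]
    ctx <- data.frame(g_start = grid$s, g_end = grid$e)
    got <- vapply(seq_len(nrow(grid)), function(i) {
      classify_junction(m, grid$s[i], grid$e[i], context = ctx,
                        opts = opts)$kind
    }, "")
    want <- vapply(seq_len(nrow(grid)), function(i) {
      oracle_classify(m, grid$s[i], grid$e[i], context = ctx,
                      max_shift = 2000)
    }, "")
    expect_equal(got, want,
                 info = sprintf("model rep %d (%s strand)", rep, m$strand))
  }
})

test_that("classification depends on input order only through context membership", {
  m <- cdh1_model()
  ctx <- canonical_junctions(m)[, c("g_start", "g_end")]
  shuffled <- ctx[sample(nrow(ctx)), ]
  a <- classify_junction(m, 68825358, 68836615, ctx)
  b <- classify_junction(m, 68825358, 68836615, shuffled)
  expect_equal(a$kind, b$kind)
})

test_that("known/novel marking matches the annotation fixture", {
  m <- cdh1_model()
  ann <- cdh1_known_junctions()
  ev <- classify_junction(m, 68849679, 68856499)
  ev <- mark_known(ev, ann)
  expect_true(ev$known)
  expect_equal(ev$labels, "ENST00000566612.1")

  # empty annotation -> novel
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chrom\tg_start\tg_end\tlabel", p)
  expect_false(mark_known(ev, load_annotation(p))$known)

  # the 6 intron-2 junctions against the 2-entry fixture: exactly 4 novel
  prof <- cdh1_event_profile(m)
  afe <- prof$events[grepl("AFE", prof$events$name), ]
  known <- is_known_junction(ann, afe$g_start, afe$g_end)
  expect_equal(sum(known), 2)
  expect_equal(sum(!known), 4)
})
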