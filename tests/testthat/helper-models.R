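# Shared fixtures and the independent brute-force classifier oracle.

# Three-exon toy model on the forward strand:
#   exon1 g.1001-1100 (c.1-100), exon2 g.1201-1300 (c.101-200),
#   exon3 g.1401-1500 (c.201-300)
toy_model <- function(strand = "+") {
  if (strand == "+") {
    ex <- data.frame(g_start = c(1001, 1201, 1401),
                     g_end = c(1100, 1300, 1500))
  } else {
    ex <- data.frame(g_start = c(1401, 1201, 1001),
                     g_end = c(1500, 1300, 1100))
  }
  transcript_model("TOY", "TOY-1", "chr1", strand, ex,
                   cds_start = 1, cds_end = 300)
}

# Random small model (2-6 exons) on a coarse grid, either strand.
random_toy_model <- function(n_exons = sample(2:6, 1),
                             strand = sample(c("+", "-"), 1)) {
  # exon lengths 6-30, intron lengths 8-40, grid start 1000
  len <- sample(seq(6, 30, by = 3), n_exons, replace = TRUE)
  gap <- sample(seq(8, 40, by = 4), max(n_exons - 1, 1), replace = TRUE)
  starts <- 1000 + cumsum(c(0, head(len, -1) + gap))
  ex <- data.frame(g_start = starts, g_end = starts + len - 1)
  if (strand == "-") ex <- ex[rev(seq_len(n_exons)), ]
  transcript_model("RND", "RND-1", "chrR", strand, ex,
                   cds_start = 1, cds_end = sum(len))
}

# Brute-force classifier written directly from the taxonomy definitions,
# independent of the production code path: enumerates every interpretation
# and picks the one whose defining conditions hold.
oracle_classify <- function(model, s, e, context = NULL,
                            max_shift = 2000L) {
  ex <- model$exons
  n <- nrow(ex)
  plus <- model$strand == "+"
  # canonical gaps, transcript order
  gaps <- lapply(seq_len(n - 1), function(i) {
    if (plus) c(ex$g_end[i] + 1, ex$g_start[i + 1] - 1)
    else c(ex$g_end[i + 1] + 1, ex$g_start[i] - 1)
  })
  for (i in seq_len(n - 1))
    if (s == gaps[[i]][1] && e == gaps[[i]][2]) return("canonical")
  # exon skip: donor boundary of intron i, acceptor boundary of intron j>i,
  # at least one whole exon in between
  don <- vapply(gaps, function(g) if (plus) g[1] else g[2], 0)
  acc <- vapply(gaps, function(g) if (plus) g[2] else g[1], 0)
  jd <- if (plus) s else e
  ja <- if (plus) e else s
  di <- match(jd, don); ai <- match(ja, acc)
  if (!is.na(di) && !is.na(ai) && ai > di) return("exon_skip")
  in_exon <- function(g) {
    h <- which(g >= ex$g_start & g <= ex$g_end)
    if (length(h)) h else NA_integer_
  }
  in_intron <- function(g) {
    for (i in seq_len(n - 1)) {
      lo <- min(gaps[[i]]); hi <- max(gaps[[i]])
      if (g >= lo && g <= hi) return(i)
    }
    NA_integer_
  }
  if (!is.na(di) && is.na(ai)) {
    hx <- in_exon(ja)
    if (!is.na(hx) && hx == di + 1) return("exonic_acceptor_shift")
    hi <- in_intron(ja)
    if (!is.na(hi) && hi == di) {
      m <- if (plus) acc[di] - ja else ja - acc[di]
      if (m <= max_shift) return("intronic_acceptor_shift")
    }
    return("unresolved")
  }
  if (is.na(di) && !is.na(ai)) {
    hx <- in_exon(jd)
    if (!is.na(hx) && hx == ai) return("exonic_donor_shift")
    hi <- in_intron(jd)
    if (!is.na(hi) && hi == ai) {
      k <- if (plus) jd - don[ai] else don[ai] - jd
      if (k <= max_shift) return("intronic_donor_shift")
      # deep donor: cryptic-exon partner from the preceding exon's end?
      partner <- FALSE
      if (!is.null(context) && nrow(context)) {
        for (r in seq_len(nrow(context))) {
          cd <- if (plus) context$g_start[r] else context$g_end[r]
          ca <- if (plus) context$g_end[r] else context$g_start[r]
          if (cd != don[ai] || ca == acc[ai]) next
          within <- if (plus) ca >= don[ai] && ca <= jd
                    else ca <= don[ai] && ca >= jd
          if (within) { partner <- TRUE; break }
        }
      }
      return(if (partner) "intronic_donor_shift" else "alt_first_exon")
    }
    return("unresolved")
  }
  "unresolved"
}

# Junction table for one synthetic sample with all canonical junctions at
# the given depth plus optional extra rows.
canonical_sample <- function(model, depth = 1000, overhang = 40) {
  cj <- canonical_junctions(model)
  data.frame(chrom = model$chrom, g_start = cj$g_start, g_end = cj$g_end,
             strand = model$strand, reads = depth,
             overhang_left = overhang, overhang_right = overhang)
}

add_junction <- function(junctions, g_start, g_end, reads, overhang = 40) {
  rbind(junctions,
        data.frame(chrom = junctions$chrom[1], g_start = g_start,
                   g_end = g_end, strand = junctions$strand[1],
                   reads = reads, overhang_left = overhang,
                   overhang_right = overhang))
}

# Random coding sequence with no in-frame stop codon (length in nt,
# multiple of 3).
make_stop_free_cds <- function(len) {
  stopifnot(len %% 3 == 0)
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste(sample(codons, len / 3, replace = TRUE), collapse = "")
}

# Cohort with identical canonical-only samples (null cohort helper).
null_cohort <- function(model, n = 5, depth = 1000) {
  ids <- sprintf("S%02d", seq_len(n))
  jl <- lapply(ids, function(id) {
    j <- canonical_sample(model, depth)
    j$sample_id <- id
    j
  })
  cohort_table(data.frame(sample_id = ids, puromycin = TRUE),
               do.call(rbind, jl))
}
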