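#' Build an event profile for simulation
#'
#' An event profile lists the alternative splicing events a simulated
#' cohort should carry: the junction span of each event, its true
#' expression ratio (percent of the physiological counterpart), its
#' recurrence across samples, and whether the event is sensitive to
#' nonsense-mediated decay (suppressed when the cohort is simulated
#' without puromycin).
#'
#' @param events Data frame with columns `name`, `g_start`, `g_end`,
#'   `true_ratio_pct`, `recurrence_pct`, `nmd_sensitive`, `known`.
#' @param depth Default canonical junction depth D (reads per canonical
#'   junction).
#' @param chrom Chromosome of all spans.
#' @return Object of class `event_profile`.
#' @export
event_profile <- function(events, depth, chrom) {
  stopifnot(is.data.frame(events),
            all(c("name", "g_start", "g_end", "true_ratio_pct",
                  "recurrence_pct", "nmd_sensitive", "known") %in%
                  names(events)))
  if (any(events$true_ratio_pct < 0)) stop("ratios must be >= 0")
  if (any(events$recurrence_pct < 0 | events$recurrence_pct > 100))
    stop("recurrences must lie in [0, 100]")
  structure(list(events = events, depth = depth, chrom = chrom),
            class = "event_profile")
}

#' Simulation configuration
#'
#' @param n_samples Number of cohort samples (default 20).
#' @param depth Canonical junction depth D; `NULL` uses the profile's
#'   default.
#' @param puromycin Logical: cohort treated with the NMD inhibitor? When
#'   `FALSE`, NMD-sensitive events are generated at `nmd_factor` times
#'   their true ratio.
#' @param nmd_factor NMD suppression factor in (0, 1], default 0.2.
#' @param seed Integer seed; the generated cohort is deterministic given
#'   the seed.
#' @param min_overhang,max_overhang Overhang sampling range (default
#'   30-70 bases, so well-supported junctions reach the high tier).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_samples = 20, depth = NULL, puromycin = TRUE,
                       nmd_factor = 0.2, seed = 1L, min_overhang = 30,
                       max_overhang = 70) {
  stopifnot(n_samples >= 1, nmd_factor > 0, nmd_factor <= 1,
            min_overhang <= max_overhang)
  structure(list(n_samples = as.integer(n_samples), depth = depth,
                 puromycin = isTRUE(puromycin), nmd_factor = nmd_factor,
                 seed = as.integer(seed),
                 min_overhang = as.integer(min_overhang),
                 max_overhang = as.integer(max_overhang)),
            class = "sim_config")
}

#' Generate a synthetic junction-count cohort
#'
#' Per sample, every canonical junction of the model receives a Poisson(D)
#' read count. Each profile event is present with probability
#' `recurrence_pct / 100`; a present event draws its alternative-junction
#' reads as Binomial(counterpart draw, ratio) for ratios at or below 100%,
#' or Poisson(ratio x D) above 100% (the alt-to-physiological ratio
#' definition admits ratios beyond 100%, which a binomial cannot produce).
#' The counterpart follows the quantification rule: mean of the two
#' flanking canonical draws for an exon skip, the host-intron canonical
#' draw otherwise. NMD-sensitive events are scaled by `nmd_factor` when
#' the sample is simulated without puromycin. Overhangs are drawn
#' uniformly from the configured range.
#'
#' The returned ground truth is for validation only and is never read by
#' the analysis pipeline.
#'
#' @param profile An [event_profile()].
#' @param cfg A [sim_config()].
#' @param model A [transcript_model()].
#' @return List with `cohort` (a [cohort_table()]) and `truth` (data frame
#'   `sample_id`, `name`, `present`, `expected_ratio_pct`, `alt_reads`,
#'   `counterpart_reads`).
#' @export
generate_cohort <- function(profile, cfg, model) {
  stopifnot(inherits(profile, "event_profile"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  D <- if (is.null(cfg$depth)) profile$depth else cfg$depth
  cj <- canonical_junctions(model)
  n_intron <- nrow(cj)
  pe <- profile$events
  # counterpart introns per event, via the classifier
  cp <- lapply(seq_len(nrow(pe)), function(i) {
    ev <- classify_junction(model, pe$g_start[i], pe$g_end[i],
                            context = NULL, opts = classify_opts(),
                            context_depth = NULL)
    if (ev$kind %in% c("canonical", "unresolved"))
      stop("profile event does not type against the model: ", pe$name[i])
    sf <- if (length(ev$skipped)) ev$skipped[1] else NA_integer_
    st <- if (length(ev$skipped)) ev$skipped[length(ev$skipped)]
          else NA_integer_
    counterpart_introns(ev$kind, ev$host_intron, sf, st, "mean")
  })
  undetectable <- pe$name[pe$true_ratio_pct / 100 * D < 1]
  if (length(undetectable))
    warning("depth too low to detect event(s): ",
            paste(undetectable, collapse = ", "))

  samples <- data.frame(
    sample_id = sprintf("LCL%02d", seq_len(cfg$n_samples)),
    puromycin = cfg$puromycin,
    provenance = "synthetic junction counts")
  draw_oh <- function(n) sample(cfg$min_overhang:cfg$max_overhang, n,
                                replace = TRUE)
  jl <- vector("list", cfg$n_samples)
  tl <- vector("list", cfg$n_samples)
  for (s in seq_len(cfg$n_samples)) {
    canon_reads <- rpois(n_intron, D)
    present <- rbinom(nrow(pe), 1L, pe$recurrence_pct / 100) == 1L
    nmd_mult <- ifelse(!cfg$puromycin & pe$nmd_sensitive, cfg$nmd_factor, 1)
    p <- pe$true_ratio_pct / 100 * nmd_mult
    counterpart <- vapply(cp, function(ix) mean(canon_reads[ix]), 0)
    alt <- integer(nrow(pe))
    for (i in seq_len(nrow(pe))) {
      if (!present[i]) next
      alt[i] <- if (p[i] <= 1)
        rbinom(1L, round(counterpart[i]), p[i])
      else
        rpois(1L, p[i] * D)
    }
    keep <- present & alt > 0
    j <- data.frame(
      chrom = profile$chrom,
      g_start = c(cj$g_start, pe$g_start[keep]),
      g_end = c(cj$g_end, pe$g_end[keep]),
      strand = model$strand,
      reads = c(canon_reads, alt[keep]))
    j$overhang_left <- draw_oh(nrow(j))
    j$overhang_right <- draw_oh(nrow(j))
    j$sample_id <- samples$sample_id[s]
    jl[[s]] <- j
    tl[[s]] <- data.frame(
      sample_id = samples$sample_id[s], name = pe$name,
      present = present, expected_ratio_pct = pe$true_ratio_pct * nmd_mult,
      alt_reads = alt, counterpart_reads = counterpart)
  }
  list(cohort = cohort_table(samples, do.call(rbind, jl)),
       truth = do.call(rbind, tl))
}

#' Spike aberrant junctions into a sample (variant carrier emulation)
#'
#' Adds aberrant junctions at target ratios of their physiological
#' counterpart and optionally depletes the counterpart itself (allelic
#' imbalance). The counterpart is resolved with the same rule as the
#' quantification: the canonical junction(s) replaced or shared by the
#' aberrant event.
#'
#' @param sample_junctions Junction records of one sample.
#' @param model A [transcript_model()].
#' @param spikes Data frame with columns `g_start`, `g_end`,
#'   `target_ratio_pct`.
#' @param imbalance_factor Factor in (0, 1] applied to the physiological
#'   counterpart junction reads before the aberrant reads are computed
#'   (default 1 = no imbalance).
#' @return The modified junction data frame.
#' @export
spike_variant_carrier <- function(sample_junctions, model, spikes,
                                  imbalance_factor = 1) {
  stopifnot(is.data.frame(spikes),
            all(c("g_start", "g_end", "target_ratio_pct") %in% names(spikes)))
  j <- sample_junctions
  key <- paste(j$g_start, j$g_end)
  if (any(paste(spikes$g_start, spikes$g_end) %in% key))
    stop("spike conflicts with an existing junction span")
  cj <- canonical_junctions(model)
  counterpart_hits <- lapply(seq_len(nrow(spikes)), function(i) {
    ev <- classify_junction(model, spikes$g_start[i], spikes$g_end[i],
                            context = j[, c("g_start", "g_end")],
                            context_depth = sum(j$reads))
    if (ev$kind %in% c("canonical", "unresolved"))
      stop("spike does not type as an alternative event")
    sf <- if (length(ev$skipped)) ev$skipped[1] else NA_integer_
    st <- if (length(ev$skipped)) ev$skipped[length(ev$skipped)]
          else NA_integer_
    introns <- counterpart_introns(ev$kind, ev$host_intron, sf, st, "mean")
    r <- cj[cj$intron_index %in% introns, ]
    match(paste(r$g_start, r$g_end), paste(j$g_start, j$g_end))
  })
  if (imbalance_factor < 1) {
    # deplete each affected physiological counterpart exactly once
    hits <- unique(stats::na.omit(unlist(counterpart_hits)))
    j$reads[hits] <- as.integer(round(j$reads[hits] * imbalance_factor))
  }
  for (i in seq_len(nrow(spikes))) {
    hit <- counterpart_hits[[i]]
    D <- mean(ifelse(is.na(hit), 0, j$reads[hit]))
    add <- data.frame(
      chrom = j$chrom[1], g_start = spikes$g_start[i],
      g_end = spikes$g_end[i], strand = j$strand[1],
      reads = as.integer(round(spikes$target_ratio_pct[i] / 100 * D)),
      overhang_left = max(j$overhang_left),
      overhang_right = max(j$overhang_right))
    if ("sample_id" %in% names(j)) add$sample_id <- j$sample_id[1]
    add <- add[, names(j)]
    j <- rbind(j, add)
  }
  j
}
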