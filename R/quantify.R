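#' Reporting filter configuration
#'
#' An event is reported in a sample iff its junction has at least
#' `min_reads` reads and an expression ratio above `min_ratio_pct` percent
#' of the physiological counterpart. Defaults follow the diagnostic cutoff
#' of 100 reads and 0.1%.
#'
#' @param min_reads Minimum junction read count (default 100).
#' @param min_ratio_pct Minimum expression ratio in percent (default 0.1).
#' @param strict_ratio If `TRUE` (default) the ratio comparison is strict
#'   (`>`), matching the wording "higher than 0.1%"; `FALSE` uses `>=`.
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_reads = 100, min_ratio_pct = 0.1,
                          strict_ratio = TRUE) {
  stopifnot(min_reads >= 0, min_ratio_pct >= 0)
  structure(list(min_reads = min_reads, min_ratio_pct = min_ratio_pct,
                 strict_ratio = isTRUE(strict_ratio)),
            class = "filter_config")
}

#' Confidence tier configuration
#'
#' Confidence describes the junction evidence, independently of the
#' reporting filters: `high` requires at least `min_overhang` aligned bases
#' on both sides of the junction and more than `high_depth` reads;
#' `moderate` requires the overhang condition and between
#' `moderate_depth_low` and `high_depth` reads; everything else is `low`
#' (the low tier is an explicit catch-all -- low-evidence events are never
#' silently dropped).
#'
#' @param min_overhang Minimum overhang on both sides (default 30 bases).
#' @param high_depth Depth above which confidence is high (default 50).
#' @param moderate_depth_low Lower depth bound of the moderate tier
#'   (default 30).
#' @return List of class `confidence_config`.
#' @export
confidence_config <- function(min_overhang = 30, high_depth = 50,
                              moderate_depth_low = 30) {
  stopifnot(moderate_depth_low <= high_depth, min_overhang >= 0)
  structure(list(min_overhang = min_overhang, high_depth = high_depth,
                 moderate_depth_low = moderate_depth_low),
            class = "confidence_config")
}

#' Confidence tier of junction evidence
#'
#' @param reads Read counts (vector).
#' @param overhang_left,overhang_right Maximal overhangs (vectors).
#' @param cfg A [confidence_config()].
#' @return Character vector in `{"high", "moderate", "low"}`.
#' @export
confidence_tier <- function(reads, overhang_left, overhang_right,
                            cfg = confidence_config()) {
  oh_ok <- pmin(overhang_left, overhang_right) >= cfg$min_overhang
  ifelse(oh_ok & reads > cfg$high_depth, "high",
         ifelse(oh_ok & reads >= cfg$moderate_depth_low &
                  reads <= cfg$high_depth, "moderate", "low"))
}

# Canonical counterpart intron indices for one typed event row.
counterpart_introns <- function(kind, host_intron, skipped_from, skipped_to,
                                denominator = "mean") {
  if (is.na(kind) || kind %in% c("canonical", "unresolved"))
    return(integer())
  if (kind == "exon_skip") {
    fl <- c(skipped_from - 1L, skipped_to)
    if (denominator == "upstream") fl <- fl[1]
    return(fl)
  }
  host_intron
}

#' Expression ratio of an event relative to its physiological counterpart
#'
#' The ratio is alt-to-physiological (not alt-to-total), so it may exceed
#' 100%: `ratio_pct = 100 * reads(alt) / D`, where `D` is the mean read
#' count of the canonical counterpart junction(s) in the same sample. For
#' an exon skip the counterpart is the two canonical junctions replaced by
#' the skip (their mean by default, or the upstream one alone); for a
#' splice-site shift it is the canonical junction of the host intron
#' (sharing the unshifted site); for an alternative first exon it is the
#' canonical junction using the same acceptor. A zero or unresolvable
#' counterpart yields `NA` with a reason, never an infinite ratio.
#'
#' @param event One typed event row (a one-row data frame from
#'   [annotate_sample()], or a `splicing_event`).
#' @param sample_junctions All junction records of the same sample.
#' @param model A [transcript_model()].
#' @param denominator `"mean"` (default) or `"upstream"` (exon skips only).
#' @return List with `ratio_pct`, `counterpart_reads`, `reason`
#'   (`NA` unless the ratio is undefined).
#' @export
expression_ratio <- function(event, sample_junctions, model,
                             denominator = c("mean", "upstream")) {
  denominator <- match.arg(denominator)
  if (inherits(event, "splicing_event")) {
    kind <- event$kind; hi <- event$host_intron
    sf <- if (length(event$skipped)) event$skipped[1] else NA_integer_
    st <- if (length(event$skipped)) event$skipped[length(event$skipped)]
          else NA_integer_
    reads <- event$reads
  } else {
    kind <- event$kind; hi <- event$host_intron
    sf <- event$skipped_from; st <- event$skipped_to
    reads <- event$reads
  }
  introns <- counterpart_introns(kind, hi, sf, st, denominator)
  if (!length(introns) || any(introns < 1))
    return(list(ratio_pct = NA_real_, counterpart_reads = NA_real_,
                reason = "unresolvable counterpart"))
  cj <- canonical_junctions(model)
  cj <- cj[cj$intron_index %in% introns, ]
  key <- paste(sample_junctions$g_start, sample_junctions$g_end)
  hit <- match(paste(cj$g_start, cj$g_end), key)
  creads <- ifelse(is.na(hit), 0, sample_junctions$reads[hit])
  D <- mean(creads)
  if (!is.finite(D) || D == 0)
    return(list(ratio_pct = NA_real_, counterpart_reads = D,
                reason = "zero counterpart depth"))
  list(ratio_pct = 100 * reads / D, counterpart_reads = D, reason = NA_character_)
}

#' Quantify, filter and tier a cohort's typed events
#'
#' Adds to each non-canonical typed junction its expression ratio,
#' counterpart depth, reporting-filter status (with failure reason) and
#' confidence tier. Filters and confidence are two independent annotations:
#' filters gate event *reporting*, confidence describes junction
#' *evidence*.
#'
#' @param events Typed cohort events from [annotate_cohort()].
#' @param filter_cfg A [filter_config()].
#' @param conf_cfg A [confidence_config()].
#' @param model A [transcript_model()].
#' @param denominator Passed to [expression_ratio()].
#' @return The events data frame with added columns `ratio_pct`,
#'   `counterpart_reads`, `pass`, `fail_reason`, `confidence`.
#' @export
quantify_cohort <- function(events, model, filter_cfg = filter_config(),
                            conf_cfg = confidence_config(),
                            denominator = "mean") {
  stopifnot(is.data.frame(events))
  events$ratio_pct <- NA_real_
  events$counterpart_reads <- NA_real_
  events$pass <- FALSE
  events$fail_reason <- NA_character_
  for (sid in unique(events$sample_id)) {
    idx <- which(events$sample_id == sid)
    sj <- events[idx, c("g_start", "g_end", "reads")]
    for (i in idx) {
      if (events$kind[i] %in% c("canonical", "unresolved")) next
      r <- expression_ratio(events[i, ], sj, model, denominator)
      events$ratio_pct[i] <- r$ratio_pct
      events$counterpart_reads[i] <- r$counterpart_reads
      if (!is.na(r$reason)) events$fail_reason[i] <- r$reason
    }
  }
  alt <- !events$kind %in% c("canonical", "unresolved")
  ratio_ok <- if (filter_cfg$strict_ratio)
    events$ratio_pct > filter_cfg$min_ratio_pct
  else events$ratio_pct >= filter_cfg$min_ratio_pct
  reads_ok <- events$reads >= filter_cfg$min_reads
  events$pass <- alt & !is.na(events$ratio_pct) & ratio_ok & reads_ok
  need_reason <- alt & !events$pass & is.na(events$fail_reason)
  events$fail_reason[need_reason] <-
    ifelse(!reads_ok[need_reason] & !(ratio_ok[need_reason] %in% TRUE),
           "min_reads,min_ratio",
           ifelse(!reads_ok[need_reason], "min_reads", "min_ratio"))
  events$confidence <- confidence_tier(events$reads, events$overhang_left,
                                       events$overhang_right, conf_cfg)
  events
}

#' Cohort recurrence of an event
#'
#' @param n_pass Number of samples in which the event passes the reporting
#'   filters.
#' @param n_samples Cohort size (must be > 0).
#' @return Recurrence in percent.
#' @export
recurrence <- function(n_pass, n_samples) {
  if (any(n_samples <= 0)) stop("empty cohort: recurrence undefined")
  100 * n_pass / n_samples
}

#' Summarise a quantified cohort into an event profile
#'
#' One row per distinct event span: shorthand, kind, known/novel status,
#' recurrence (percent of cohort samples in which the event passes the
#' reporting filters), mean expression ratio over filter-passing samples
#' (`NA` when it passes nowhere), mean ratio over all samples where the
#' junction was observed, and the best confidence tier reached.
#'
#' @param quant Quantified events from [quantify_cohort()].
#' @param n_samples Cohort size used for recurrence (defaults to the number
#'   of distinct samples in `quant`).
#' @param reported_only Keep only events passing filters in at least one
#'   sample (default `TRUE`).
#' @return Data frame of class `cohort_profile`, ordered by genomic span.
#' @export
cohort_profile <- function(quant, n_samples = length(unique(quant$sample_id)),
                           reported_only = TRUE) {
  if (n_samples <= 0) stop("empty cohort")
  alt <- quant[!quant$kind %in% c("canonical", "unresolved"), ]
  if (nrow(alt) == 0) {
    out <- data.frame(event_key = character(), shorthand = character(),
                      kind = character(), r_description = character(),
                      known = logical(), labels = character(),
                      n_pass = integer(), recurrence_pct = numeric(),
                      mean_ratio_pct = numeric(),
                      mean_ratio_observed_pct = numeric(),
                      best_confidence = character(), reported = logical())
    class(out) <- c("cohort_profile", class(out))
    return(out)
  }
  tier_rank <- c(high = 3, moderate = 2, low = 1)
  agg <- lapply(split(alt, alt$event_key), function(d) {
    data.frame(
      event_key = d$event_key[1], shorthand = d$shorthand[1],
      kind = d$kind[1], r_description = d$r_description[1],
      known = d$known[1], labels = d$labels[1],
      g_start = d$g_start[1], g_end = d$g_end[1],
      n_pass = sum(d$pass),
      recurrence_pct = recurrence(sum(d$pass), n_samples),
      mean_ratio_pct = if (any(d$pass)) mean(d$ratio_pct[d$pass]) else NA_real_,
      mean_ratio_observed_pct = mean(d$ratio_pct[!is.na(d$ratio_pct)]),
      best_confidence = d$confidence[which.max(tier_rank[d$confidence])],
      reported = any(d$pass))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$g_start, out$g_end), ]
  rownames(out) <- NULL
  if (reported_only) out <- out[out$reported, ]
  class(out) <- c("cohort_profile", class(out))
  out
}

#' Write a cohort profile with an audit header
#'
#' @param profile A `cohort_profile`.
#' @param path Output TSV path.
#' @param header Named character vector written as `# key: value` lines.
#' @return Invisibly, `path`.
#' @export
write_cohort_profile <- function(profile, path, header = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(header), header), con)
  write.table(profile, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
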