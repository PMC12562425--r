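#' Variant assessment configuration
#'
#' @param dominance_pct Expression ratio (percent of the physiological
#'   counterpart) a truncating carrier-specific event must reach before the
#'   evidence is called pathogenic-supporting. Default 50: physiological
#'   alternative events top out around 40% of the counterpart, while
#'   pathogenic transcripts in carriers reach well above 100%.
#' @param imbalance_frac Allelic-imbalance threshold: the physiological
#'   counterpart junction is flagged as depleted when its read count is at
#'   most this fraction of the carrier's own flanking canonical junction
#'   depth. Default 0.25.
#' @param max_control_prevalence_pct An event is carrier-specific when it
#'   passes the reporting filters in at most this percentage of controls.
#'   Default 10.
#' @param window_exons Number of exons on each side of the variant's host
#'   exon/intron searched for aberrant events. Default 1.
#' @param filter A [filter_config()].
#' @param confidence A [confidence_config()].
#' @param classify A [classify_opts()].
#' @return List of class `assessment_config`.
#' @export
assessment_config <- function(dominance_pct = 50, imbalance_frac = 0.25,
                              max_control_prevalence_pct = 10,
                              window_exons = 1,
                              filter = filter_config(),
                              confidence = confidence_config(),
                              classify = classify_opts()) {
  structure(list(dominance_pct = dominance_pct,
                 imbalance_frac = imbalance_frac,
                 max_control_prevalence_pct = max_control_prevalence_pct,
                 window_exons = as.integer(window_exons),
                 filter = filter, confidence = confidence,
                 classify = classify),
            class = "assessment_config")
}

# Host exon/intron of a cDNA locus; returns list(kind, index, exon_range)
# where exon_range is the exon-index window used for event linkage.
locus_host <- function(model, locus, window_exons = 1L) {
  ex <- model$exons
  i <- which(locus$base >= ex$c_start & locus$base <= ex$c_end)
  if (length(i) != 1) stop("locus outside the transcript model")
  if (locus$offset > 0) {
    # after the donor of exon i -> intron i
    if (locus$base != ex$c_end[i] || i == nrow(ex))
      stop("donor-offset locus must anchor on an exon's last base")
    host <- list(kind = "intron", index = i, exons = c(i, i + 1L))
  } else if (locus$offset < 0) {
    if (locus$base != ex$c_start[i] || i == 1L)
      stop("acceptor-offset locus must anchor on an exon's first base")
    host <- list(kind = "intron", index = i - 1L, exons = c(i - 1L, i))
  } else {
    host <- list(kind = "exon", index = i, exons = c(i, i))
  }
  lo <- max(1L, host$exons[1] - window_exons)
  hi <- min(nrow(ex), host$exons[2] + window_exons)
  host$exon_range <- c(lo, hi)
  host$g_range <- range(ex$g_start[lo:hi], ex$g_end[lo:hi])
  host
}

#' Assess a candidate splice variant against a control cohort
#'
#' Compares the carrier's junction profile to the controls within a window
#' around the variant locus. Aberrant events are filter-passing,
#' non-canonical events in the carrier that are absent (or below the
#' reporting filters) in virtually all controls. Evidence is
#' `splicing_altering_pathogenic_supporting` when at least one aberrant,
#' carrier-specific, truncating event reaches the dominance threshold;
#' `no_splicing_effect_detected` when no aberrant event survives; otherwise
#' `inconclusive`. Allelic imbalance is flagged when the physiological
#' counterpart junction of the host intron is depleted relative to the
#' carrier's own flanking canonical junction depth (the flag reports the
#' observation only -- it cannot distinguish its mechanism).
#'
#' In-silico scores (e.g. SPiP / SpliceAI strings) supplied via `scores`
#' are stored verbatim in the report, never computed or interpreted.
#'
#' @param carrier_id Sample id of the carrier within `cohort`.
#' @param cohort A [cohort_table()] containing the carrier and the
#'   controls.
#' @param locus Variant position as a c. string (e.g. `"c.1008+1"`) or
#'   [cdna_coord()].
#' @param model A [transcript_model()].
#' @param annotation Optional known-junction annotation.
#' @param cfg An [assessment_config()].
#' @param variant_label Label for the report (defaults to the locus
#'   string).
#' @param scores Optional named character vector of pass-through in-silico
#'   predictions.
#' @return Object of class `variant_assessment`.
#' @export
assess_variant <- function(carrier_id, cohort, locus, model,
                           annotation = NULL, cfg = assessment_config(),
                           variant_label = NULL, scores = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!carrier_id %in% cohort$samples$sample_id)
    stop("carrier sample not found in the cohort: ", carrier_id)
  if (is.character(locus)) locus <- parse_cdna(locus)
  if (is.null(variant_label)) variant_label <- format_cdna(locus)
  host <- locus_host(model, locus, cfg$window_exons)

  events <- annotate_cohort(cohort, model, annotation, cfg$classify)
  quant <- quantify_cohort(events, model, cfg$filter, cfg$confidence)
  quant <- append_consequences(quant, model)

  controls <- setdiff(cohort$samples$sample_id, carrier_id)
  if (length(controls) == 0) stop("no control samples in the cohort")
  in_window <- !quant$kind %in% c("canonical", "unresolved") &
    quant$g_start <= host$g_range[2] & quant$g_end >= host$g_range[1]

  carrier_ev <- quant[in_window & quant$sample_id == carrier_id &
                        quant$pass, , drop = FALSE]
  # control prevalence per event span (filter-passing controls)
  prev <- function(keys) {
    vapply(keys, function(k) {
      100 * sum(quant$event_key == k & quant$sample_id %in% controls &
                  quant$pass) / length(controls)
    }, 0)
  }
  if (nrow(carrier_ev)) {
    carrier_ev$control_prevalence_pct <- prev(carrier_ev$event_key)
    aberrant <- carrier_ev[carrier_ev$control_prevalence_pct <=
                             cfg$max_control_prevalence_pct, , drop = FALSE]
  } else {
    carrier_ev$control_prevalence_pct <- numeric(0)
    aberrant <- carrier_ev
  }

  truncating <- nrow(aberrant) > 0 &
    (aberrant$frame == "frameshift" | !is.na(aberrant$ptc))
  dominant <- nrow(aberrant) > 0 & aberrant$ratio_pct >= cfg$dominance_pct
  evidence <- if (nrow(aberrant) == 0) {
    "no_splicing_effect_detected"
  } else if (any(truncating & dominant)) {
    "splicing_altering_pathogenic_supporting"
  } else {
    "inconclusive"
  }

  # physiological counterpart and allelic imbalance on the host intron
  cj <- canonical_junctions(model)
  carrier_j <- cohort$junctions[cohort$junctions$sample_id == carrier_id, ]
  jreads <- function(intron) {
    r <- cj[cj$intron_index == intron, ]
    if (nrow(r) == 0) return(NA_real_)
    hit <- carrier_j$g_start == r$g_start & carrier_j$g_end == r$g_end
    if (any(hit)) sum(carrier_j$reads[hit]) else 0
  }
  host_intron <- if (host$kind == "intron") host$index
                 else max(1L, host$index - 1L)
  phys <- jreads(host_intron)
  flank <- c(jreads(host_intron - 1L), jreads(host_intron + 1L))
  flank <- flank[!is.na(flank)]
  imbalance <- length(flank) > 0 && !is.na(phys) &&
    phys <= cfg$imbalance_frac * mean(flank)

  aberrant_fraction <- if (nrow(aberrant) > 0 && !is.na(phys) &&
                             (sum(aberrant$reads) + phys) > 0)
    100 * sum(aberrant$reads) / (sum(aberrant$reads) + phys)
  else NA_real_

  structure(list(
    variant = variant_label, carrier_id = carrier_id,
    locus = format_cdna(locus), host = host[c("kind", "index")],
    n_controls = length(controls),
    aberrant_events = aberrant[, intersect(
      c("event_key", "shorthand", "kind", "r_description", "reads",
        "ratio_pct", "control_prevalence_pct", "frame", "nmd_candidate",
        "confidence"), names(aberrant)), drop = FALSE],
    physiological_reads = phys,
    aberrant_fraction_pct = aberrant_fraction,
    allelic_imbalance = imbalance,
    evidence = evidence,
    scores = scores,
    config = cfg), class = "variant_assessment")
}

#' @export
print.variant_assessment <- function(x, ...) {
  cat(sprintf("<variant_assessment> %s (carrier %s, %d controls)\n",
              x$variant, x$carrier_id, x$n_controls))
  cat(sprintf("  evidence: %s\n", x$evidence))
  cat(sprintf("  allelic imbalance: %s (physiological counterpart %s reads)\n",
              x$allelic_imbalance, format(x$physiological_reads)))
  if (nrow(x$aberrant_events)) {
    cat(sprintf("  aberrant events (%d):\n", nrow(x$aberrant_events)))
    for (i in seq_len(nrow(x$aberrant_events))) {
      e <- x$aberrant_events[i, ]
      cat(sprintf("    %-12s %-30s %6d reads  %6.1f%%  %s\n",
                  e$shorthand, ifelse(is.na(e$r_description), "",
                                      e$r_description),
                  e$reads, e$ratio_pct, e$frame))
    }
  }
  invisible(x)
}

#' Write a variant assessment as JSON (plus optional plain text)
#'
#' @param assessment A `variant_assessment`.
#' @param path JSON output path.
#' @param text_path Optional human-readable text report path.
#' @return Invisibly, `path`.
#' @export
write_assessment <- function(assessment, path, text_path = NULL) {
  x <- unclass(assessment)
  if (!is.null(x$scores)) x$scores <- as.list(x$scores)
  x$config <- lapply(x$config[c("dominance_pct", "imbalance_frac",
                                "max_control_prevalence_pct",
                                "window_exons")], identity)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows", na = "null")
  if (!is.null(text_path)) {
    con <- file(text_path, "w", encoding = "UTF-8")
    sink(con); print(assessment); sink()
    close(con)
  }
  invisible(path)
}

#' Read a variant table
#'
#' TSV with columns `variant`, `c_position` and optional pass-through score
#' columns (e.g. `spip`, `spliceai`).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_variant_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("variant", "c_position") %in% names(tab)))
  tab
}
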