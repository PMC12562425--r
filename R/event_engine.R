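# Map a junction gap (g_start, g_end = first/last intronic base, genomic
# orientation) to donor/acceptor genomic positions in transcript orientation.
junction_donor_acceptor <- function(model, g_start, g_end) {
  if (model$strand == "+") list(donor = g_start, acceptor = g_end)
  else list(donor = g_end, acceptor = g_start)
}

#' Classification options for the event engine
#'
#' @param max_shift_offset Maximum donor/acceptor offset (bases into the
#'   intron) still interpreted as a splice-site shift, i.e. partial intron
#'   retention. The offset equals the length of the implied retained
#'   segment, so the cap is a plausibility bound on intron retention:
#'   reported partial retentions run up to roughly 1.3 kb, while donors
#'   tens of kilobases into an intron imply an implausibly large retained
#'   segment and are instead candidates for alternative first exons.
#'   Default 2000 bases.
#' @param afe_min_depth Minimum total junction read depth a sample must have
#'   before the absence of a partner junction is accepted as evidence for an
#'   alternative first exon; below it, deep intronic donors stay
#'   `unresolved`. Default 1000 reads.
#' @return List of class `classify_opts`.
#' @export
classify_opts <- function(max_shift_offset = 2000L, afe_min_depth = 1000L) {
  stopifnot(max_shift_offset >= 0, afe_min_depth >= 0)
  structure(list(max_shift_offset = as.integer(max_shift_offset),
                 afe_min_depth = as.integer(afe_min_depth)),
            class = "classify_opts")
}

new_event <- function(model, g_start, g_end, kind, host_exon = NA_integer_,
                      host_intron = NA_integer_, skipped = integer(),
                      offset = NA_integer_, reason = NA_character_) {
  ev <- structure(list(chrom = model$chrom, g_start = as.integer(g_start),
                       g_end = as.integer(g_end), strand = model$strand,
                       kind = kind, host_exon = host_exon,
                       host_intron = host_intron, skipped = skipped,
                       offset = offset, known = FALSE, labels = character(),
                       reason = reason, shorthand = NA_character_,
                       r_description = NA_character_),
                  class = "splicing_event")
  if (!kind %in% c("canonical", "unresolved")) {
    d <- format_event(model, ev)
    ev$shorthand <- d$shorthand
    ev$r_description <- d$r_description
  } else if (kind == "canonical") {
    ev$shorthand <- "canonical"
  }
  ev
}

#' Type one observed junction against the transcript model
#'
#' Deterministically assigns an observed splice gap to the event taxonomy:
#' `canonical`, `exon_skip`, `exonic_donor_shift` (\eqn{\Delta}xq),
#' `exonic_acceptor_shift` (\eqn{\Delta}xp), `intronic_donor_shift`
#' (\eqn{\blacktriangledown}xp), `intronic_acceptor_shift`
#' (\eqn{\blacktriangledown}xq), `alt_first_exon` or `unresolved`.
#' Endpoint matching is exact (no fuzz window): junction callers emit exact
#' boundaries.
#'
#' A junction whose acceptor is a canonical exon start but whose donor lies
#' deep inside the upstream intron (beyond `max_shift_offset`) is typed as
#' an alternative first exon only if no non-canonical partner junction in
#' `context` links the preceding exon's end to a point inside the intron at
#' or upstream of the donor (such a partner would instead indicate a cryptic
#' internal exon / partial retention structure) and the sample's total
#' junction depth reaches `afe_min_depth`.
#'
#' @param model A [transcript_model()].
#' @param g_start,g_end First and last intronic base of the spliced-out gap
#'   (1-based inclusive, genomic orientation).
#' @param context Data frame of all junction spans observed in the same
#'   sample (columns `g_start`, `g_end`); membership is order-free.
#' @param opts A [classify_opts()].
#' @param context_depth Total junction read depth of the sample (used only
#'   for the alternative-first-exon depth gate; `NULL` skips the gate).
#' @return A `splicing_event` (list) with the typed kind, host exon/intron
#'   indices, skipped exon set, donor/acceptor offset, shorthand and
#'   r. description.
#' @export
classify_junction <- function(model, g_start, g_end, context = NULL,
                              opts = classify_opts(), context_depth = NULL) {
  g_start <- as.integer(g_start); g_end <- as.integer(g_end)
  if (g_end < g_start) stop("zero- or negative-length gap: g_end < g_start")
  span <- model_span(model)
  if (g_end < span[1] || g_start > span[2])
    return(new_event(model, g_start, g_end, "unresolved",
                     reason = "outside transcript span"))
  cj <- canonical_junctions(model)
  if (nrow(cj) == 0)
    return(new_event(model, g_start, g_end, "unresolved",
                     reason = "single-exon model"))
  # donor/acceptor genomic positions per intron, transcript orientation
  if (model$strand == "+") {
    don <- cj$g_start; acc <- cj$g_end
  } else {
    don <- cj$g_end; acc <- cj$g_start
  }
  ja <- junction_donor_acceptor(model, g_start, g_end)
  di <- which(don == ja$donor)
  ai <- which(acc == ja$acceptor)
  has_d <- length(di) == 1; has_a <- length(ai) == 1

  if (has_d && has_a) {
    if (di == ai)
      return(new_event(model, g_start, g_end, "canonical",
                       host_intron = di))
    if (ai > di)
      return(new_event(model, g_start, g_end, "exon_skip",
                       skipped = seq.int(di + 1L, ai),
                       host_intron = di))
    return(new_event(model, g_start, g_end, "unresolved",
                     reason = "acceptor upstream of donor"))
  }

  loc_or_null <- function(g) tryCatch(locate_genomic(model, g),
                                      error = function(e) NULL)

  if (has_d) {
    # canonical donor of intron di, non-canonical acceptor
    loc <- loc_or_null(ja$acceptor)
    if (is.null(loc))
      return(new_event(model, g_start, g_end, "unresolved",
                       reason = "acceptor outside transcript span"))
    if (loc$type == "exon" && loc$index == di + 1L) {
      return(new_event(model, g_start, g_end, "exonic_acceptor_shift",
                       host_exon = di + 1L, host_intron = di))
    }
    if (loc$type == "intron" && loc$index == di) {
      # acceptor shifted upstream into intron di: terminal intron retention
      m <- if (model$strand == "+") acc[di] - ja$acceptor
           else ja$acceptor - acc[di]
      if (m <= opts$max_shift_offset)
        return(new_event(model, g_start, g_end, "intronic_acceptor_shift",
                         host_intron = di, offset = as.integer(m)))
      return(new_event(model, g_start, g_end, "unresolved",
                       reason = "deep intronic acceptor"))
    }
    return(new_event(model, g_start, g_end, "unresolved",
                     reason = "acceptor beyond the adjacent exon"))
  }

  if (has_a) {
    # canonical acceptor of intron ai, non-canonical donor
    loc <- loc_or_null(ja$donor)
    if (is.null(loc))
      return(new_event(model, g_start, g_end, "unresolved",
                       reason = "donor outside transcript span"))
    if (loc$type == "exon" && loc$index == ai) {
      return(new_event(model, g_start, g_end, "exonic_donor_shift",
                       host_exon = ai, host_intron = ai))
    }
    if (loc$type == "intron" && loc$index == ai) {
      k <- if (model$strand == "+") ja$donor - don[ai]
           else don[ai] - ja$donor
      if (k <= opts$max_shift_offset)
        return(new_event(model, g_start, g_end, "intronic_donor_shift",
                         host_intron = ai, offset = as.integer(k)))
      # deep intronic donor: alternative first exon unless a non-canonical
      # partner junction from the preceding exon's end reaches into the
      # intron at/upstream of this donor
      if (!is.null(context_depth) && context_depth < opts$afe_min_depth)
        return(new_event(model, g_start, g_end, "unresolved",
                         reason = "insufficient depth for first-exon inference"))
      partner <- FALSE
      if (!is.null(context) && nrow(context) > 0) {
        pda <- if (model$strand == "+")
          list(d = context$g_start, a = context$g_end)
        else
          list(d = context$g_end, a = context$g_start)
        canon_acc <- acc[ai]
        if (model$strand == "+") {
          partner <- any(pda$d == don[ai] & pda$a != canon_acc &
                           pda$a <= ja$donor & pda$a >= don[ai])
        } else {
          partner <- any(pda$d == don[ai] & pda$a != canon_acc &
                           pda$a >= ja$donor & pda$a <= don[ai])
        }
      }
      if (partner)
        return(new_event(model, g_start, g_end, "intronic_donor_shift",
                         host_intron = ai, offset = as.integer(k)))
      return(new_event(model, g_start, g_end, "alt_first_exon",
                       host_intron = ai, offset = as.integer(k)))
    }
    return(new_event(model, g_start, g_end, "unresolved",
                     reason = "donor outside the adjacent intron/exon"))
  }

  new_event(model, g_start, g_end, "unresolved",
            reason = "no canonical endpoint")
}

#' Mark an event as known or novel against an annotation
#'
#' @param event A `splicing_event` (or data frame of events from
#'   [annotate_sample()], in which case marking is vectorised).
#' @param ann A `known_junction_annotation` from [load_annotation()].
#' @return The event(s) with `known` and `labels` filled in; events whose
#'   span is absent from the annotation are novel (`known = FALSE`).
#' @export
mark_known <- function(event, ann) {
  stopifnot(inherits(ann, "known_junction_annotation"))
  key <- function(s, e) paste(s, e, sep = ":")
  if (is.data.frame(event)) {
    k <- key(event$g_start, event$g_end)
    hit <- match(k, key(ann$spans$g_start, ann$spans$g_end))
    event$known <- !is.na(hit)
    event$labels <- ifelse(is.na(hit), "", ann$spans$labels[hit])
    return(event)
  }
  stopifnot(inherits(event, "splicing_event"))
  hit <- which(ann$spans$g_start == event$g_start &
                 ann$spans$g_end == event$g_end)
  if (length(hit)) {
    event$known <- TRUE
    event$labels <- strsplit(ann$spans$labels[hit[1]], ",")[[1]]
  } else {
    event$known <- FALSE
    event$labels <- character()
  }
  event
}

event_key <- function(chrom, g_start, g_end) {
  paste(chrom, g_start, g_end, sep = ":")
}

#' Type every junction of one sample
#'
#' Classifies each junction record against the model using the sample's own
#' junction set as cohort context, and marks events known/novel against the
#' annotation.
#'
#' @param junctions Data frame of junction records for one sample (columns
#'   `chrom`, `g_start`, `g_end`, `reads`, `overhang_left`,
#'   `overhang_right`, optionally `strand`).
#' @param model A [transcript_model()].
#' @param annotation Optional `known_junction_annotation`.
#' @param opts A [classify_opts()].
#' @return The input data frame with added columns `kind`, `host_exon`,
#'   `host_intron`, `skipped_from`, `skipped_to`, `offset`, `shorthand`,
#'   `r_description`, `known`, `labels`, `event_key`.
#' @export
annotate_sample <- function(junctions, model, annotation = NULL,
                            opts = classify_opts()) {
  stopifnot(is.data.frame(junctions))
  depth <- sum(junctions$reads)
  evs <- lapply(seq_len(nrow(junctions)), function(i) {
    classify_junction(model, junctions$g_start[i], junctions$g_end[i],
                      context = junctions[, c("g_start", "g_end")],
                      opts = opts, context_depth = depth)
  })
  take <- function(f, default) vapply(evs, function(e) {
    v <- f(e); if (length(v)) v[1] else default
  }, default)
  out <- junctions
  out$kind <- take(function(e) e$kind, NA_character_)
  out$host_exon <- take(function(e) e$host_exon, NA_integer_)
  out$host_intron <- take(function(e) e$host_intron, NA_integer_)
  out$skipped_from <- take(function(e) e$skipped[1], NA_integer_)
  out$skipped_to <- take(function(e) e$skipped[length(e$skipped)], NA_integer_)
  out$offset <- take(function(e) e$offset, NA_integer_)
  out$shorthand <- take(function(e) e$shorthand, NA_character_)
  out$r_description <- take(function(e) e$r_description, NA_character_)
  out$event_key <- event_key(out$chrom, out$g_start, out$g_end)
  out$known <- FALSE
  out$labels <- ""
  if (!is.null(annotation)) out <- mark_known(out, annotation)
  out
}

#' Type every junction of a cohort
#'
#' @param cohort A `cohort_table` (see [cohort_table()]).
#' @param model A [transcript_model()].
#' @param annotation Optional `known_junction_annotation`.
#' @param opts A [classify_opts()].
#' @return One data frame of typed junctions across all samples (column
#'   `sample_id` first).
#' @export
annotate_cohort <- function(cohort, model, annotation = NULL,
                            opts = classify_opts()) {
  stopifnot(inherits(cohort, "cohort_table"))
  per <- lapply(split(cohort$junctions, cohort$junctions$sample_id),
                annotate_sample, model = model, annotation = annotation,
                opts = opts)
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  out[order(out$sample_id, out$g_start, out$g_end), ]
}
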