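#' Specify a tandem multi-exon duplication
#'
#' Describes a genomic duplication of exons `from_exon..to_exon` together
#' with the internal alternative splicing events (whole-exon skips) that
#' apply independently to each copy of their host exon. Only the tandem
#' direct geometry is enumerable; inverted duplications raise an explicit
#' unsupported error at enumeration time.
#'
#' @param from_exon,to_exon 1-based exon range of the duplicated segment.
#' @param orientation `"direct"` or `"inverted"`.
#' @param breakpoints Optional genomic breakpoint pair (informational).
#' @param internal_events Integer vector of exon indices (within the
#'   duplicated range) whose skipping applies independently to the proximal
#'   and distal copy; may be named (names become event labels).
#' @return List of class `duplication_spec`.
#' @export
duplication_spec <- function(from_exon, to_exon, orientation = "direct",
                             breakpoints = NULL, internal_events = integer()) {
  from_exon <- as.integer(from_exon); to_exon <- as.integer(to_exon)
  stopifnot(from_exon >= 1, from_exon <= to_exon)
  if (!orientation %in% c("direct", "inverted"))
    stop("orientation must be 'direct' or 'inverted'")
  ie <- as.integer(internal_events)
  if (length(ie) && (any(ie < from_exon) || any(ie > to_exon)))
    stop("internal events must be hosted inside the duplicated exon range")
  structure(list(from_exon = from_exon, to_exon = to_exon,
                 orientation = orientation, breakpoints = breakpoints,
                 internal_events = ie,
                 event_labels = if (is.null(names(internal_events)))
                   paste0(.DELTA, ie) else names(internal_events)),
            class = "duplication_spec")
}

#' Enumerate the transcripts of a tandem direct duplication
#'
#' A tandem direct duplication of exons `a..b` produces the exon walk
#' `1..b, a..b, (b+1)..n`; each internal event applies independently to the
#' proximal and distal copy of its host exon, giving `2^k` combinations
#' for `k` (event, copy) pairs. Structurally identical outcomes (same
#' labelled exon sequence) are deduplicated -- identity is structural, not
#' by net length, since different structures of equal length are distinct
#' transcripts.
#'
#' @param model A [transcript_model()].
#' @param spec A [duplication_spec()].
#' @return List of `derived_transcript` objects, each with `exons` (data
#'   frame `exon`, `copy`), `applied` (event/copy flags), `net_change`
#'   (coding-length change in nt vs the reference transcript) and
#'   `junctions` (exon-to-exon pairs, including the duplication
#'   back-junction when present).
#' @export
enumerate_transcripts <- function(model, spec) {
  stopifnot(inherits(spec, "duplication_spec"))
  if (spec$orientation == "inverted")
    stop("inverted duplications are not enumerable (unsupported orientation)")
  n <- nrow(model$exons)
  if (spec$to_exon > n) stop("duplicated range exceeds the exon count")
  a <- spec$from_exon; b <- spec$to_exon
  base <- data.frame(
    exon = c(seq_len(b), seq.int(a, b), if (b < n) seq.int(b + 1L, n)),
    copy = c(rep("proximal", b), rep("distal", b - a + 1L),
             if (b < n) rep("proximal", n - b)))
  ev <- spec$internal_events
  k <- 2L * length(ev)
  combos <- if (k == 0) list(logical(0)) else {
    g <- expand.grid(rep(list(c(FALSE, TRUE)), k))
    lapply(seq_len(nrow(g)), function(i) as.logical(g[i, ]))
  }
  len <- model$exons$g_end - model$exons$g_start + 1L
  canonical_len <- sum(len)
  seen <- character()
  out <- list()
  for (flags in combos) {
    keep <- rep(TRUE, nrow(base))
    applied <- character()
    if (length(ev)) {
      for (j in seq_along(ev)) {
        for (ci in 1:2) {
          cp <- c("proximal", "distal")[ci]
          if (flags[(j - 1L) * 2L + ci]) {
            keep[base$exon == ev[j] & base$copy == cp] <- FALSE
            applied <- c(applied, paste0(spec$event_labels[j], "-", cp))
          }
        }
      }
    }
    tx <- base[keep, ]
    sig <- paste(tx$exon, substr(tx$copy, 1, 1), sep = ".", collapse = "|")
    if (sig %in% seen) next
    seen <- c(seen, sig)
    jn <- if (nrow(tx) > 1)
      data.frame(from = tx$exon[-nrow(tx)], to = tx$exon[-1])
    else data.frame(from = integer(), to = integer())
    out[[length(out) + 1L]] <- structure(
      list(exons = tx, applied = applied,
           net_change = sum(len[tx$exon]) - canonical_len,
           junctions = jn, signature = sig),
      class = "derived_transcript")
  }
  out
}

#' Predict the consequence of each duplication transcript
#'
#' Frame is assessed two ways: the net coding-length change modulo 3, and a
#' segment walk that flags any exon read outside its native reading frame.
#' A transcript whose duplicated block is read out of frame is overwhelming
#' likely to encounter a stop codon within it (an out-of-frame reading of
#' coding sequence meets a stop about every 20 codons), so such transcripts
#' are flagged `ptc_likely` and counted as truncating even when the net
#' change is a multiple of three. The summary reports whether any
#' combination restores the frame with no predicted truncation
#' (`rescue`).
#'
#' @param transcripts List from [enumerate_transcripts()].
#' @param model A [transcript_model()].
#' @return List with `transcripts` (each gaining a `consequence` element:
#'   `frame`, `out_of_frame_nt`, `ptc_likely`, `truncating`) and `rescue`
#'   (logical).
#' @export
duplication_consequences <- function(transcripts, model) {
  len <- model$exons$g_end - model$exons$g_start + 1L
  c_start <- model$exons$c_start
  for (i in seq_along(transcripts)) {
    tx <- transcripts[[i]]
    cum <- cumsum(c(0L, len[tx$exons$exon]))[seq_len(nrow(tx$exons))]
    native <- c_start[tx$exons$exon] - 1L
    oof <- (cum - native) %% 3L != 0L
    # only coding sequence matters for frame
    coding <- model$exons$c_end[tx$exons$exon] >= model$cds_start &
      c_start[tx$exons$exon] <= model$cds_end
    oof_nt <- sum(len[tx$exons$exon][oof & coding])
    frame <- if (tx$net_change %% 3L == 0L) "in_frame" else "frameshift"
    ptc_likely <- frame == "frameshift" || oof_nt > 0L
    transcripts[[i]]$consequence <- list(
      frame = frame, out_of_frame_nt = as.integer(oof_nt),
      ptc_likely = ptc_likely, truncating = ptc_likely)
  }
  rescue <- any(vapply(transcripts, function(t)
    t$consequence$frame == "in_frame" && !t$consequence$ptc_likely, TRUE))
  list(transcripts = transcripts, rescue = rescue)
}

#' Full duplication report
#'
#' Enumerates the transcript space of a tandem direct duplication, predicts
#' per-transcript consequences and writes an optional JSON report.
#'
#' @param model A [transcript_model()].
#' @param spec A [duplication_spec()].
#' @param path Optional JSON output path.
#' @return List of class `duplication_report`: `spec`, `transcripts` (with
#'   consequences), `rescue`, `n_transcripts`.
#' @export
duplication_report <- function(model, spec, path = NULL) {
  txs <- enumerate_transcripts(model, spec)
  cq <- duplication_consequences(txs, model)
  rep <- structure(list(
    gene = model$gene, transcript_id = model$transcript_id,
    spec = list(from_exon = spec$from_exon, to_exon = spec$to_exon,
                orientation = spec$orientation,
                breakpoints = spec$breakpoints,
                internal_events = spec$event_labels),
    n_transcripts = length(cq$transcripts),
    rescue = cq$rescue,
    transcripts = lapply(cq$transcripts, function(t) list(
      exons = paste(t$exons$exon,
                    ifelse(t$exons$copy == "distal", "d", "p"),
                    sep = "", collapse = "-"),
      applied = t$applied, net_change = t$net_change,
      frame = t$consequence$frame,
      out_of_frame_nt = t$consequence$out_of_frame_nt,
      truncating = t$consequence$truncating))),
    class = "duplication_report")
  if (!is.null(path))
    jsonlite::write_json(unclass(rep), path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  rep
}

#' @export
print.duplication_report <- function(x, ...) {
  cat(sprintf("<duplication_report> %s exons %d-%d (%s): %d transcript(s), rescue: %s\n",
              x$gene, x$spec$from_exon, x$spec$to_exon, x$spec$orientation,
              x$n_transcripts, x$rescue))
  for (t in x$transcripts)
    cat(sprintf("  %-40s net %+5d nt  %s%s\n", t$exons, t$net_change,
                t$frame, if (t$truncating) " (truncating)" else ""))
  invisible(x)
}
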