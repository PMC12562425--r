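#' Consequence prediction configuration
#'
#' @param ptc_rule_nt Distance rule for nonsense-mediated decay candidacy:
#'   a premature termination codon more than this many nucleotides upstream
#'   of the last exon-exon junction marks the transcript as an NMD
#'   candidate. The canonical boundary rule is 50 nt (configurable 50-55).
#' @return List of class `consequence_config`.
#' @export
consequence_config <- function(ptc_rule_nt = 50) {
  stopifnot(ptc_rule_nt >= 0)
  structure(list(ptc_rule_nt = ptc_rule_nt), class = "consequence_config")
}

# cDNA-level change implied by a typed event: deleted exonic span (del) or
# inserted intronic length at an exon-exon boundary (ins).
event_cdna_change <- function(event, model) {
  ex <- model$exons
  kind <- event$kind
  if (kind == "exon_skip") {
    x <- if (inherits(event, "splicing_event")) event$skipped[1]
         else event$skipped_from
    y <- if (inherits(event, "splicing_event"))
           event$skipped[length(event$skipped)]
         else event$skipped_to
    return(list(type = "del", del = c(ex$c_start[x], ex$c_end[y]), ins = 0L))
  }
  if (kind == "exonic_donor_shift") {
    x <- event$host_exon
    a <- genomic_to_cdna(model, if (model$strand == "+") event$g_start
                                else event$g_end)
    return(list(type = "del", del = c(a$base, ex$c_end[x]), ins = 0L))
  }
  if (kind == "exonic_acceptor_shift") {
    x <- event$host_exon
    b <- genomic_to_cdna(model, if (model$strand == "+") event$g_end
                                else event$g_start)
    return(list(type = "del", del = c(ex$c_start[x], b$base), ins = 0L))
  }
  if (kind %in% c("intronic_donor_shift", "intronic_acceptor_shift")) {
    i <- event$host_intron
    return(list(type = "ins", ins = as.integer(event$offset),
                point = ex$c_end[i]))
  }
  if (kind == "alt_first_exon")
    return(list(type = "transcript_start", ins = 0L))
  list(type = "none", ins = 0L)
}

#' Predict the coding consequence of a splicing event
#'
#' Frame is classified from the net coding-length change modulo 3. When the
#' coding sequence is supplied, the altered reading frame is scanned for
#' the first stop codon and the premature-termination position is reported;
#' without it the PTC position is omitted and NMD candidacy falls back to
#' the length rule (a frameshift starting more than `ptc_rule_nt`
#' nucleotides upstream of the last exon-exon junction is assumed to
#' terminate early). NMD candidacy uses the canonical boundary rule: a PTC
#' more than `ptc_rule_nt` (default 50) nucleotides upstream of the last
#' exon-exon junction.
#'
#' @param event A typed event (`splicing_event` or one-row data frame from
#'   [annotate_sample()]).
#' @param model A [transcript_model()].
#' @param cds_seq Optional coding sequence (single string, `cds_start` to
#'   `cds_end` of the model, uppercase ACGT).
#' @param cfg A [consequence_config()].
#' @return List of class `consequence_prediction`: `frame` (`"in_frame"`,
#'   `"frameshift"` or `"not_applicable"`), `net_change` (signed coding-
#'   length change in nt), `ptc` (cDNA position of the first premature stop
#'   in the altered transcript, or `NA`), `nmd_candidate`, `protein_note`.
#' @examples
#' # a 106-nt coding deletion is a frameshift (106 %% 3 == 1)
#' @export
predict_consequence <- function(event, model, cds_seq = NULL,
                                cfg = consequence_config()) {
  ch <- event_cdna_change(event, model)
  cds <- c(model$cds_start, model$cds_end)
  n_ex <- nrow(model$exons)
  last_junc <- if (n_ex >= 2) model$exons$c_end[n_ex - 1] else NA_integer_
  out <- list(frame = "not_applicable", net_change = 0L, ptc = NA_integer_,
              nmd_candidate = FALSE, protein_note = "")
  class(out) <- "consequence_prediction"
  if (ch$type == "none") {
    out$protein_note <- "no change relative to the reference transcript"
    return(out)
  }
  if (ch$type == "transcript_start") {
    out$protein_note <- paste("alternative first exon; upstream structure",
                              "unknown, effect on translation start not",
                              "predicted")
    return(out)
  }
  if (ch$type == "del") {
    a <- max(ch$del[1], cds[1]); b <- min(ch$del[2], cds[2])
    del_cds <- max(0L, b - a + 1L)
    net <- -del_cds
    change_start <- ch$del[1]
  } else {
    in_cds <- ch$point >= cds[1] && ch$point < cds[2]
    net <- if (in_cds) ch$ins else 0L
    del_cds <- 0L
    change_start <- ch$point + 1L
  }
  out$net_change <- as.integer(net)
  if (net == 0L && ch$type == "del" && del_cds == 0L) {
    out$frame <- "not_applicable"
    out$protein_note <- "change confined to non-coding region"
    return(out)
  }
  if (ch$type == "ins" && net == 0L) {
    out$frame <- "not_applicable"
    out$protein_note <- "intron retention outside the coding region"
    return(out)
  }
  out$frame <- if (net %% 3L == 0L) "in_frame" else "frameshift"
  out$protein_note <- if (out$frame == "in_frame")
    sprintf("in-frame change of %+d nt", net)
  else
    sprintf("frameshift (%+d nt); truncated protein expected", net)

  # PTC scan with explicit sequence (deletions of coding sequence only;
  # retained intronic sequence is not available from the exon model)
  if (!is.null(cds_seq) && ch$type == "del") {
    seq <- toupper(cds_seq)
    rel <- function(p) p - cds[1] + 1L  # cDNA -> CDS-relative
    a <- max(ch$del[1], cds[1]); b <- min(ch$del[2], cds[2])
    if (b >= a) {
      altered <- paste0(substr(seq, 1L, rel(a) - 1L),
                        substr(seq, rel(b) + 1L, nchar(seq)))
      ptc_rel <- first_stop(altered, from_codon = max(1L, (rel(a) - 1L) %/% 3L))
      if (!is.na(ptc_rel)) {
        # skip the genuine terminal stop of an in-frame change
        if (!(out$frame == "in_frame" && ptc_rel * 3L >= nchar(altered) - 2L)) {
          out$ptc <- cds[1] + (ptc_rel - 1L) * 3L  # altered-transcript cDNA pos
        }
      }
    }
  }
  # NMD candidacy
  if (!is.na(last_junc)) {
    altered_last_junc <- if (change_start <= last_junc) last_junc + net
                         else last_junc
    if (!is.na(out$ptc)) {
      out$nmd_candidate <- out$ptc < (altered_last_junc - cfg$ptc_rule_nt)
    } else if (out$frame == "frameshift") {
      # length rule: a frameshift terminates shortly after the change start
      out$nmd_candidate <- change_start <= (altered_last_junc - cfg$ptc_rule_nt)
    }
  }
  out
}

# Index (codon number, 1-based) of the first stop codon in frame, scanning
# from `from_codon`; NA when none.
first_stop <- function(seq, from_codon = 1L) {
  n <- nchar(seq) %/% 3L
  if (n < from_codon) return(NA_integer_)
  starts <- seq.int(from_codon, n)
  codons <- substring(seq, (starts - 1L) * 3L + 1L, starts * 3L)
  hit <- which(codons %in% c("TAA", "TAG", "TGA", "UAA", "UAG", "UGA"))
  if (length(hit)) starts[hit[1]] else NA_integer_
}

#' Append consequence columns to a typed event table
#'
#' @param events Typed events from [annotate_cohort()] /
#'   [quantify_cohort()].
#' @param model A [transcript_model()].
#' @param cds_seq Optional coding sequence.
#' @param cfg A [consequence_config()].
#' @return `events` with added columns `frame`, `net_change`, `ptc`,
#'   `nmd_candidate`, `protein_note`.
#' @export
append_consequences <- function(events, model, cds_seq = NULL,
                                cfg = consequence_config()) {
  events$frame <- NA_character_
  events$net_change <- NA_integer_
  events$ptc <- NA_integer_
  events$nmd_candidate <- NA
  events$protein_note <- NA_character_
  for (i in seq_len(nrow(events))) {
    if (events$kind[i] %in% c("canonical", "unresolved")) next
    p <- predict_consequence(events[i, ], model, cds_seq, cfg)
    events$frame[i] <- p$frame
    events$net_change[i] <- p$net_change
    events$ptc[i] <- p$ptc
    events$nmd_candidate[i] <- p$nmd_candidate
    events$protein_note[i] <- p$protein_note
  }
  events
}
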