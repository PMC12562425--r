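#' Parse an HGVS-style r. change string (restricted grammar)
#'
#' Parses the restricted RNA-change dialect used for junction-level events:
#' `r.<pos>_<pos>del` (loss of an exonic span) and
#' `r.<pos>_<pos>ins<pos>_<pos>` (insertion of an intronic span, written in
#' donor/acceptor offset notation). Positions are c.-style, with optional
#' `+k`/`-k` intron offsets. This is deliberately not a full HGVS parser.
#'
#' @param s A single r. string, e.g. `"r.1977_2164del"` or
#'   `"r.2164_2165ins2164+1_2164+1270"`.
#' @return A list of class `r_change` with elements `kind` (`"del"` or
#'   `"ins"`), `span` (a [cdna_coord()] pair: the deleted span, or the
#'   flanking bases of the insertion point), `ins_span` (for insertions, the
#'   inserted span as a `cdna_coord` pair, else `NULL`) and `length` (the
#'   affected length in nucleotides: deleted length for `del`, inserted
#'   length for `ins`).
#' @examples
#' parse_r_description("r.1977_2164del")$length      # 188
#' parse_r_description("r.2164_2165ins2164+1_2164+1270")$length  # 1270
#' @export
parse_r_description <- function(s) {
  stopifnot(is.character(s), length(s) == 1)
  pos <- "([0-9]+(?:[+-][0-9]+)?)"
  m_del <- regmatches(s, regexec(paste0("^r\\.", pos, "_", pos, "del$"), s))[[1]]
  m_ins <- regmatches(s, regexec(paste0("^r\\.", pos, "_", pos, "ins",
                                        pos, "_", pos, "$"), s))[[1]]
  span_len <- function(a, b) {
    # inclusive length on a span of (base, offset) positions; exact for
    # exonic spans and for intronic spans anchored on one exon boundary
    (b$base - a$base) + (b$offset - a$offset) + 1L
  }
  cmp_le <- function(a, b) {
    a$base < b$base || (a$base == b$base && a$offset <= b$offset)
  }
  one <- function(x) cdna_coord(x$base, x$offset)  # defensive copy
  if (length(m_del)) {
    a <- parse_cdna(m_del[2]); b <- parse_cdna(m_del[3])
    if (!cmp_le(a, b)) stop("r. span start is after its end: ", s)
    out <- list(kind = "del", span = list(start = one(a), end = one(b)),
                ins_span = NULL, length = span_len(a, b))
  } else if (length(m_ins)) {
    a <- parse_cdna(m_ins[2]); b <- parse_cdna(m_ins[3])
    ia <- parse_cdna(m_ins[4]); ib <- parse_cdna(m_ins[5])
    if (!cmp_le(a, b)) stop("r. span start is after its end: ", s)
    if (!cmp_le(ia, ib)) stop("inserted span start is after its end: ", s)
    out <- list(kind = "ins", span = list(start = one(a), end = one(b)),
                ins_span = list(start = one(ia), end = one(ib)),
                length = span_len(ia, ib))
  } else {
    stop("malformed r. description: ", s)
  }
  class(out) <- "r_change"
  out
}

#' Format an r. change string
#'
#' Inverse of [parse_r_description()] on the same restricted grammar.
#'
#' @param kind `"del"` or `"ins"`.
#' @param span [cdna_coord()] pair (`start`, `end`): the deleted span, or
#'   the two exonic bases flanking an insertion point.
#' @param ins_span For insertions, the inserted intronic span.
#' @return The r. string.
#' @export
format_r_description <- function(kind = c("del", "ins"), span,
                                 ins_span = NULL) {
  kind <- match.arg(kind)
  p <- function(x) format_cdna(x, prefix = "")
  if (kind == "del")
    sprintf("r.%s_%sdel", p(span$start), p(span$end))
  else
    sprintf("r.%s_%sins%s_%s", p(span$start), p(span$end),
            p(ins_span$start), p(ins_span$end))
}

#' Format a typed splicing event as shorthand + r. description
#'
#' Produces the compact event shorthand used for splicing profiles
#' (\eqn{\Delta}x exon skip, \eqn{\Delta}xp / \eqn{\Delta}xq loss of the
#' initial/terminal part of exon x, \eqn{\blacktriangledown}xp /
#' \eqn{\blacktriangledown}xq retention of the initial/terminal part of
#' intron x) and the matching HGVS-style r. string. The `xq` triangle form
#' (terminal intron retention) is a symmetric extension of the published
#' donor-side convention, provided so acceptor-side intronic shifts can be
#' named generically.
#'
#' Alternative-first-exon events have no r. representation in this dialect
#' (the upstream exon structure is unknown); they are labelled
#' `AFE<intron>+<donor offset>` with `r_description` `NA`.
#'
#' @param model A [transcript_model()].
#' @param event A `splicing_event` as returned by [classify_junction()].
#' @return List of class `event_description` with `shorthand` and
#'   `r_description`.
#' @export
format_event <- function(model, event) {
  stopifnot(inherits(event, "splicing_event"))
  ex <- model$exons
  kind <- event$kind
  if (kind %in% c("canonical", "unresolved"))
    stop("format_event requires a typed, non-canonical event (got ", kind, ")")
  res <- switch(kind,
    exon_skip = {
      x <- event$skipped[1]; y <- event$skipped[length(event$skipped)]
      sh <- if (x == y) paste0(.DELTA, x) else paste0(.DELTA, x, "_", y)
      sp <- list(start = cdna_coord(ex$c_start[x]),
                 end = cdna_coord(ex$c_end[y]))
      list(sh, format_r_description("del", sp))
    },
    exonic_donor_shift = {
      x <- event$host_exon
      a <- genomic_to_cdna(model, if (model$strand == "+") event$g_start
                                  else event$g_end)
      sp <- list(start = a, end = cdna_coord(ex$c_end[x]))
      list(paste0(.DELTA, x, "q"), format_r_description("del", sp))
    },
    exonic_acceptor_shift = {
      x <- event$host_exon
      b <- genomic_to_cdna(model, if (model$strand == "+") event$g_end
                                  else event$g_start)
      sp <- list(start = cdna_coord(ex$c_start[x]), end = b)
      list(paste0(.DELTA, x, "p"), format_r_description("del", sp))
    },
    intronic_donor_shift = {
      i <- event$host_intron
      L <- event$offset
      anchor <- ex$c_end[i]
      sp <- list(start = cdna_coord(anchor), end = cdna_coord(anchor + 1L))
      ins <- list(start = cdna_coord(anchor, 1L), end = cdna_coord(anchor, L))
      list(paste0(.TRI, i, "p"), format_r_description("ins", sp, ins))
    },
    intronic_acceptor_shift = {
      i <- event$host_intron
      L <- event$offset
      anchor <- ex$c_start[i + 1]
      sp <- list(start = cdna_coord(anchor - 1L), end = cdna_coord(anchor))
      ins <- list(start = cdna_coord(anchor, -L), end = cdna_coord(anchor, -1L))
      list(paste0(.TRI, i, "q"), format_r_description("ins", sp, ins))
    },
    alt_first_exon = {
      i <- event$host_intron
      list(sprintf("AFE%d+%d", i, event$offset), NA_character_)
    },
    stop("unhandled event kind: ", kind)
  )
  structure(list(shorthand = res[[1]], r_description = res[[2]]),
            class = "event_description")
}
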