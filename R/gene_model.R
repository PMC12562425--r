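#' Build a reference transcript model
#'
#' The transcript model is the frame of reference for every splicing event:
#' an ordered set of exons with genomic and cDNA coordinates plus the coding
#' bounds. Coordinates are 1-based inclusive throughout; cDNA positions run
#' contiguously from 1 across exons in transcription order, so for a model
#' whose position 1 is the first base of the start codon the cDNA coordinate
#' equals the HGVS c. coordinate.
#'
#' @param gene Gene symbol, e.g. `"CDH1"`.
#' @param transcript_id Reference transcript identifier string.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`; exons must be supplied in transcription
#'   order (ascending genomic coordinates on `+`, descending on `-`).
#' @param exons Data frame with columns `g_start`, `g_end` (1-based
#'   inclusive genomic positions of each exon), one row per exon in
#'   transcription order.
#' @param cds_start,cds_end cDNA positions of the first and last coding base.
#'
#' @return An object of class `transcript_model`: a list with `gene`,
#'   `transcript_id`, `chrom`, `strand`, `exons` (data frame with `index`,
#'   `g_start`, `g_end`, `c_start`, `c_end`) and the coding bounds.
#' @examples
#' m <- transcript_model("TOY", "TOY-1", "chr1", "+",
#'                       data.frame(g_start = c(1001, 1201, 1401),
#'                                  g_end   = c(1100, 1300, 1500)),
#'                       cds_start = 1, cds_end = 300)
#' canonical_junctions(m)
#' @export
transcript_model <- function(gene, transcript_id, chrom, strand = c("+", "-"),
                             exons, cds_start, cds_end) {
  strand <- match.arg(strand)
  stopifnot(is.data.frame(exons), all(c("g_start", "g_end") %in% names(exons)),
            nrow(exons) >= 1)
  exons <- data.frame(g_start = as.integer(exons$g_start),
                      g_end = as.integer(exons$g_end))
  if (any(exons$g_start > exons$g_end))
    stop("exon g_start must be <= g_end")
  n <- nrow(exons)
  if (n > 1) {
    ok <- if (strand == "+")
      all(exons$g_start[-1] > exons$g_end[-n])
    else
      all(exons$g_end[-1] < exons$g_start[-n])
    if (!ok)
      stop("exons must be non-overlapping and ordered in transcription direction")
  }
  len <- exons$g_end - exons$g_start + 1L
  c_end <- cumsum(len)
  c_start <- c_end - len + 1L
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (!(cds_start >= 1L && cds_end <= c_end[n] && cds_start < cds_end))
    stop("coding bounds must satisfy 1 <= cds_start < cds_end <= transcript length")
  out <- list(gene = gene, transcript_id = transcript_id, chrom = chrom,
              strand = strand,
              exons = data.frame(index = seq_len(n), g_start = exons$g_start,
                                 g_end = exons$g_end, c_start = c_start,
                                 c_end = c_end),
              cds_start = cds_start, cds_end = cds_end)
  class(out) <- "transcript_model"
  out
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s%s, %d exons, cDNA length %d, CDS %d..%d\n",
              x$gene, x$transcript_id, x$chrom, x$strand, nrow(x$exons),
              max(x$exons$c_end), x$cds_start, x$cds_end))
  invisible(x)
}

# Genomic span of the transcript (min/max genomic coordinates of its exons).
model_span <- function(model) {
  c(min(model$exons$g_start), max(model$exons$g_end))
}

# Locate a genomic position within the model: list(type = "exon"/"intron",
# index) where intron i separates exon i from exon i+1 in transcription order.
locate_genomic <- function(model, g) {
  ex <- model$exons
  n <- nrow(ex)
  span <- model_span(model)
  if (g < span[1] || g > span[2])
    stop(sprintf("position %d lies outside the transcript span %d-%d",
                 g, span[1], span[2]))
  hit <- which(g >= ex$g_start & g <= ex$g_end)
  if (length(hit) == 1)
    return(list(type = "exon", index = hit))
  # intron i in transcription order
  if (model$strand == "+") {
    i <- max(which(ex$g_end < g))
  } else {
    i <- max(which(ex$g_start > g))
  }
  list(type = "intron", index = i)
}

#' cDNA coordinate with intron offset
#'
#' A cDNA position in the HGVS style: an exonic base plus a signed intron
#' offset (`0` for exonic positions, `+k` for the k-th base after a donor
#' site, `-k` for the k-th base before an acceptor site).
#'
#' @param base Integer cDNA position (>= 1).
#' @param offset Signed integer intron offset (default 0).
#' @return Object of class `cdna_coord` (vectorised: `base` and `offset` may
#'   be equal-length vectors).
#' @seealso [format_cdna()], [parse_cdna()]
#' @export
cdna_coord <- function(base, offset = 0L) {
  base <- as.integer(base)
  offset <- as.integer(rep_len(offset, length(base)))
  if (any(base < 1L)) stop("cDNA base positions must be >= 1")
  structure(list(base = base, offset = offset), class = "cdna_coord")
}

#' Format a cDNA coordinate as a c. string
#'
#' @param x A `cdna_coord`.
#' @param prefix Prefix to prepend, `"c."` by default (use `""` for the bare
#'   position as it appears inside r. strings).
#' @return Character vector like `"c.1008+7"`, `"c.1566-10"`, `"c.50"`.
#' @export
format_cdna <- function(x, prefix = "c.") {
  stopifnot(inherits(x, "cdna_coord"))
  off <- ifelse(x$offset > 0L, paste0("+", x$offset),
                ifelse(x$offset < 0L, as.character(x$offset), ""))
  paste0(prefix, x$base, off)
}

#' @export
print.cdna_coord <- function(x, ...) {
  cat(format_cdna(x), sep = "\n")
  invisible(x)
}

#' Parse a c. position string
#'
#' @param s Character vector like `"c.1008+1"`, `"1566-10"`, `"c.50"` (the
#'   `c.` prefix is optional).
#' @return A `cdna_coord`.
#' @export
parse_cdna <- function(s) {
  s2 <- sub("^c\\.", "", s)
  m <- regmatches(s2, regexec("^([0-9]+)([+-][0-9]+)?$", s2))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad))
    stop("malformed c. position: ", paste(s[bad], collapse = ", "))
  base <- vapply(m, function(p) as.integer(p[2]), 1L)
  offset <- vapply(m, function(p) if (p[3] == "") 0L else as.integer(p[3]), 1L)
  cdna_coord(base, offset)
}

#' Map genomic positions to cDNA coordinates
#'
#' Exonic positions map to offset 0; intronic positions map to the nearer
#' exon boundary in transcript orientation, with a positive offset from the
#' upstream donor or a negative offset from the downstream acceptor (ties go
#' to the donor side). The mapping is strand-aware and is the inverse of
#' [cdna_to_genomic()].
#'
#' @param model A [transcript_model()].
#' @param g Vector of genomic positions inside the transcript span.
#' @return A `cdna_coord` of the same length.
#' @examples
#' m <- transcript_model("TOY", "TOY-1", "chr1", "+",
#'                       data.frame(g_start = 1001, g_end = 1100), 1, 99)
#' format_cdna(genomic_to_cdna(m, 1050))  # "c.50"
#' @export
genomic_to_cdna <- function(model, g) {
  g <- as.integer(g)
  res <- lapply(g, function(gi) {
    loc <- locate_genomic(model, gi)
    ex <- model$exons
    if (loc$type == "exon") {
      e <- ex[loc$index, ]
      base <- if (model$strand == "+") e$c_start + (gi - e$g_start)
              else e$c_start + (e$g_end - gi)
      c(base, 0L)
    } else {
      i <- loc$index
      up <- ex[i, ]       # exon upstream (donor side) in transcription order
      dn <- ex[i + 1, ]   # exon downstream (acceptor side)
      if (model$strand == "+") {
        d_off <- gi - up$g_end
        a_off <- dn$g_start - gi
      } else {
        d_off <- up$g_start - gi
        a_off <- gi - dn$g_end
      }
      if (d_off <= a_off) c(up$c_end, d_off) else c(dn$c_start, -a_off)
    }
  })
  cdna_coord(vapply(res, `[`, 1L, 1), vapply(res, `[`, 1L, 2))
}

#' Map cDNA coordinates back to genomic positions
#'
#' @param model A [transcript_model()].
#' @param coord A `cdna_coord` (or a c. string accepted by [parse_cdna()]).
#' @return Integer vector of genomic positions.
#' @export
cdna_to_genomic <- function(model, coord) {
  if (is.character(coord)) coord <- parse_cdna(coord)
  stopifnot(inherits(coord, "cdna_coord"))
  ex <- model$exons
  vapply(seq_along(coord$base), function(k) {
    b <- coord$base[k]
    off <- coord$offset[k]
    i <- which(b >= ex$c_start & b <= ex$c_end)
    if (length(i) != 1)
      stop(sprintf("cDNA position %d outside the transcript", b))
    e <- ex[i, ]
    g <- if (model$strand == "+") e$g_start + (b - e$c_start)
         else e$g_end - (b - e$c_start)
    if (off == 0L) return(as.integer(g))
    # positive offset walks into the downstream intron, negative upstream
    if (model$strand == "+") as.integer(g + off) else as.integer(g - off)
  }, 1L)
}

#' Canonical junctions of a transcript model
#'
#' Returns the spliced-out gap of each intron between adjacent exons: the
#' first and last intronic base, 1-based inclusive, one row per intron in
#' transcription (5' to 3') order. These spans define the physiological
#' transcript; an observed junction is canonical iff it matches one of them
#' exactly.
#'
#' @param model A [transcript_model()].
#' @return Data frame with `intron_index`, `g_start`, `g_end` (`g_start <=
#'   g_end` in genomic orientation). A single-exon model returns an empty
#'   data frame with a warning.
#' @export
canonical_junctions <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2) {
    warning("single-exon model has no canonical junctions")
    return(data.frame(intron_index = integer(), g_start = integer(),
                      g_end = integer()))
  }
  if (model$strand == "+") {
    data.frame(intron_index = seq_len(n - 1),
               g_start = ex$g_end[-n] + 1L, g_end = ex$g_start[-1] - 1L)
  } else {
    # minus strand: exon i sits at higher genomic coordinates than exon i+1
    data.frame(intron_index = seq_len(n - 1),
               g_start = ex$g_end[-1] + 1L, g_end = ex$g_start[-n] - 1L)
  }
}

# -- model I/O ---------------------------------------------------------------

#' Read a transcript model from a tabular exon file or its JSON mirror
#'
#' The TSV layout is a commented header block (`# gene: ...`,
#' `# transcript_id: ...`, `# chrom: ...`, `# strand: ...`,
#' `# cds_start: ...`, `# cds_end: ...`) followed by tab-separated columns
#' `exon_index`, `chrom`, `strand`, `g_start`, `g_end` in transcription
#' order. A `.json` path is read as the JSON mirror written by
#' [write_transcript_model()].
#'
#' @param path File path (`.tsv` or `.json`).
#' @return A [transcript_model()].
#' @export
read_transcript_model <- function(path) {
  if (grepl("\\.json$", path)) {
    x <- jsonlite::fromJSON(path)
    return(transcript_model(x$gene, x$transcript_id, x$chrom, x$strand,
                            as.data.frame(x$exons)[, c("g_start", "g_end")],
                            x$cds_start, x$cds_end))
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    v <- sub(sprintf("^#\\s*%s:\\s*", key), "",
             grep(sprintf("^#\\s*%s:", key), hdr, value = TRUE)[1])
    if (is.na(v)) stop("model header missing field: ", key)
    v
  }
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  tab <- tab[order(tab$exon_index), ]
  transcript_model(get("gene"), get("transcript_id"), get("chrom"),
                   get("strand"), tab[, c("g_start", "g_end")],
                   as.integer(get("cds_start")), as.integer(get("cds_end")))
}

#' Write a transcript model to TSV (or its JSON mirror)
#'
#' @param model A [transcript_model()].
#' @param path Output path; a `.json` suffix selects the JSON mirror.
#' @return Invisibly, `path`.
#' @export
write_transcript_model <- function(model, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(gene = model$gene,
                              transcript_id = model$transcript_id,
                              chrom = model$chrom, strand = model$strand,
                              cds_start = model$cds_start,
                              cds_end = model$cds_end,
                              exons = model$exons),
                         path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# gene: %s", model$gene),
               sprintf("# transcript_id: %s", model$transcript_id),
               sprintf("# chrom: %s", model$chrom),
               sprintf("# strand: %s", model$strand),
               sprintf("# cds_start: %d", model$cds_start),
               sprintf("# cds_end: %d", model$cds_end)), con)
  tab <- data.frame(exon_index = model$exons$index, chrom = model$chrom,
                    strand = model$strand, g_start = model$exons$g_start,
                    g_end = model$exons$g_end)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
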