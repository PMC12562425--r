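#' Packaged CDH1-like reference transcript model
#'
#' A 16-exon model of the CDH1 E-cadherin transcript (NM_004360.3-style
#' numbering) shipped as an in-repo fixture. cDNA position 1 is the first
#' base of the start codon, so cDNA coordinates coincide with HGVS c.
#' coordinates; the exon boundaries in c. space (intron 7 after c.1008,
#' intron 10 acceptor at c.1566, intron 12 after c.1936, intron 13 after
#' c.2164, ...) match the published CDH1 splice-site positions. The
#' genomic coordinates are synthetic: they are anchored on chromosome 16
#' and preserve the features the analyses depend on (intron 2 spans
#' 63,258 bp; the exon 4-11 duplication breakpoints 68,841,756 and
#' 68,855,314 fall deep inside introns 3 and 11), but are not the hg19
#' positions. The fixture file is labelled accordingly
#' (`cdh1_synthetic_model.tsv`).
#'
#' @return A [transcript_model()].
#' @export
cdh1_model <- function() {
  read_transcript_model(system.file("extdata", "cdh1_synthetic_model.tsv",
                                    package = "spliceprof", mustWork = TRUE))
}

#' Packaged known-junction annotation for the CDH1 fixture
#'
#' Known alternative junctions of the CDH1 fixture: the exon-11 and exon-6
#' skip junctions (specific to the Ensembl NMD transcripts
#' ENST00000566612.1 and ENST00000561751.1) and two of the six intron-2
#' alternative-first-exon junctions, which correspond to the exon 1 of
#' reported alternative transcripts (synthetic placeholder labels).
#'
#' @return A `known_junction_annotation`.
#' @export
cdh1_known_junctions <- function() {
  load_annotation(system.file("extdata",
                              "cdh1_synthetic_known_junctions.tsv",
                              package = "spliceprof", mustWork = TRUE))
}

#' Packaged CDH1 lymphoblastoid event profile
#'
#' The `cdh1_lcl` simulation profile: the 11 alternative splicing events of
#' the CDH1 puromycin-treated lymphoblastoid profile with their mean
#' expression ratios and recurrences -- exon-6 skip 4.4% (100%
#' recurrence, NMD-sensitive), exon-11 skip 14.1% (100%, NMD-sensitive),
#' exon-14 acceptor shift 6.1% (100%), exon-13 donor shift 1.4% (50%),
#' intron-13 partial retention 0.7% (50%), and six intron-2
#' alternative-first-exon junctions: two known (ratios 10% each --
#' placeholders, as no published level exists for them) and four novel at
#' 26, 35.8, 74.1 and 134% with recurrences 85-100%. The default
#' canonical junction depth is 50,000 reads, a typical capture-RNA-seq
#' junction depth at which even the 0.7% event clears the 100-read
#' reporting filter.
#'
#' @param model The CDH1 fixture model (used to derive the junction
#'   spans).
#' @return An [event_profile()].
#' @export
cdh1_event_profile <- function(model = cdh1_model()) {
  ex <- model$exons
  gap_skip <- function(x, y) c(ex$g_end[x - 1] + 1L, ex$g_start[y + 1] - 1L)
  i2 <- c(ex$g_end[2] + 1L, ex$g_start[3] - 1L)  # intron 2 span
  i13 <- c(ex$g_end[13] + 1L, ex$g_start[14] - 1L)
  afe <- function(offset) c(i2[1] + offset, i2[2])
  rows <- rbind(
    data.frame(name = "D6",   g_start = gap_skip(6, 6)[1],
               g_end = gap_skip(6, 6)[2], true_ratio_pct = 4.4,
               recurrence_pct = 100, nmd_sensitive = TRUE,  known = TRUE),
    data.frame(name = "D11",  g_start = gap_skip(11, 11)[1],
               g_end = gap_skip(11, 11)[2], true_ratio_pct = 14.1,
               recurrence_pct = 100, nmd_sensitive = TRUE,  known = TRUE),
    data.frame(name = "D14p", g_start = i13[1],
               g_end = ex$g_start[14] + 33L, true_ratio_pct = 6.1,
               recurrence_pct = 100, nmd_sensitive = FALSE, known = FALSE),
    data.frame(name = "D13q", g_start = ex$g_start[13] + (1977L - ex$c_start[13]),
               g_end = i13[2], true_ratio_pct = 1.4,
               recurrence_pct = 50,  nmd_sensitive = FALSE, known = FALSE),
    data.frame(name = "T13p", g_start = i13[1] + 1270L,
               g_end = i13[2], true_ratio_pct = 0.7,
               recurrence_pct = 50,  nmd_sensitive = FALSE, known = FALSE),
    data.frame(name = "AFE2a_known", g_start = afe(8000L)[1],
               g_end = i2[2], true_ratio_pct = 10,
               recurrence_pct = 100, nmd_sensitive = FALSE, known = TRUE),
    data.frame(name = "AFE2b_known", g_start = afe(22000L)[1],
               g_end = i2[2], true_ratio_pct = 10,
               recurrence_pct = 100, nmd_sensitive = FALSE, known = TRUE),
    data.frame(name = "AFE2c", g_start = afe(5000L)[1],
               g_end = i2[2], true_ratio_pct = 26,
               recurrence_pct = 85,  nmd_sensitive = FALSE, known = FALSE),
    data.frame(name = "AFE2d", g_start = afe(15000L)[1],
               g_end = i2[2], true_ratio_pct = 35.8,
               recurrence_pct = 90,  nmd_sensitive = FALSE, known = FALSE),
    data.frame(name = "AFE2e", g_start = afe(35000L)[1],
               g_end = i2[2], true_ratio_pct = 74.1,
               recurrence_pct = 95,  nmd_sensitive = FALSE, known = FALSE),
    data.frame(name = "AFE2f", g_start = afe(52000L)[1],
               g_end = i2[2], true_ratio_pct = 134,
               recurrence_pct = 100, nmd_sensitive = FALSE, known = FALSE))
  event_profile(rows, depth = 50000, chrom = model$chrom)
}

#' Write / read an event profile as TSV
#'
#' @param profile An [event_profile()].
#' @param path File path.
#' @return Invisibly `path` (write) / an `event_profile` (read).
#' @export
write_event_profile <- function(profile, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# depth: %s", format(profile$depth)),
               sprintf("# chrom: %s", profile$chrom)), con)
  write.table(profile$events, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_profile
#' @export
read_event_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^#\\s*%s:\\s*", key), "",
                           grep(sprintf("^#\\s*%s:", key), hdr,
                                value = TRUE)[1])
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  event_profile(tab, depth = as.numeric(get("depth")), chrom = get("chrom"))
}
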