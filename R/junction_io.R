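#' Read a per-sample junction count file (BED)
#'
#' Two dialects are supported. `"overhang_cols"` (the default) is BED6 plus
#' two integer columns: `chrom`, `start` (0-based), `end` (half-open),
#' `name`, `score` = junction read count, `strand`, `overhang_left`,
#' `overhang_right`, where the BED interval is the spliced-out gap itself.
#' `"block"` is the junction-extractor convention in which the BED interval
#' extends to the outermost aligned bases and two block sizes encode the
#' maximal overhangs; the gap is recovered as
#' `[start + overhang_left, end - overhang_right)`.
#'
#' Coordinates are converted to the internal 1-based inclusive gap
#' representation (`g_start` = first intronic base, `g_end` = last).
#'
#' @param path File path.
#' @param dialect `"overhang_cols"` or `"block"`.
#' @param chroms Optional character vector of expected chromosome names;
#'   records on other chromosomes are kept but flagged
#'   (`chrom_known = FALSE`).
#' @return Data frame with columns `chrom`, `g_start`, `g_end`, `name`,
#'   `reads`, `strand`, `overhang_left`, `overhang_right`, `chrom_known`.
#' @export
read_junction_bed <- function(path, dialect = c("overhang_cols", "block"),
                              chroms = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), g_start = integer(),
                      g_end = integer(), name = character(),
                      reads = integer(), strand = character(),
                      overhang_left = integer(), overhang_right = integer(),
                      chrom_known = logical()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol_needed <- if (dialect == "overhang_cols") 8L else 12L
  rows <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) < ncol_needed)
      stop(sprintf("%s: line %d has %d fields, expected >= %d",
                   path, i, length(p), ncol_needed))
    start0 <- suppressWarnings(as.integer(p[2]))
    end0 <- suppressWarnings(as.integer(p[3]))
    score <- suppressWarnings(as.numeric(p[5]))
    if (is.na(start0) || is.na(end0) || is.na(score))
      stop(sprintf("%s: line %d is malformed", path, i))
    if (score < 0)
      stop(sprintf("%s: line %d has a negative read count", path, i))
    if (dialect == "overhang_cols") {
      ol <- as.integer(p[7]); or <- as.integer(p[8])
      gs <- start0 + 1L; ge <- end0
    } else {
      sizes <- as.integer(strsplit(p[11], ",")[[1]])
      if (length(sizes) < 2)
        stop(sprintf("%s: line %d lacks two block sizes", path, i))
      ol <- sizes[1]; or <- sizes[2]
      gs <- start0 + ol + 1L; ge <- end0 - or
    }
    if (is.na(ol) || is.na(or) || ol < 0 || or < 0)
      stop(sprintf("%s: line %d has invalid overhangs", path, i))
    list(chrom = p[1], g_start = gs, g_end = ge, name = p[4],
         reads = as.integer(round(score)), strand = p[6],
         overhang_left = ol, overhang_right = or)
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out$chrom_known <- if (is.null(chroms)) TRUE else out$chrom %in% chroms
  out
}

#' Write junction records as BED
#'
#' Inverse of [read_junction_bed()] on the same dialect; records are written
#' in deterministic (chrom, start, end) order.
#'
#' @param junctions Data frame with columns `chrom`, `g_start`, `g_end`,
#'   `reads`, `strand`, `overhang_left`, `overhang_right` (a `name` column
#'   is used if present).
#' @param path Output path.
#' @param dialect `"overhang_cols"` or `"block"`.
#' @return Invisibly, `path`.
#' @export
write_junction_bed <- function(junctions, path,
                               dialect = c("overhang_cols", "block")) {
  dialect <- match.arg(dialect)
  j <- junctions[order(junctions$chrom, junctions$g_start, junctions$g_end), ]
  nm <- if ("name" %in% names(j)) j$name
        else sprintf("JUNC%05d", seq_len(nrow(j)))
  if (dialect == "overhang_cols") {
    tab <- data.frame(j$chrom, j$g_start - 1L, j$g_end, nm, j$reads,
                      j$strand, j$overhang_left, j$overhang_right)
  } else {
    s0 <- j$g_start - 1L - j$overhang_left
    e0 <- j$g_end + j$overhang_right
    tab <- data.frame(j$chrom, s0, e0, nm, j$reads, j$strand, s0, e0,
                      "255,0,0", 2L,
                      paste(j$overhang_left, j$overhang_right, sep = ","),
                      paste(0L, j$g_end - s0, sep = ","))
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Load a known-junction annotation
#'
#' Reads a TSV of junction spans tagged with source transcript labels
#' (columns `chrom`, `g_start`, `g_end`, `label`; 1-based inclusive gap
#' coordinates; lines starting with `#` ignored). Duplicate spans have
#' their labels merged, with a warning when the labels conflict.
#'
#' @param path File path.
#' @return Object of class `known_junction_annotation` with a `spans` data
#'   frame (`chrom`, `g_start`, `g_end`, `labels` -- comma-joined).
#' @export
load_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) <= 1) {  # header only (or empty)
    spans <- data.frame(chrom = character(), g_start = integer(),
                        g_end = integer(), labels = character())
    return(structure(list(spans = spans),
                     class = "known_junction_annotation"))
  }
  tab <- read.table(text = lines, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "g_start", "g_end", "label") %in% names(tab)))
  if (any(!nzchar(tab$label))) stop("annotation labels must be non-empty")
  key <- paste(tab$chrom, tab$g_start, tab$g_end)
  if (anyDuplicated(key)) {
    confl <- tapply(tab$label, key, function(l) length(unique(l)) > 1)
    if (any(confl))
      warning("duplicate spans with conflicting labels; labels merged")
    agg <- tapply(tab$label, key, function(l)
      paste(sort(unique(l)), collapse = ","))
    first <- !duplicated(key)
    tab <- tab[first, c("chrom", "g_start", "g_end")]
    tab$labels <- as.character(agg[paste(tab$chrom, tab$g_start, tab$g_end)])
  } else {
    tab$labels <- tab$label
    tab <- tab[, c("chrom", "g_start", "g_end", "labels")]
  }
  rownames(tab) <- NULL
  structure(list(spans = tab), class = "known_junction_annotation")
}

#' Query annotation membership by exact span
#'
#' @param ann A `known_junction_annotation`.
#' @param g_start,g_end Gap coordinates (vectors).
#' @return Logical vector.
#' @export
is_known_junction <- function(ann, g_start, g_end) {
  stopifnot(inherits(ann, "known_junction_annotation"))
  paste(g_start, g_end) %in% paste(ann$spans$g_start, ann$spans$g_end)
}

#' Assemble a cohort table
#'
#' @param samples Data frame with columns `sample_id`, `puromycin`
#'   (logical), optionally `provenance` (free text, e.g. whether counts are
#'   uniquely-mapping reads only).
#' @param junctions Data frame of junction records with a `sample_id`
#'   column; every `sample_id` must appear in `samples`.
#' @return Object of class `cohort_table`.
#' @export
cohort_table <- function(samples, junctions) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "puromycin") %in% names(samples)))
  if (anyDuplicated(samples$sample_id))
    stop("sample ids must be unique")
  if (!all(junctions$sample_id %in% samples$sample_id))
    stop("junction records reference unknown sample ids")
  if (!"provenance" %in% names(samples)) samples$provenance <- ""
  structure(list(samples = samples, junctions = junctions),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d samples, %d junction records (%d puromycin-treated)\n",
              nrow(x$samples), nrow(x$junctions), sum(x$samples$puromycin)))
  invisible(x)
}

#' Read a cohort manifest
#'
#' The manifest is a TSV with columns `sample_id`, `path` (junction BED,
#' relative paths resolved against the manifest's directory), `puromycin`
#' (`yes`/`no`), optionally `provenance`.
#'
#' @param path Manifest path.
#' @return Data frame of samples with absolute `path`.
#' @export
read_manifest <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("sample_id", "path", "puromycin") %in% names(tab)))
  rel <- !grepl("^/", tab$path)
  tab$path[rel] <- file.path(dirname(path), tab$path[rel])
  tab$puromycin <- tolower(tab$puromycin) %in% c("yes", "true", "1")
  if (!"provenance" %in% names(tab)) tab$provenance <- rep("", nrow(tab))
  tab
}

#' Read a full cohort from a manifest
#'
#' @param manifest_path Manifest path (see [read_manifest()]).
#' @param dialect BED dialect passed to [read_junction_bed()].
#' @return A `cohort_table`.
#' @export
read_cohort <- function(manifest_path, dialect = "overhang_cols") {
  man <- read_manifest(manifest_path)
  if (nrow(man) == 0) stop("empty manifest: ", manifest_path)
  jl <- lapply(seq_len(nrow(man)), function(i) {
    j <- read_junction_bed(man$path[i], dialect = dialect)
    if (nrow(j)) j$sample_id <- man$sample_id[i]
    j
  })
  junctions <- do.call(rbind, jl[vapply(jl, nrow, 1L) > 0])
  cohort_table(man[, c("sample_id", "puromycin", "provenance")], junctions)
}

#' Write a cohort as per-sample BED files plus a manifest
#'
#' @param cohort A `cohort_table`.
#' @param dir Output directory (created if needed).
#' @param dialect BED dialect.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir, dialect = "overhang_cols") {
  stopifnot(inherits(cohort, "cohort_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$samples
  man$path <- paste0(man$sample_id, ".junctions.bed")
  for (i in seq_len(nrow(man))) {
    j <- cohort$junctions[cohort$junctions$sample_id == man$sample_id[i], ]
    write_junction_bed(j, file.path(dir, man$path[i]), dialect = dialect)
  }
  man$puromycin <- ifelse(man$puromycin, "yes", "no")
  mp <- file.path(dir, "manifest.tsv")
  write.table(man[, c("sample_id", "path", "puromycin", "provenance")],
              mp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mp)
}
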