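#' Load a run configuration from YAML
#'
#' The run configuration bundles input paths (model, annotation,
#' manifest), the reporting-filter and confidence settings, the assessment
#' thresholds, a seed and the output directory. A run is reproducible from
#' its persisted configuration plus inputs; every output header records a
#' hash of the configuration.
#'
#' @param path YAML file. Recognised keys: `model`, `annotation`,
#'   `manifest`, `out_dir`, `seed`, and nested `filter`, `confidence`,
#'   `assessment` blocks mirroring the respective `*_config()` arguments.
#' @return List of class `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(model = y$model, annotation = y$annotation,
             manifest = y$manifest, out_dir = y$out_dir,
             seed = if (is.null(y$seed)) 1L else y$seed,
             filter = do.call(filter_config,
                              if (is.null(y$filter)) list() else y$filter),
             confidence = do.call(confidence_config,
                                  if (is.null(y$confidence)) list()
                                  else y$confidence),
             assessment_args = if (is.null(y$assessment)) list()
                               else y$assessment)
}

#' @rdname load_run_config
#' @param model,annotation,manifest,out_dir Paths.
#' @param seed Integer seed.
#' @param filter,confidence Config objects.
#' @param assessment_args Extra arguments for [assessment_config()].
#' @export
run_config <- function(model = NULL, annotation = NULL, manifest = NULL,
                       out_dir = ".", seed = 1L, filter = filter_config(),
                       confidence = confidence_config(),
                       assessment_args = list()) {
  structure(list(model = model, annotation = annotation,
                 manifest = manifest, out_dir = out_dir,
                 seed = as.integer(seed), filter = filter,
                 confidence = confidence,
                 assessment_args = assessment_args),
            class = "run_config")
}

config_hash <- function(cfg) substr(rlang::hash(unclass(cfg)), 1, 12)

audit_header <- function(cfg, model) {
  c(tool = sprintf("spliceprof %s", as.character(packageVersion("spliceprof"))),
    config_hash = config_hash(cfg),
    model = sprintf("%s (%s)", model$gene, model$transcript_id),
    date = format(Sys.Date()))
}

#' Cohort profiling workflow
#'
#' Reads a cohort manifest, types and quantifies every junction, appends
#' consequences and writes the cohort profile TSV (with an audit header:
#' tool version, configuration hash, model id) plus the per-sample event
#' table.
#'
#' @param manifest Manifest path (see [read_manifest()]).
#' @param model A [transcript_model()] or a model file path.
#' @param annotation A `known_junction_annotation`, a path, or `NULL`.
#' @param out_dir Output directory.
#' @param cfg A [run_config()] (filters/confidence taken from it).
#' @return Invisibly, a list with `profile` (the [cohort_profile()]) and
#'   the output paths.
#' @export
run_profile <- function(manifest, model, annotation = NULL,
                        out_dir = ".", cfg = run_config()) {
  if (is.character(model)) model <- read_transcript_model(model)
  if (is.character(annotation)) annotation <- load_annotation(annotation)
  cohort <- read_cohort(manifest)
  events <- annotate_cohort(cohort, model, annotation)
  quant <- quantify_cohort(events, model, cfg$filter, cfg$confidence)
  quant <- append_consequences(quant, model)
  prof <- cohort_profile(quant, n_samples = nrow(cohort$samples))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- audit_header(cfg, model)
  hdr["samples"] <- as.character(nrow(cohort$samples))
  hdr["events_reported"] <- as.character(nrow(prof))
  hdr["filters"] <- sprintf("min_reads=%g, min_ratio_pct=%g",
                            cfg$filter$min_reads, cfg$filter$min_ratio_pct)
  p_prof <- file.path(out_dir, "cohort_profile.tsv")
  p_ev <- file.path(out_dir, "events.tsv")
  write_cohort_profile(prof, p_prof, hdr)
  con <- file(p_ev, "w", encoding = "UTF-8")
  writeLines(sprintf("# %s: %s", names(hdr), hdr), con)
  write.table(quant, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(list(profile = prof, events = quant,
                 paths = c(profile = p_prof, events = p_ev)))
}

#' Variant assessment workflow
#'
#' Assesses each variant of a variant table against the cohort: the
#' carrier sample versus all remaining samples as controls.
#'
#' @param carrier_id Carrier sample id.
#' @param manifest Cohort manifest path (must include the carrier).
#' @param variants Variant table path (see [read_variant_table()]) or data
#'   frame.
#' @param model A [transcript_model()] or path.
#' @param annotation Annotation or path or `NULL`.
#' @param out_dir Output directory.
#' @param cfg A [run_config()].
#' @return Invisibly, the list of `variant_assessment` objects.
#' @export
run_assess <- function(carrier_id, manifest, variants, model,
                       annotation = NULL, out_dir = ".",
                       cfg = run_config()) {
  if (is.character(model)) model <- read_transcript_model(model)
  if (is.character(annotation)) annotation <- load_annotation(annotation)
  if (is.character(variants)) variants <- read_variant_table(variants)
  if (nrow(variants) == 0) stop("no variants to assess")
  cohort <- read_cohort(manifest)
  acfg <- do.call(assessment_config,
                  c(list(filter = cfg$filter, confidence = cfg$confidence),
                    cfg$assessment_args))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  score_cols <- setdiff(names(variants), c("variant", "c_position"))
  out <- lapply(seq_len(nrow(variants)), function(i) {
    sc <- unlist(variants[i, score_cols, drop = FALSE])
    a <- assess_variant(carrier_id, cohort, variants$c_position[i], model,
                        annotation, acfg,
                        variant_label = variants$variant[i],
                        scores = if (length(sc)) sc else NULL)
    base <- gsub("[^A-Za-z0-9._-]", "_", variants$variant[i])
    write_assessment(a, file.path(out_dir, paste0(base, ".json")),
                     file.path(out_dir, paste0(base, ".txt")))
    a
  })
  invisible(out)
}

#' Duplication analysis workflow
#'
#' @param model A [transcript_model()] or path.
#' @param spec A [duplication_spec()] or a JSON path with fields
#'   `from_exon`, `to_exon`, `orientation`, optional `breakpoints`,
#'   `internal_events` (exon indices).
#' @param out Output JSON path (or `NULL`).
#' @return The [duplication_report()].
#' @export
run_dup <- function(model, spec, out = NULL) {
  if (is.character(model)) model <- read_transcript_model(model)
  if (is.character(spec)) {
    y <- jsonlite::fromJSON(spec)
    spec <- duplication_spec(y$from_exon, y$to_exon,
                             orientation = if (is.null(y$orientation))
                               "direct" else y$orientation,
                             breakpoints = y$breakpoints,
                             internal_events = if (is.null(y$internal_events))
                               integer() else y$internal_events)
  }
  duplication_report(model, spec, path = out)
}

#' Cohort simulation workflow
#'
#' Generates a synthetic cohort from an event profile and writes it in the
#' same junction BED + manifest form the profiling workflow consumes,
#' with the ground truth alongside (the truth table is written for
#' validation and is never read back by the analysis).
#'
#' @param profile An [event_profile()] or profile TSV path; `NULL` uses
#'   the packaged CDH1 profile.
#' @param model A [transcript_model()] or path; `NULL` uses the CDH1
#'   fixture.
#' @param out_dir Output directory.
#' @param cfg A [sim_config()].
#' @return Invisibly, the manifest path.
#' @export
run_simulate <- function(profile = NULL, model = NULL, out_dir = ".",
                         cfg = sim_config()) {
  if (is.null(model)) model <- cdh1_model()
  else if (is.character(model)) model <- read_transcript_model(model)
  if (is.null(profile)) profile <- cdh1_event_profile(model)
  else if (is.character(profile)) profile <- read_event_profile(profile)
  sim <- generate_cohort(profile, cfg, model)
  mp <- write_cohort(sim$cohort, out_dir)
  write.table(sim$truth, file.path(out_dir, "ground_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mp)
}
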