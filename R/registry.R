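# Flat-file study registry: one canonical TSV plus one metadata JSON per
# study, and a single index.json listing all registered metadata records.

registry_index_path <- function(registry_dir) file.path(registry_dir, "index.json")

read_registry_index <- function(registry_dir) {
  p <- registry_index_path(registry_dir)
  if (!file.exists(p)) return(list())
  jsonlite::fromJSON(p, simplifyVector = FALSE)
}

#' Register a study in a flat-file registry
#'
#' Writes the canonical TSV and a metadata JSON under `registry_dir` and adds
#' the study to `index.json`. Registration normally requires a QC verdict
#' attached to the table (see [qc_verdict()]); `force = TRUE` overrides, as
#' the verdict is advisory and the final decision rests with the user.
#'
#' @param table A `sumstats_table`, ideally carrying a `"qc_report"` attribute.
#' @param registry_dir Registry directory (created if absent).
#' @param overwrite Replace an existing study with the same `study_id`.
#' @param force Register without an attached QC verdict.
#' @return The study id, invisibly.
#' @export
register_study <- function(table, registry_dir, overwrite = FALSE, force = FALSE) {
  stopifnot(inherits(table, "sumstats_table"))
  qc <- attr(table, "qc_report")
  if (is.null(qc) && !force)
    stop_input("no QC verdict attached; run qc_verdict() first or use force = TRUE")
  dir.create(registry_dir, showWarnings = FALSE, recursive = TRUE)
  idx <- read_registry_index(registry_dir)
  ids <- vapply(idx, function(e) e$study_id, character(1))
  sid <- table$metadata$study_id
  if (sid %in% ids && !overwrite)
    stop_input("study_id already registered: ", sid,
               " (use overwrite = TRUE to replace)")
  entry <- unclass(table$metadata)
  entry$n_records <- nrow(table$records)
  entry$qc_verdict <- if (!is.null(qc)) qc$verdict else NA
  write_sumstats(table, file.path(registry_dir, paste0(sid, ".tsv")))
  jsonlite::write_json(entry, file.path(registry_dir, paste0(sid, ".json")),
                       auto_unbox = TRUE, null = "null", na = "null")
  idx <- c(idx[ids != sid], list(entry))
  jsonlite::write_json(idx, registry_index_path(registry_dir),
                       auto_unbox = TRUE, null = "null", na = "null")
  invisible(sid)
}

#' List registered studies
#'
#' @param registry_dir Registry directory.
#' @param domain Optional domain filter (one of the five study domains).
#' @return Data frame of registry entries (study_id, trait_name, domain,
#'   sample_size, n_records, qc_verdict).
#' @export
list_registry <- function(registry_dir, domain = NULL) {
  idx <- read_registry_index(registry_dir)
  if (!is.null(domain)) {
    domain <- match.arg(domain, STUDY_DOMAINS)
    idx <- Filter(function(e) identical(e$domain, domain), idx)
  }
  if (length(idx) == 0L)
    return(data.frame(study_id = character(), trait_name = character(),
                      domain = character(), sample_size = integer(),
                      n_records = integer(), qc_verdict = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(idx, function(e)
    data.frame(study_id = e$study_id, trait_name = e$trait_name,
               domain = e$domain,
               sample_size = as.integer(e$sample_size %||% NA_integer_),
               n_records = as.integer(e$n_records %||% NA_integer_),
               qc_verdict = as.character(e$qc_verdict %||% NA_character_),
               stringsAsFactors = FALSE)))
}

#' Load a registered study
#'
#' @param registry_dir Registry directory.
#' @param study_id Identifier of a registered study.
#' @return The `sumstats_table` for the study.
#' @export
load_study <- function(registry_dir, study_id) {
  jp <- file.path(registry_dir, paste0(study_id, ".json"))
  tp <- file.path(registry_dir, paste0(study_id, ".tsv"))
  if (!file.exists(jp) || !file.exists(tp))
    stop_input("study not found in registry: ", study_id)
  md <- jsonlite::fromJSON(jp)
  meta <- study_metadata(md$study_id, md$trait_name, md$domain,
                         sample_size = md$sample_size %||% NA_integer_,
                         collection = md$collection %||% "",
                         ancestry = md$ancestry %||% "EUR",
                         genome_build = md$genome_build %||% "GRCh37",
                         source = md$source %||% "")
  read_sumstats(tp, canonical_dialect(), meta)
}
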