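# Subject/cohort manifests: one YAML or JSON file describing where a
# subject's multi-TR series, masks, CBF map and laboratory values live.

.read_config <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

.validate_manifest <- function(m, where = "manifest") {
  req <- c("subject_id", "tr_series_paths", "tr_values_ms")
  missing <- setdiff(req, names(m))
  if (length(missing)) {
    stop(where, ": missing required keys: ", paste(missing, collapse = ", "))
  }
  m$tr_values_ms <- as.double(unlist(m$tr_values_ms))
  m$tr_series_paths <- as.character(unlist(m$tr_series_paths))
  if (length(m$tr_values_ms) != length(m$tr_series_paths)) {
    stop(where, ": tr_values_ms (", length(m$tr_values_ms),
         ") and tr_series_paths (", length(m$tr_series_paths), ") differ in length")
  }
  if (any(m$tr_values_ms <= 0) || any(diff(m$tr_values_ms) <= 0)) {
    stop(where, ": tr_values_ms must be positive and strictly increasing")
  }
  if (!is.null(m$hct)) {
    m$hct <- as.double(m$hct)
    if (!is.finite(m$hct) || m$hct <= 0 || m$hct >= 1) {
      stop(where, ": hct must lie in (0, 1), got ", m$hct)
    }
  }
  if (!is.null(m$age_years)) {
    m$age_years <- as.double(m$age_years)
    if (m$age_years <= 0) stop(where, ": age_years must be positive")
  }
  if (!is.null(m$mask_paths)) m$mask_paths <- lapply(m$mask_paths, as.character)
  structure(m, class = "castrr_manifest")
}

#' Load a subject manifest
#'
#' Reads and validates a per-subject manifest (YAML or JSON by file
#' extension). Required keys: `subject_id`, `tr_series_paths` and matching
#' `tr_values_ms` (strictly increasing, ms). Optional: `mask_paths` (named:
#' `brain`, `blood`, `phantom_1`..`phantom_5`, `gm`, `wm`, `csf`),
#' `cbf_path`, `anatomical_path`, `hct` (fraction in (0,1)), `age_years`,
#' `sex`.
#'
#' @param path Manifest file path.
#' @return A validated `castrr_manifest` list.
#' @export
load_manifest <- function(path) {
  .validate_manifest(.read_config(path), where = basename(path))
}

#' Load a cohort manifest
#'
#' A cohort manifest has a `subjects` list (each entry a subject manifest,
#' validated as by [load_manifest()]) plus optional cohort-level fields such
#' as `seed`. Relative paths inside subject entries are interpreted relative
#' to the manifest's directory by the CLI.
#'
#' @param path Cohort manifest file path.
#' @return List with `subjects` (list of `castrr_manifest`) and any
#'   cohort-level fields.
#' @export
load_cohort_manifest <- function(path) {
  raw <- .read_config(path)
  if (is.null(raw$subjects) || !length(raw$subjects)) {
    stop("cohort manifest must contain a non-empty 'subjects' list")
  }
  subs <- raw$subjects
  if (is.data.frame(subs)) subs <- split(subs, seq_len(nrow(subs)))
  raw$subjects <- lapply(seq_along(subs), function(i) {
    m <- as.list(subs[[i]])
    .validate_manifest(m, where = sprintf("subject %d", i))
  })
  raw
}
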