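#' Write a session dataset to delimited text
#'
#' One trial per row, tab-separated: feature columns named `ch<i>_bin<j>`
#' and a final `label` column.  A sidecar `<path>.meta.json` records the
#' session name, day index, feature layout, and (optionally) the hash of the
#' generating configuration and the master seed.
#'
#' @param session A `session_dataset`.
#' @param path Output file path (e.g. `"S1D1.tsv"`).
#' @param config Optional generating [sim_config()]; its hash and seed are
#'   embedded in the sidecar for provenance.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, config = NULL) {
  df <- as.data.frame(session$features)
  df$label <- session$labels
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cn <- colnames(session$features)
  meta <- list(
    name = session$name, day_index = session$day_index,
    n_features = ncol(session$features),
    n_channels = length(unique(sub("_bin\\d+$", "", cn))),
    n_bins = length(unique(sub("^ch\\d+_", "", cn))),
    n_classes = length(unique(session$labels))
  )
  if (!is.null(config)) {
    meta$config_hash <- .config_hash(config)
    meta$seed <- config$seed
  }
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a session dataset from delimited text
#'
#' Parses and validates a file written by [write_session()]: the header must
#' name `ch<i>_bin<j>` feature columns with a final `label` column, every
#' row must have the same number of fields, and all counts must be
#' nonnegative integers.  Violations are reported with the offending row.
#'
#' @param path Path to the `.tsv` file.
#' @return A `session_dataset`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2L) .stopf("malformed session file: no data rows")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  nf <- length(header) - 1L
  if (nf < 1L || header[length(header)] != "label" ||
      !all(grepl("^ch[0-9]+_bin[0-9]+$", header[-length(header)]))) {
    .stopf("malformed header: expected ch<i>_bin<j> columns and a final 'label'")
  }
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  lens <- lengths(rows)
  if (any(lens != length(header))) {
    .stopf("ragged row %d: %d fields, expected %d",
           which(lens != length(header))[1] + 1L,
           lens[lens != length(header)][1], length(header))
  }
  M <- matrix(suppressWarnings(as.numeric(unlist(rows))),
              ncol = length(header), byrow = TRUE)
  bad <- which(rowSums(is.na(M)) > 0)
  if (length(bad) > 0) .stopf("non-numeric value in row %d", bad[1] + 1L)
  X <- M[, seq_len(nf), drop = FALSE]
  y <- M[, nf + 1L]
  neg <- which(rowSums(X < 0) > 0)
  if (length(neg) > 0) .stopf("negative count in row %d", neg[1] + 1L)
  nonint <- which(rowSums(X != round(X)) > 0)
  if (length(nonint) > 0) .stopf("non-integer count in row %d", nonint[1] + 1L)
  if (any(y != round(y)) || any(y < 1)) {
    .stopf("labels must be positive integers")
  }
  storage.mode(X) <- "integer"
  colnames(X) <- header[seq_len(nf)]
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(
    list(features = X, labels = as.integer(y),
         day_index = if (is.null(meta$day_index)) 1L
                     else as.integer(meta$day_index),
         name = if (is.null(meta$name)) {
           sub("\\.tsv$", "", basename(path))
         } else {
           meta$name
         }),
    class = "session_dataset"
  )
}

#' Write a whole session series to a directory
#'
#' @param series A `session_series`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- attr(series, "config")
  for (s in series) {
    write_session(s, file.path(dir, paste0(s$name, ".tsv")), config = cfg)
  }
  if (!is.null(cfg)) {
    jsonlite::write_json(
      c(unclass(cfg), list(config_hash = .config_hash(cfg))),
      file.path(dir, "series.json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}

#' Read a session series from a directory
#'
#' @param dir Directory of `.tsv` session files (sorted by day index).
#' @return A list of `session_dataset` (class `session_series`).
#' @export
read_series <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(files) == 0L) .stopf("no .tsv session files in %s", dir)
  sessions <- lapply(files, read_session)
  ord <- order(vapply(sessions, function(s) s$day_index, integer(1)))
  structure(sessions[ord], class = "session_series")
}

#' Save a trained decoder model
#'
#' Serialises the model (weights, PDA basis, configuration, and training
#' history) to a single-file binary container for reuse across runs.
#'
#' @param model A `decoder_model`.
#' @param path Output file path (e.g. `"model.rds"`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "decoder_model"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a decoder model saved by [save_model()]
#'
#' @param path Path to the model file.
#' @return The `decoder_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "decoder_model")) .stopf("not a decoder model: %s", path)
  model
}
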