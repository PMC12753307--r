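# fread with gzip handled through a base connection, so compressed files
# work without the optional R.utils dependency fread would otherwise need
fread_maybe_gz <- function(path, colClasses) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    data.table::fread(text = readLines(con), header = TRUE, sep = "auto",
                      colClasses = colClasses)
  } else {
    data.table::fread(path, header = TRUE, sep = "auto",
                      colClasses = colClasses)
  }
}

#' Read a sample-by-feature omics table
#'
#' Expects a header row of feature identifiers and a first column of sample
#' identifiers; TSV or CSV is auto-detected and gzip is transparent. Rows
#' are samples (one fixed orientation; transpose upstream if needed).
#'
#' @param path File path (`.tsv`, `.csv`, optionally `.gz`).
#' @param modality Modality label to attach to the view.
#' @param normalized Whether the stored matrix is already normalized.
#' @return An [omics_view()].
#' @export
read_omics_table <- function(path, modality, normalized = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread_maybe_gz(path, colClasses = list(character = 1L))
  if (ncol(dt) < 2L) stop("omics table needs a sample-id column plus features")
  ids <- dt[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s) at row(s): ",
         paste(utils::head(which(duplicated(ids)), 5), collapse = ", "))
  }
  body <- dt[, -1L, with = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stop(sprintf("non-numeric cell in column '%s' at data row %d",
                     names(body)[j], bad[1]))
      }
      data.table::set(body, j = j, value = num)
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  omics_view(m, modality, normalized = normalized)
}

#' Write an omics view as TSV
#'
#' @param view An [omics_view()].
#' @param path Output path (`.gz` suffix enables compression).
#' @return The path, invisibly.
#' @export
write_omics_table <- function(view, path) {
  stopifnot(inherits(view, "omics_view"))
  dt <- data.table::data.table(sample_id = sample_ids(view))
  dt <- cbind(dt, data.table::as.data.table(view$matrix))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a two-column sample label table
#'
#' @param path TSV/CSV with columns `sample_id` and `subtype` (names free;
#'   first two columns are used).
#' @return Named factor of subtypes, names = sample ids.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread_maybe_gz(path, colClasses = list(character = 1:2))
  if (ncol(dt) < 2L) stop("label table needs sample-id and subtype columns")
  ids <- dt[[1L]]
  if (anyDuplicated(ids)) stop("duplicate sample ids in label table")
  stats::setNames(factor(dt[[2L]]), ids)
}

#' Align a multi-omics cohort to the strict sample intersection
#'
#' Keeps only samples for which every modality and a valid label are
#' simultaneously available, in the label order, and reports how many
#' samples were dropped per modality.
#'
#' @param views Named list of [omics_view()] objects.
#' @param labels Named factor (names = sample ids).
#' @return List with `views` (aligned, same sample order), `labels`,
#'   `dropped` (named integer, per modality + labels).
#' @export
align_cohort <- function(views, labels) {
  stopifnot(length(views) >= 1L, !is.null(names(labels)))
  common <- Reduce(intersect, c(list(names(labels)),
                                lapply(views, sample_ids)))
  if (length(common) == 0L) stop("no samples shared by all modalities and labels")
  common <- names(labels)[names(labels) %in% common]
  dropped <- c(
    vapply(views, function(v) nrow(v$matrix) - length(common), integer(1)),
    labels = length(labels) - length(common)
  )
  if (any(dropped > 0)) {
    message("align_cohort: dropped ",
            paste(sprintf("%s=%d", names(dropped), dropped), collapse = ", "),
            " samples outside the strict intersection")
  }
  views <- lapply(views, function(v) {
    omics_view(v$matrix[common, , drop = FALSE], v$modality, v$normalized)
  })
  list(views = views, labels = droplevels(labels[common]), dropped = dropped)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory holding a schema-versioned JSON manifest
#' (modalities, dimensions, class labels, seed, parameter hash) next to the
#' serialized parameters, so components can be partially reloaded and runs
#' audited.
#'
#' @param model A `mogedn_model` (or pretraining bundle component).
#' @param dir Checkpoint directory (created if needed).
#' @param extra Optional named list merged into the manifest (e.g. config,
#'   seed, history summary).
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(model, dir, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- c(
    list(
      schema = model$schema %||% "mogedn-checkpoint-v1",
      modalities = model$modalities,
      input_dims = as.list(model$input_dims),
      n_classes = model$n_classes,
      classes = model$classes,
      hidden_dims = model$hidden_dims,
      latent_dim = model$latent_dim,
      core_width = model$core_width,
      param_hash = param_hash(model$params)
    ),
    extra
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(manifest_path)
  model <- readRDS(file.path(dir, "model.rds"))
  if (!identical(param_hash(model$params), manifest$param_hash)) {
    stop("checkpoint parameter hash mismatch in ", dir)
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
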