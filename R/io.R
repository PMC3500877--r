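#' Time-course dataset schema
#'
#' A time-course dataset is a data frame with one row per measured replicate
#' value and columns:
#' * `gene` — gene symbol (`GR`, `cJun`, `Bim`, `Erg`, ...)
#' * `level` — `"protein"` or `"mrna"`
#' * `time_h` — sampling time in hours (0 is the untreated control)
#' * `replicate` — integer replicate index
#' * `value_fold` — expression as fold of the t = 0 control (positive)
#'
#' Validation enforces the schema, positivity, uniqueness of
#' `(gene, level, time_h, replicate)`, presence of a t = 0 control for every
#' observable, and t = 0 values equal to 1 (the fold-change convention).
#'
#' @param data data frame to validate.
#' @param source label used in error messages (e.g. a file name).
#' @param line_offset added to row numbers in error messages (1 when rows
#'   came from a file with a header line).
#' @return the validated data frame, classed `gr_dataset`, invisibly sorted
#'   by gene, level, time, replicate.
#' @export
as_timecourse <- function(data, source = "dataset", line_offset = 0) {
  required <- c("gene", "level", "time_h", "replicate", "value_fold")
  if (!is.data.frame(data) || nrow(data) == 0)
    stop_validation("%s: no data", source)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop_validation("%s: missing column(s): %s", source,
                    paste(missing_cols, collapse = ", "))
  data <- data[required]
  data$time_h <- as.numeric(data$time_h)
  data$value_fold <- as.numeric(data$value_fold)
  row_ref <- function(i) paste0("row ", i + line_offset)

  bad <- which(!(data$level %in% c("protein", "mrna")))
  if (length(bad))
    stop_validation("%s: %s: level must be 'protein' or 'mrna'", source,
                    row_ref(bad[1]))
  bad <- which(!is.finite(data$value_fold) | data$value_fold <= 0)
  if (length(bad))
    stop_validation("%s: %s: value_fold must be positive", source,
                    row_ref(bad[1]))
  bad <- which(!is.finite(data$time_h) | data$time_h < 0)
  if (length(bad))
    stop_validation("%s: %s: time_h must be a non-negative number", source,
                    row_ref(bad[1]))
  key <- paste(data$gene, data$level, data$time_h, data$replicate)
  dup <- which(duplicated(key))
  if (length(dup))
    stop_validation("%s: %s: duplicate (gene, level, time, replicate) key",
                    source, row_ref(dup[1]))
  for (og in unique(paste(data$gene, data$level))) {
    sel <- paste(data$gene, data$level) == og
    t0 <- data$value_fold[sel & data$time_h == 0]
    if (!length(t0))
      stop_validation("%s: observable '%s' lacks a t=0 control", source, og)
    if (any(abs(t0 - 1) > 1e-8))
      stop_validation("%s: observable '%s' has t=0 values != 1 (data must be fold of the t=0 control)",
                      source, og)
  }
  data <- data[order(data$gene, data$level, data$time_h, data$replicate), ]
  rownames(data) <- NULL
  class(data) <- c("gr_dataset", "data.frame")
  data
}

#' Read / write a time-course dataset
#'
#' Tab-delimited text with the columns described in [as_timecourse()].
#' Reading validates the schema and reports the first offending line by
#' number; writing then reading is lossless.
#'
#' @param path file path.
#' @return [read_timecourse()] returns a validated `gr_dataset`.
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  data <- try(read.delim(path, stringsAsFactors = FALSE), silent = TRUE)
  if (inherits(data, "try-error") || nrow(data) == 0)
    stop_validation("%s: no data", path)
  as_timecourse(data, source = path, line_offset = 1)
}

#' @rdname read_timecourse
#' @param dataset a `gr_dataset` (or a data frame passing validation).
#' @export
write_timecourse <- function(dataset, path) {
  dataset <- as_timecourse(dataset)
  write.table(dataset, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Replicate means per (gene, level, time), with SD carried for display.
dataset_means <- function(data) {
  data <- as_timecourse(data)
  agg <- aggregate(value_fold ~ gene + level + time_h, data = data,
                   FUN = function(v) c(mean = mean(v), sd = sd(v),
                                       n = length(v)))
  out <- data.frame(gene = agg$gene, level = agg$level, time_h = agg$time_h,
                    mean_fold = agg$value_fold[, "mean"],
                    sd_fold = agg$value_fold[, "sd"],
                    n = agg$value_fold[, "n"],
                    stringsAsFactors = FALSE)
  out[order(out$gene, out$level, out$time_h), ]
}

dataset_observables <- function(data) {
  unique(data.frame(gene = data$gene, level = data$level,
                    stringsAsFactors = FALSE))
}
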