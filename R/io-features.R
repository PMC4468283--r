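# Canonical feature-name registry and the on-disk feature table (TSV).

#' Names of the 33 word-level prosodic features
#'
#' Canonical order: pause features, then energy, duration and F0 features,
#' each with its word-pause-word (WPW) variant before the single-word (W)
#' variant where both contexts exist.
#' @export
local_feature_names <- function() {
  c("PauseBefore", "PauseFillBefore", "PauseAfter", "PauseFillAfter",
    "EnRegCoeffWPW", "EnRegCoeffW", "EnMseRegWPW", "EnMseRegW",
    "EnAbsWPW", "EnAbsW", "EnNormWPW", "EnNormW", "EnMeanWPW", "EnMeanW",
    "EnMaxW", "EnMaxPosW",
    "DurAbsWPW", "DurAbsW", "DurNormWPW", "DurNormW",
    "F0RegCoeffWPW", "F0RegCoeffW", "F0MseRegWPW", "F0MseRegW",
    "F0MeanW", "F0MaxW", "F0MaxPosW", "F0MinW", "F0MinPosW",
    "F0OffW", "F0OffPosW", "F0OnW", "F0OnPosW")
}

#' Names of the 15 global prosodic features (per 15-word window)
#' @export
global_feature_names <- function() {
  c("MeanJitter", "StandDevJitter", "MeanShimmer", "StandDevShimmer",
    "NumVoiced", "MaxLenVoiced", "NumUnvoiced", "MaxLenUnvoiced",
    "RelNumVoicedUnvoiced", "RelLenVoicedSignal", "RelLenUnvoicedSignal",
    "StandDevF0", "MeanLenVoiced", "MeanLenUnvoiced", "RelLenVoicedUnvoiced")
}

#' All recording-level feature names (48 prosodic + CFx, CQx)
#' @export
feature_names <- function() {
  c(local_feature_names(), global_feature_names(), "CFx", "CQx")
}

#' Construct a feature table
#'
#' @param ids recording identifiers (one per row).
#' @param values numeric matrix or data.frame of features; columns are
#'   reordered into the canonical registry order, missing registry columns
#'   are added as NA, unknown columns are an error.
#' @return data.frame of class `voq_features` with an `id` column first.
#' @export
new_feature_table <- function(ids, values) {
  values <- as.data.frame(values)
  unknown <- setdiff(names(values), feature_names())
  if (length(unknown))
    voq_stop("voq_validation_error", "unknown feature column(s): %s",
             paste(unknown, collapse = ", "))
  out <- data.frame(id = as.character(ids), stringsAsFactors = FALSE)
  for (f in feature_names())
    out[[f]] <- if (f %in% names(values)) as.numeric(values[[f]]) else NA_real_
  all_na <- vapply(out[-1], function(col) all(is.na(col)), TRUE)
  class(out) <- c("voq_features", "data.frame")
  out
}

#' Write a feature table as TSV
#'
#' Header row, "." decimal separator, empty cells for missing values;
#' values reproduce to at least 12 significant digits on re-read.
#' @param table a `voq_features` table.
#' @param path output path.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "voq_features"))
  cols <- names(table)
  lines <- c(paste(cols, collapse = "\t"),
             vapply(seq_len(nrow(table)), function(i) {
               paste(c(table$id[i],
                       fmt_num(as.numeric(table[i, -1]), 15)), collapse = "\t")
             }, ""))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path TSV path.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "", colClasses = c(id = "character"))
  if (!identical(names(df), c("id", feature_names())))
    voq_stop("voq_format_error", "feature table header mismatch in %s", path)
  new_feature_table(df$id, df[-1])
}

#' @export
print.voq_features <- function(x, ...) {
  cat(sprintf("<voq_features: %d recordings x %d features (%d missing cells)>\n",
              nrow(x), ncol(x) - 1L, sum(is.na(x[-1]))))
  invisible(x)
}
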