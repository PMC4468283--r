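# Perceptual rating panels: items x raters x {R, B, H}, integer scores 0-3,
# missing cells allowed (recorded as NA, never as zero).

RBH <- c("R", "B", "H")

#' Construct a rating panel
#'
#' @param scores 3-D numeric array items x raters x criteria, with
#'   `dimnames` giving item ids, rater ids, and c("R","B","H"); values in
#'   \{0,1,2,3\} or NA.
#' @return object of class `voq_panel` (the validated array).
#' @export
new_panel <- function(scores) {
  stopifnot(length(dim(scores)) == 3)
  if (is.null(dimnames(scores)[[3]])) dimnames(scores)[[3]] <- RBH
  v <- scores[!is.na(scores)]
  if (length(v) && (any(v != round(v)) || any(v < 0 | v > 3)))
    voq_stop("voq_validation_error", "ratings must be integers in {0,1,2,3}")
  structure(scores, class = "voq_panel")
}

#' Read perceptual ratings from a delimited file
#'
#' Expects a header with columns `item`, `rater`, `R`, `B`, `H`; tab or
#' comma separated. Empty cells are stored as missing.
#'
#' @param path file path.
#' @return a `voq_panel`.
#' @export
read_ratings <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          na.strings = c("", "NA"))
  names(df) <- trimws(names(df))
  need <- c("item", "rater", RBH)
  if (!all(need %in% names(df)))
    voq_stop("voq_format_error", "ratings file needs columns %s",
             paste(need, collapse = ", "))
  key <- paste(df$item, df$rater)
  if (anyDuplicated(key))
    voq_stop("voq_validation_error", "duplicate (item, rater) pair: %s",
             key[duplicated(key)][1])
  for (cr in RBH) {
    bad <- which(!is.na(df[[cr]]) & !(df[[cr]] %in% 0:3))
    if (length(bad))
      voq_stop("voq_validation_error",
               "rating outside {0..3} in row %d (item %s, criterion %s)",
               bad[1], df$item[bad[1]], cr)
  }
  items <- unique(as.character(df$item))
  raters <- unique(as.character(df$rater))
  arr <- array(NA_real_, dim = c(length(items), length(raters), 3),
               dimnames = list(items, raters, RBH))
  ii <- match(as.character(df$item), items)
  ri <- match(as.character(df$rater), raters)
  for (k in 1:3) arr[cbind(ii, ri, k)] <- df[[RBH[k]]]
  new_panel(arr)
}

#' Per-item averaged ratings
#'
#' Averages available raters per item for each criterion; the standard
#' human reference for human-machine correlation.
#'
#' @param panel a `voq_panel`.
#' @return data.frame with columns item, R, B, H.
#' @export
panel_item_means <- function(panel) {
  m <- apply(unclass(panel), c(1, 3), mean, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  items <- rownames(m) %||% as.character(seq_len(nrow(m)))
  data.frame(item = items, R = m[, "R"], B = m[, "B"], H = m[, "H"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.voq_panel <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<voq_panel: %d items x %d raters x %d criteria, %d missing>\n",
              d[1], d[2], d[3], sum(is.na(x))))
  invisible(x)
}
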