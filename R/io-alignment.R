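# Word alignments: Praat TextGrid (long or short text form) and CTM.
# Times are seconds, 0-based, half-open intervals [start, end).

#' Construct a word alignment
#'
#' Empty-label intervals are dropped from the word list but retained
#' internally for pause computation.
#'
#' @param labels,starts,ends parallel vectors describing labelled intervals.
#' @return object of class `voq_alignment`: list with `words` (data.frame
#'   label/start/end, non-empty labels only) and `intervals` (all intervals,
#'   including silences).
#' @export
new_alignment <- function(labels, starts, ends) {
  df <- data.frame(label = as.character(labels),
                   start = as.numeric(starts),
                   end = as.numeric(ends),
                   stringsAsFactors = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  if (any(df$start >= df$end))
    voq_stop("voq_validation_error", "alignment has an interval with start >= end")
  if (nrow(df) > 1) {
    ov <- df$start[-1] < df$end[-nrow(df)] - 1e-9
    if (any(ov))
      voq_stop("voq_validation_error",
               "overlapping word intervals at %.3f s", df$start[-1][ov][1])
  }
  words <- df[nzchar(trimws(df$label)), , drop = FALSE]
  rownames(words) <- NULL
  if (nrow(words) == 0)
    voq_stop("voq_validation_error", "alignment contains no words")
  structure(list(words = words, intervals = df), class = "voq_alignment")
}

#' Read a word alignment file
#'
#' @param path TextGrid or CTM file.
#' @param dialect `"textgrid"` or `"ctm"`.
#' @param tier for TextGrids: name (or index) of the interval tier holding
#'   the words; default: the first interval tier.
#' @return a `voq_alignment`.
#' @export
read_alignment <- function(path, dialect = c("textgrid", "ctm"), tier = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "ctm") read_ctm(path) else read_textgrid(path, tier)
}

read_ctm <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), ";;")]
  if (length(lines) == 0)
    voq_stop("voq_validation_error", "empty CTM file: %s", path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- vapply(parts, length, 1L) < 5L
  if (any(bad))
    voq_stop("voq_format_error", "malformed CTM line: '%s'", lines[bad][1])
  start <- vapply(parts, function(p) as.numeric(p[3]), 1)
  dur <- vapply(parts, function(p) as.numeric(p[4]), 1)
  word <- vapply(parts, function(p) p[5], "")
  new_alignment(word, start, start + dur)
}

# Tolerant TextGrid parser: handles both the long ("item [1]:", keyed
# attributes) and short (bare values) text forms by scanning tier blocks.
read_textgrid <- function(path, tier = NULL) {
  txt <- readLines(path, warn = FALSE, encoding = "UTF-8")
  txt <- trimws(txt)
  is_long <- any(grepl("^xmin\\s*=", txt))
  tiers <- if (is_long) parse_textgrid_long(txt) else parse_textgrid_short(txt)
  tiers <- Filter(function(t) t$type == "IntervalTier", tiers)
  if (length(tiers) == 0)
    voq_stop("voq_format_error", "no interval tier in %s", path)
  sel <- if (is.null(tier)) tiers[[1]]
    else if (is.numeric(tier)) tiers[[tier]]
    else {
      hit <- Filter(function(t) identical(t$name, tier), tiers)
      if (length(hit) == 0)
        voq_stop("voq_config_error", "no tier named '%s' in %s", tier, path)
      hit[[1]]
    }
  new_alignment(sel$label, sel$start, sel$end)
}

parse_textgrid_long <- function(txt) {
  tier_starts <- grep("^item\\s*\\[", txt)
  if (length(tier_starts) == 0) return(list())
  tier_starts <- tier_starts[-1][grepl("^item\\s*\\[\\s*[0-9]", txt[tier_starts[-1]])]
  if (length(tier_starts) == 0)
    tier_starts <- grep("^item\\s*\\[\\s*[0-9]+\\s*\\]", txt)
  bounds <- c(tier_starts, length(txt) + 1L)
  lapply(seq_along(tier_starts), function(i) {
    block <- txt[bounds[i]:(bounds[i + 1] - 1L)]
    type <- sub('.*=\\s*"(.*)".*', "\\1", grep("^class\\s*=", block, value = TRUE)[1])
    name <- sub('.*=\\s*"(.*)".*', "\\1", grep("^name\\s*=", block, value = TRUE)[1])
    xmins <- as.numeric(sub(".*=\\s*", "", grep("^xmin\\s*=", block, value = TRUE)))
    xmaxs <- as.numeric(sub(".*=\\s*", "", grep("^xmax\\s*=", block, value = TRUE)))
    texts <- sub('.*=\\s*"(.*)"\\s*$', "\\1",
                 grep('^text\\s*=', block, value = TRUE))
    # first xmin/xmax pair is the tier's own range
    list(type = type, name = name,
         start = xmins[-1], end = xmaxs[-1], label = texts)
  })
}

parse_textgrid_short <- function(txt) {
  # short form: after the 2-line header and file xmin/xmax/<exists>/n_tiers,
  # each tier is: "IntervalTier"/"TextTier", name, xmin, xmax, n, then per
  # interval xmin, xmax, "text".
  vals <- txt[nzchar(txt)]
  vals <- vals[-(1:2)]  # file type + object class
  i <- 1L
  unquote <- function(s) sub('^"(.*)"$', "\\1", s)
  num <- function() { v <- as.numeric(vals[i]); i <<- i + 1L; v }
  str <- function() { v <- unquote(vals[i]); i <<- i + 1L; v }
  num(); num()            # file xmin, xmax
  str()                   # <exists>
  n_tiers <- num()
  tiers <- vector("list", n_tiers)
  for (k in seq_len(n_tiers)) {
    type <- str(); name <- str()
    num(); num()
    n_int <- num()
    start <- end <- numeric(0); label <- character(0)
    if (type == "IntervalTier") {
      start <- end <- numeric(n_int); label <- character(n_int)
      for (j in seq_len(n_int)) {
        start[j] <- num(); end[j] <- num(); label[j] <- str()
      }
    } else {
      for (j in seq_len(n_int)) { num(); str() }  # point tier, skipped
    }
    tiers[[k]] <- list(type = type, name = name,
                       start = start, end = end, label = label)
  }
  tiers
}

#' @export
print.voq_alignment <- function(x, ...) {
  cat(sprintf("<voq_alignment: %d words, %.2f-%.2f s>\n",
              nrow(x$words), min(x$intervals$start), max(x$intervals$end)))
  invisible(x)
}
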