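# Correlation-based feature selection (CFS): subset merit
#   M_S = k * mean(|r_cf|) / sqrt(k + k (k - 1) mean(|r_ff|))
# maximized by best-first search, applied per fold of a seeded 10-fold
# cross-validation; features are ranked by selection frequency.

#' CFS merit of a feature subset
#'
#' @param cor_cf absolute feature-target correlations (named).
#' @param cor_ff absolute feature-feature correlation matrix.
#' @param subset integer or character indices of the subset.
#' @return the merit (|r_cf| itself for a single feature).
#' @export
cfs_merit <- function(cor_cf, cor_ff, subset) {
  k <- length(subset)
  if (k == 0) return(0)
  rcf <- mean(cor_cf[subset])
  if (k == 1) return(rcf)
  sub_ff <- cor_ff[subset, subset]
  rff <- mean(sub_ff[upper.tri(sub_ff)])
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

# Best-first forward search over subsets; stops after `stall` consecutive
# expansions that fail to improve the best merit seen.
cfs_best_first <- function(cor_cf, cor_ff, stall = 5L) {
  p <- length(cor_cf)
  key <- function(s) paste(sort(s), collapse = ",")
  open <- list(list(s = integer(0), m = 0))
  visited <- new.env(hash = TRUE)
  best_s <- integer(0); best_m <- 0
  stalled <- 0L
  while (length(open) > 0 && stalled < stall) {
    merits <- vapply(open, function(e) e$m, 1)
    pick <- which.max(merits)
    node <- open[[pick]]
    open[[pick]] <- NULL
    improved <- FALSE
    for (f in setdiff(seq_len(p), node$s)) {
      s2 <- c(node$s, f)
      k2 <- key(s2)
      if (!is.null(visited[[k2]])) next
      visited[[k2]] <- TRUE
      m2 <- cfs_merit(cor_cf, cor_ff, s2)
      open[[length(open) + 1L]] <- list(s = s2, m = m2)
      if (m2 > best_m + 1e-12) {
        best_m <- m2; best_s <- s2
        improved <- TRUE
      }
    }
    stalled <- if (improved) 0L else stalled + 1L
  }
  list(subset = sort(best_s), merit = best_m)
}

#' Correlation-based feature selection in cross-validation
#'
#' Runs best-first CFS on the training part of each fold (seeded shuffle,
#' contiguous blocks) and ranks features by how often they are selected
#' across folds; ties broken by mean merit of the folds selecting the
#' feature, then by name.
#'
#' @param table a `voq_features` table (or plain data.frame of features).
#' @param target per-item numeric target (no constant target).
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed for the fold shuffle.
#' @return object of class `voq_cfs`: `ranking` (data.frame feature /
#'   frequency / mean_merit), `fold_subsets` (list of character vectors),
#'   `fold_merits`.
#' @export
cfs_select <- function(table, target, folds = 10L, seed = 1L) {
  X <- as.data.frame(table)
  if ("id" %in% names(X)) X$id <- NULL
  X <- X[vapply(X, is.numeric, TRUE)]
  n <- nrow(X)
  if (n < folds)
    voq_stop("voq_validation_error",
             "only %d items for %d folds; reduce folds", n, folds)
  if (stats::sd(target) == 0)
    voq_stop("voq_validation_error", "constant target")
  keep <- vapply(X, function(col) all(is.finite(col)) && stats::sd(col) > 0, TRUE)
  if (any(!keep)) {
    warning(sprintf("dropping %d constant/incomplete feature column(s)",
                    sum(!keep)))
    X <- X[keep]
  }
  p <- ncol(X)
  shuffled <- with_seed(seed, sample.int(n))
  fold_of <- rep(seq_len(folds), length.out = 0)
  sizes <- rep(n %/% folds, folds) + (seq_len(folds) <= n %% folds)
  assign_f <- rep(seq_len(folds), times = sizes)
  fold_id <- integer(n)
  fold_id[shuffled] <- assign_f
  Xm <- as.matrix(X)
  subsets <- vector("list", folds)
  merits <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    cor_cf <- abs(suppressWarnings(stats::cor(Xm[tr, , drop = FALSE], target[tr])))[, 1]
    cor_ff <- abs(suppressWarnings(stats::cor(Xm[tr, , drop = FALSE])))
    cor_cf[!is.finite(cor_cf)] <- 0
    cor_ff[!is.finite(cor_ff)] <- 0
    res <- cfs_best_first(cor_cf, cor_ff)
    subsets[[f]] <- colnames(Xm)[res$subset]
    merits[f] <- res$merit
  }
  freq <- vapply(colnames(Xm), function(nm)
    mean(vapply(subsets, function(s) nm %in% s, TRUE)), 1)
  mean_merit <- vapply(colnames(Xm), function(nm) {
    sel <- vapply(subsets, function(s) nm %in% s, TRUE)
    if (any(sel)) mean(merits[sel]) else 0
  }, 1)
  ord <- order(-freq, -mean_merit, colnames(Xm))
  ranking <- data.frame(feature = colnames(Xm)[ord],
                        frequency = freq[ord],
                        mean_merit = mean_merit[ord],
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(ranking = ranking, fold_subsets = subsets,
                 fold_merits = merits, folds = folds, seed = seed),
            class = "voq_cfs")
}

#' Features selected by a CFS ranking
#'
#' @param selection a `voq_cfs` object.
#' @param min_freq minimum cross-fold selection frequency (at least the
#'   top-ranked feature is always returned).
#' @export
selected_features <- function(selection, min_freq = 0.5) {
  r <- selection$ranking
  out <- r$feature[r$frequency >= min_freq]
  if (length(out) == 0) out <- r$feature[1]
  out
}

#' @export
print.voq_cfs <- function(x, ...) {
  cat(sprintf("<voq_cfs: %d folds>\n", x$folds))
  print(utils::head(x$ranking, 10), row.names = FALSE)
  invisible(x)
}
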