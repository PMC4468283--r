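# End-to-end orchestration: per-recording analysis and the study-level
# human-machine evaluation (feature table, agreement report, per-criterion
# feature selection + SVR + correlation with the averaged ratings, and the
# pairwise feature-correlation matrix).

#' Analyze one recording into its feature vector
#'
#' Runs the frame-level analysis, the word-level and global prosodic
#' feature extraction, and (when an EGG channel is present) the
#' electroglottographic summary.
#'
#' @param recording a `voq_recording`, or a path to a WAV file.
#' @param alignment a `voq_alignment`, or a path to a TextGrid/CTM file.
#' @param egg_path optional separate EGG WAV (when `recording` is a path).
#' @param config see [voq_config()].
#' @return list with `features` (named vector, 48 prosodic + CFx/CQx, the
#'   EGG entries NA without an EGG channel), `egg` (`voq_egg_summary` or
#'   NULL) and `counts` (words, voiced/unvoiced sections, EGG cycles).
#' @export
analyze_recording <- function(recording, alignment, egg_path = NULL,
                              config = voq_config()) {
  if (is.character(recording))
    recording <- read_recording(recording, egg_path = egg_path)
  if (is.character(alignment)) {
    dialect <- if (grepl("\\.ctm$", alignment, ignore.case = TRUE))
      "ctm" else "textgrid"
    alignment <- read_alignment(alignment, dialect)
  }
  track <- analyze_track(recording, config)
  locals <- extract_local(recording, alignment, track, config)
  globals <- extract_global(recording, alignment, track, config)
  eggsum <- NULL
  if (!is.null(recording$egg))
    eggsum <- tryCatch(
      egg_summary(recording$egg, recording$egg_rate, config),
      voq_empty_series = function(e) NULL)
  feats <- aggregate_features(locals, globals, eggsum)
  full <- stats::setNames(rep(NA_real_, length(feature_names())), feature_names())
  full[names(feats)] <- feats
  sec <- segment_sections(track)
  list(features = full, egg = eggsum,
       counts = c(words = nrow(locals),
                  voiced_sections = sum(sec$voiced),
                  unvoiced_sections = sum(!sec$voiced),
                  egg_cycles = if (is.null(eggsum)) 0L else eggsum$n_cycles))
}

#' Run a complete human-machine evaluation study
#'
#' Builds the recording-level feature table, averages the perceptual
#' ratings per item, and fits one model per criterion: correlation-based
#' feature selection in cross-validation, then a linear SVR on the
#' selected features, evaluated against the averaged ratings by Pearson's
#' r and Spearman's rho. The whole run is deterministic given the
#' manifest, configuration and seed.
#'
#' @param manifest list of per-recording entries `list(id, recording,
#'   alignment)` (in-memory objects) or `list(id, audio, egg, alignment)`
#'   (file paths); or a data.frame with columns `id`, `audio`,
#'   `alignment` and optionally `egg`.
#' @param ratings a `voq_panel`, or a data.frame `item`/`R`/`B`/`H` of
#'   pre-averaged (possibly continuous) reference scores.
#' @param config see [voq_config()].
#' @param seed integer seed controlling fold assignment.
#' @param features optional precomputed `voq_features` table (skips the
#'   signal analysis; must cover the manifest ids).
#' @return object of class `voq_study`: `features`, `reference`,
#'   `agreement` (NULL without a panel), `models` (per criterion: the CFS
#'   selection, the fitted `voq_svr`, predictions, and r/rho/p), and
#'   `feature_cor` (r upper / rho lower triangle).
#' @export
run_study <- function(manifest, ratings, config = voq_config(), seed = 1L,
                      features = NULL) {
  if (is.data.frame(manifest))
    manifest <- lapply(seq_len(nrow(manifest)), function(i) as.list(manifest[i, ]))
  ids <- vapply(manifest, function(m) as.character(m$id), "")
  if (anyDuplicated(ids))
    voq_stop("voq_validation_error", "duplicate recording ids in manifest")

  if (is.null(features)) {
    rows <- lapply(manifest, function(m) {
      res <- tryCatch({
        eggp <- m$egg %||% NULL
        if (!is.null(eggp) && (is.na(eggp) || !nzchar(eggp))) eggp <- NULL
        rec <- if (!is.null(m$recording)) m$recording
          else read_recording(m$audio, egg_path = eggp)
        analyze_recording(rec, m$alignment, config = config)
      }, error = function(e) {
        voq_stop("voq_validation_error", "recording '%s': %s", m$id,
                 conditionMessage(e))
      })
      res$features
    })
    features <- new_feature_table(ids, do.call(rbind, rows))
  } else {
    features <- features[match(ids, features$id), , drop = FALSE]
  }

  reference <- if (inherits(ratings, "voq_panel")) panel_item_means(ratings)
    else ratings
  if (!any(ids %in% reference$item))
    voq_stop("voq_validation_error",
             "no rating item matches a manifest recording id")
  reference <- reference[match(ids, reference$item), , drop = FALSE]
  agreement <- if (inherits(ratings, "voq_panel") && dim(ratings)[2] >= 2)
    agreement_report(ratings) else NULL

  folds <- config$cfs_folds
  if (length(ids) < folds)
    voq_stop("voq_validation_error",
             "%d recordings for %d folds; reduce cfs_folds", length(ids), folds)

  usable <- names(features)[-1][!vapply(features[-1], function(col)
    all(is.na(col)), TRUE)]
  X <- features[usable]
  models <- list()
  for (cr in RBH) {
    y <- reference[[cr]]
    ok <- !is.na(y)
    sel <- cfs_select(X[ok, , drop = FALSE], y[ok], folds = folds, seed = seed)
    chosen <- selected_features(sel, config$cfs_min_freq)
    fit <- train_svr(X[ok, , drop = FALSE], y[ok], chosen,
                     C = config$svr_C, epsilon = config$svr_epsilon,
                     tol = config$svr_tol)
    pred <- predict(fit, X[ok, , drop = FALSE])
    ev <- evaluate_predictions(pred, y[ok])
    models[[cr]] <- list(selection = sel, selected = chosen, fit = fit,
                         predictions = stats::setNames(pred, ids[ok]),
                         r = ev$r, rho = ev$rho, p_r = ev$p_r,
                         p_rho = ev$p_rho)
  }
  interest <- unique(c(unlist(lapply(models, function(m) m$selected)),
                       intersect(c("CFx", "CQx"), usable)))
  feature_cor <- cor_triangle(features[interest])
  structure(list(ids = ids, features = features, reference = reference,
                 agreement = agreement, models = models,
                 feature_cor = feature_cor, seed = seed, config = config),
            class = "voq_study")
}

# Pearson r in the upper triangle, Spearman rho in the lower.
cor_triangle <- function(df) {
  m <- as.matrix(df)
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  rho <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs",
                                     method = "spearman"))
  out <- r
  out[lower.tri(out)] <- rho[lower.tri(rho)]
  diag(out) <- NA
  out
}

#' @export
print.voq_study <- function(x, ...) {
  cat(sprintf("Voice-quality study: %d recordings\n", length(x$ids)))
  for (cr in RBH) {
    m <- x$models[[cr]]
    cat(sprintf("  %s: r = %.3f (p = %.3g), rho = %.3f; features: %s\n",
                cr, m$r, m$p_r, m$rho, paste(m$selected, collapse = ", ")))
  }
  if (!is.null(x$agreement)) {
    a <- x$agreement$per_criterion
    cat("Interrater alpha:",
        paste(sprintf("%s = %.2f", a$criterion, a$alpha), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.voq_study <- function(object, ...) {
  print(object)
  cat("\nSelected-feature weights (standardized):\n")
  for (cr in RBH) {
    cat(sprintf("  [%s] ", cr))
    w <- object$models[[cr]]$fit$weights
    cat(paste(sprintf("%s=%.3f", names(w), w), collapse = ", "), "\n")
  }
  invisible(object)
}

#' Write a study report directory
#'
#' Deterministic plain-text outputs: `features.tsv`, `reference.tsv`,
#' `models.json`, `agreement.json` (when available),
#' `feature_correlations.tsv` (r upper / rho lower triangle) and
#' `summary.txt`. Identical studies produce byte-identical directories.
#'
#' @param study a `voq_study`.
#' @param dir output directory (created if needed).
#' @export
write_study_report <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(study$features, file.path(dir, "features.tsv"))
  ref <- study$reference
  writeLines(c("item\tR\tB\tH",
               sprintf("%s\t%s\t%s\t%s", ref$item, fmt_num(ref$R),
                       fmt_num(ref$B), fmt_num(ref$H))),
             file.path(dir, "reference.tsv"))
  mj <- lapply(study$models, function(m)
    list(selected = as.list(m$selected),
         weights = as.list(round(m$fit$weights, 10)),
         intercept = round(m$fit$intercept, 10),
         r = round(m$r, 10), rho = round(m$rho, 10),
         p_r = signif(m$p_r, 6), p_rho = signif(m$p_rho, 6)))
  writeLines(jsonlite::toJSON(mj, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(dir, "models.json"))
  if (!is.null(study$agreement)) {
    a <- study$agreement
    aj <- list(per_criterion = a$per_criterion, stats = a$stats,
               cross = a$cross)
    writeLines(jsonlite::toJSON(aj, dataframe = "rows", pretty = TRUE,
                                digits = 10),
               file.path(dir, "agreement.json"))
  }
  fc <- study$feature_cor
  writeLines(c(paste(c("feature", colnames(fc)), collapse = "\t"),
               vapply(seq_len(nrow(fc)), function(i)
                 paste(c(rownames(fc)[i], fmt_num(fc[i, ], 6)),
                       collapse = "\t"), "")),
             file.path(dir, "feature_correlations.tsv"))
  out <- utils::capture.output(summary(study))
  writeLines(out, file.path(dir, "summary.txt"))
  invisible(dir)
}
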