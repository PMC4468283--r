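# Published weight sets for the RBH regression formulae, shipped as a JSON
# resource. The published models did not include intercepts, so a preset
# yields a relative score: the weighted sum of z-scored features. That is
# sufficient for correlation-based evaluation but not for absolute-score
# prediction.

#' Registry of published RBH regression weight sets
#'
#' Includes the best roughness sets (with and without CFx), the best
#' breathiness set, the four hoarseness sets, and the CFx/CQx-only sets
#' for each criterion.
#'
#' @return named list of `voq_preset` objects.
#' @export
preset_registry <- function() {
  path <- system.file("extdata", "presets.json", package = "voqual")
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  out <- lapply(names(raw$presets), function(nm) {
    p <- raw$presets[[nm]]
    w <- unlist(p$weights)
    bad <- setdiff(names(w), feature_names())
    if (length(bad))
      voq_stop("voq_validation_error", "preset %s has unknown feature(s): %s",
               nm, paste(bad, collapse = ", "))
    structure(list(name = nm, criterion = p$criterion, weights = w,
                   intercept = NA_real_, relative = TRUE,
                   r = p$r, rho = p$rho, significance = p$significance),
              class = "voq_preset")
  })
  stats::setNames(out, names(raw$presets))
}

#' Fetch one published weight set by name
#' @param name e.g. `"R_best_I"`, `"B_best"`, `"H_best_I"`, `"H_egg_only"`.
#' @export
preset_model <- function(name) {
  reg <- preset_registry()
  if (!name %in% names(reg))
    voq_stop("voq_config_error", "unknown preset '%s' (have: %s)", name,
             paste(names(reg), collapse = ", "))
  reg[[name]]
}

#' Relative score of a preset on already-standardized feature values
#'
#' @param preset a `voq_preset`.
#' @param z named numeric vector of z-scored feature values (must cover
#'   the preset's features).
#' @export
preset_score <- function(preset, z) {
  miss <- setdiff(names(preset$weights), names(z))
  if (length(miss))
    voq_stop("voq_validation_error", "missing feature value(s): %s",
             paste(miss, collapse = ", "))
  sum(preset$weights * z[names(preset$weights)])
}

#' @export
predict.voq_preset <- function(object, table, ...) {
  X <- as.data.frame(table)
  miss <- setdiff(names(object$weights), names(X))
  if (length(miss))
    voq_stop("voq_validation_error", "missing feature column(s): %s",
             paste(miss, collapse = ", "))
  Z <- scale(as.matrix(X[names(object$weights)]))
  as.numeric(Z %*% object$weights)
}

#' @export
print.voq_preset <- function(x, ...) {
  cat(sprintf("Published weight set '%s' (criterion %s, r = %.2f, rho = %.2f)\n",
              x$name, x$criterion, x$r, x$rho))
  print(x$weights)
  cat("Intercept unknown; scores are relative.\n")
  invisible(x)
}
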