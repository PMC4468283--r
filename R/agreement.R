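# Interrater agreement and correlation statistics for perceptual rating
# panels: Krippendorff's alpha (coincidence-matrix formulation, interval or
# ordinal metric, missing data handled by pairable-values weighting),
# Pearson/Spearman correlations with significance, rater-versus-rest
# agreement, and panel summary tables.

#' Krippendorff's alpha for one rating criterion
#'
#' alpha = 1 - D_o/D_e via the coincidence matrix: every item with m >= 2
#' ratings contributes each ordered pair of its ratings with weight
#' 1/(m - 1). Items with fewer than two ratings are ignored.
#'
#' @param panel a `voq_panel`.
#' @param criterion `"R"`, `"B"` or `"H"`.
#' @param metric difference metric: `"interval"` (squared value difference)
#'   or `"ordinal"` (squared cumulative-margin difference).
#' @return alpha (<= 1).
#' @export
krippendorff_alpha <- function(panel, criterion = c("R", "B", "H"),
                               metric = c("interval", "ordinal")) {
  criterion <- match.arg(criterion)
  metric <- match.arg(metric)
  m <- unclass(panel)[, , criterion, drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = dim(panel)[1])
  alpha_from_matrix(m, metric)
}

# items x raters numeric matrix with NAs -> alpha
alpha_from_matrix <- function(m, metric = "interval") {
  vals <- sort(unique(as.vector(m[!is.na(m)])))
  K <- length(vals)
  if (K < 2) voq_stop("voq_undefined", "ratings are constant; alpha undefined")
  co <- matrix(0, K, K)
  for (u in seq_len(nrow(m))) {
    r <- m[u, ]; r <- r[!is.na(r)]
    mu <- length(r)
    if (mu < 2) next
    ci <- match(r, vals)
    tab <- tabulate(ci, K)
    # ordered pairs within the unit, excluding self-pairing of one rating
    pair <- outer(tab, tab) - diag(tab)
    co <- co + pair / (mu - 1)
  }
  n <- sum(co)
  if (n <= 0) voq_stop("voq_undefined", "no item has >= 2 ratings")
  nc <- rowSums(co)
  delta <- metric_delta(vals, nc, metric)
  Do <- sum(co * delta) / n
  De <- sum(outer(nc, nc) * delta) / (n * (n - 1))
  1 - Do / De
}

metric_delta <- function(vals, nc, metric) {
  K <- length(vals)
  if (metric == "interval") return(outer(vals, vals, function(a, b) (a - b)^2))
  # ordinal: squared difference of cumulative margins between the ranks
  d <- matrix(0, K, K)
  for (c in seq_len(K)) for (k in seq_len(K)) {
    if (c == k) next
    lo <- min(c, k); hi <- max(c, k)
    d[c, k] <- (sum(nc[lo:hi]) - (nc[c] + nc[k]) / 2)^2
  }
  d
}

#' Pearson correlation with significance
#'
#' Product-moment correlation; two-sided p from the t approximation for
#' n >= 10 and from the exact permutation distribution for n < 10.
#'
#' @param x,y equal-length numeric vectors (n >= 3, non-constant).
#' @return list(r, p, n).
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) voq_stop("voq_undefined", "need >= 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    voq_stop("voq_undefined", "zero variance input")
  r <- stats::cor(x, y)
  list(r = r, p = cor_pvalue(x, y, r, exact = n < 10), n = n)
}

#' Spearman rank correlation with significance
#'
#' Pearson correlation of mid-ranked values; p-value policy as in
#' [pearson()].
#' @inheritParams pearson
#' @return list(rho, p, n).
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  res <- pearson(rank(x[ok]), rank(y[ok]))
  list(rho = res$r, p = res$p, n = res$n)
}

cor_pvalue <- function(x, y, r, exact) {
  n <- length(x)
  if (!exact) {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-15))
    return(2 * stats::pt(-abs(tstat), n - 2))
  }
  perms <- all_perms(n)
  xc <- x - mean(x); yc <- y - mean(y)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  rs <- as.vector(matrix(xc[perms], nrow = nrow(perms)) %*% yc) / denom
  mean(abs(rs) >= abs(r) - 1e-12)
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Each rater against the average of the others
#'
#' For each rater, their per-item vector is correlated with the item-wise
#' mean of all remaining raters; the mean r and rho over raters is
#' returned. Raters with zero variance are skipped (counted).
#'
#' @param panel a `voq_panel` (>= 3 raters).
#' @param criterion `"R"`, `"B"` or `"H"`.
#' @return list(mean_r, mean_rho, per_rater (data.frame), n_skipped).
#' @export
rater_vs_rest <- function(panel, criterion = c("R", "B", "H")) {
  criterion <- match.arg(criterion)
  m <- unclass(panel)[, , criterion, drop = TRUE]
  if (ncol(m) < 3) voq_stop("voq_validation_error", "need >= 3 raters")
  rs <- rhos <- rep(NA_real_, ncol(m))
  skipped <- 0L
  for (j in seq_len(ncol(m))) {
    rest <- rowMeans(m[, -j, drop = FALSE], na.rm = TRUE)
    ok <- !is.na(m[, j]) & is.finite(rest)
    if (sum(ok) < 3 || stats::sd(m[ok, j]) == 0 || stats::sd(rest[ok]) == 0) {
      skipped <- skipped + 1L
      next
    }
    rs[j] <- pearson(m[ok, j], rest[ok])$r
    rhos[j] <- spearman(m[ok, j], rest[ok])$rho
  }
  if (skipped > 0)
    warning(sprintf("%d rater(s) skipped (zero variance)", skipped))
  list(mean_r = mean(rs, na.rm = TRUE), mean_rho = mean(rhos, na.rm = TRUE),
       per_rater = data.frame(rater = colnames(m) %||% seq_len(ncol(m)),
                              r = rs, rho = rhos),
       n_skipped = skipped)
}

#' Panel summary and criterion cross-correlations
#'
#' Item-level averages over raters first, then mean/sd/min/max over items
#' per criterion, plus pairwise criterion correlations (r and rho with
#' p-values) of the item averages.
#'
#' @param panel a `voq_panel`.
#' @return list(stats (data.frame), cross (data.frame)).
#' @export
panel_summary <- function(panel) {
  im <- panel_item_means(panel)
  stats_df <- do.call(rbind, lapply(RBH, function(cr) {
    v <- im[[cr]][!is.na(im[[cr]])]
    data.frame(criterion = cr, mean = mean(v), sd = stats::sd(v),
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(RBH, 2)
  cross <- do.call(rbind, apply(pairs, 2, function(pr) {
    ok <- !is.na(im[[pr[1]]]) & !is.na(im[[pr[2]]])
    res <- tryCatch({
      pe <- pearson(im[[pr[1]]][ok], im[[pr[2]]][ok])
      sp <- spearman(im[[pr[1]]][ok], im[[pr[2]]][ok])
      c(pe$r, pe$p, sp$rho, sp$p)
    }, voq_undefined = function(e) rep(NA_real_, 4))
    data.frame(a = pr[1], b = pr[2], r = res[1], p_r = res[2],
               rho = res[3], p_rho = res[4], stringsAsFactors = FALSE)
  }))
  list(stats = stats_df, cross = cross)
}

#' Full interrater-agreement report
#'
#' Per criterion: Krippendorff's alpha and rater-versus-rest mean r/rho;
#' plus the panel summary and criterion cross-correlations.
#'
#' @param panel a `voq_panel`.
#' @param metric alpha difference metric (see [krippendorff_alpha()]).
#' @return object of class `voq_agreement`.
#' @export
agreement_report <- function(panel, metric = "interval") {
  per <- do.call(rbind, lapply(RBH, function(cr) {
    a <- tryCatch(krippendorff_alpha(panel, cr, metric),
                  voq_undefined = function(e) NA_real_)
    rr <- if (dim(panel)[2] >= 3)
      rater_vs_rest(panel, cr) else list(mean_r = NA, mean_rho = NA)
    data.frame(criterion = cr, alpha = a, rater_vs_rest_r = rr$mean_r,
               rater_vs_rest_rho = rr$mean_rho, stringsAsFactors = FALSE)
  }))
  ps <- panel_summary(panel)
  structure(list(per_criterion = per, stats = ps$stats, cross = ps$cross,
                 metric = metric),
            class = "voq_agreement")
}

#' @export
print.voq_agreement <- function(x, ...) {
  cat("Interrater agreement (", x$metric, " metric)\n", sep = "")
  df <- merge(x$per_criterion, x$stats, by = "criterion", sort = FALSE)
  print(format(df, digits = 3), row.names = FALSE)
  cat("\nCriterion cross-correlations:\n")
  print(format(x$cross, digits = 3), row.names = FALSE)
  invisible(x)
}
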