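# Linear epsilon-SVR trained by sequential minimal optimization (SMO) on
# standardized features. The dual uses 2n variables theta = (alpha, alpha*)
# in [0, C] with sign vector s = (+1, -1) and equality sum(s * theta) = 0:
#   minimize 0.5 theta' Qbar theta + p' theta,
#   Qbar[t, u] = s_t s_u K[i(t), j(u)],  p = (eps - y, eps + y).
# Pair selection is maximal-violating-pair; convergence when the KKT
# violation gap falls below `tol`.

smo_solve <- function(K, y, C, eps, tol = 1e-3, max_iter = 200000L) {
  n <- length(y)
  s <- c(rep(1, n), rep(-1, n))
  idx <- c(seq_len(n), seq_len(n))
  p <- c(eps - y, eps + y)
  theta <- numeric(2 * n)
  G <- p  # gradient = Qbar theta + p
  TAU <- 1e-12
  sets <- function() {
    list(up = (s > 0 & theta < C - TAU) | (s < 0 & theta > TAU),
         lo = (s > 0 & theta > TAU) | (s < 0 & theta < C - TAU))
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    v <- -s * G
    ss <- sets()
    if (!any(ss$up) || !any(ss$lo)) break
    i <- which(ss$up)[which.max(v[ss$up])]
    j <- which(ss$lo)[which.min(v[ss$lo])]
    if (v[i] - v[j] < tol || iter > max_iter) break
    ii <- idx[i]; jj <- idx[j]
    old_i <- theta[i]; old_j <- theta[j]
    if (s[i] != s[j]) {
      quad <- K[ii, ii] + K[jj, jj] - 2 * K[ii, jj]
      if (quad <= 0) quad <- TAU
      delta <- (-G[i] - G[j]) / quad
      dd <- theta[i] - theta[j]
      theta[i] <- theta[i] + delta
      theta[j] <- theta[j] + delta
      if (dd > 0) {
        if (theta[j] < 0) { theta[j] <- 0; theta[i] <- dd }
      } else {
        if (theta[i] < 0) { theta[i] <- 0; theta[j] <- -dd }
      }
      if (dd > 0) {
        if (theta[i] > C) { theta[i] <- C; theta[j] <- C - dd }
      } else {
        if (theta[j] > C) { theta[j] <- C; theta[i] <- C + dd }
      }
    } else {
      quad <- K[ii, ii] + K[jj, jj] - 2 * K[ii, jj]
      if (quad <= 0) quad <- TAU
      delta <- (G[i] - G[j]) / quad
      tot <- theta[i] + theta[j]
      theta[i] <- theta[i] - delta
      theta[j] <- theta[j] + delta
      if (tot > C) {
        if (theta[i] > C) { theta[i] <- C; theta[j] <- tot - C }
      } else {
        if (theta[j] < 0) { theta[j] <- 0; theta[i] <- tot }
      }
      if (tot > C) {
        if (theta[j] > C) { theta[j] <- C; theta[i] <- tot - C }
      } else {
        if (theta[i] < 0) { theta[i] <- 0; theta[j] <- tot }
      }
    }
    di <- theta[i] - old_i; dj <- theta[j] - old_j
    if (abs(di) < TAU && abs(dj) < TAU) break
    G <- G + (s * s[i] * K[idx, ii]) * di + (s * s[j] * K[idx, jj]) * dj
  }
  beta <- theta[seq_len(n)] - theta[n + seq_len(n)]
  v <- -s * G
  ss <- sets()
  # KKT: v <= b on I_up, v >= b on I_low; converged when the interval closes
  b <- if (any(ss$up) && any(ss$lo)) (max(v[ss$up]) + min(v[ss$lo])) / 2
       else if (any(ss$up)) max(v[ss$up]) else min(v[ss$lo])
  gap <- if (any(ss$up) && any(ss$lo)) max(v[ss$up]) - min(v[ss$lo]) else 0
  obj <- 0.5 * sum(beta * (K %*% beta)) + eps * sum(abs(beta)) - sum(y * beta)
  list(beta = beta, b = b, objective = obj, iterations = iter, gap = gap)
}

#' Train a linear epsilon-SVR by sequential minimal optimization
#'
#' Features are standardized to zero mean and unit variance before
#' training; the recovered weight vector lives in standardized space and
#' `coef()` maps it back to original units.
#'
#' @param table a `voq_features` table or data.frame of features.
#' @param target numeric target values (>= 3 items).
#' @param selected names of the feature columns to use.
#' @param C box constraint (> 0).
#' @param epsilon insensitive-tube half width (>= 0).
#' @param tol KKT violation tolerance for convergence.
#' @return object of class `voq_svr` with elements `feature_names`,
#'   `weights` (standardized space), `intercept`, `center`, `scale`, `C`,
#'   `epsilon`, `objective`, `dual_gap`.
#' @export
train_svr <- function(table, target, selected, C = 1.0, epsilon = 0.001,
                      tol = 1e-3) {
  X <- as.data.frame(table)
  missing_cols <- setdiff(selected, names(X))
  if (length(missing_cols))
    voq_stop("voq_validation_error", "missing feature column(s): %s",
             paste(missing_cols, collapse = ", "))
  if (length(selected) == 0)
    voq_stop("voq_validation_error", "no features selected")
  n <- length(target)
  if (n < 3) voq_stop("voq_validation_error", "need >= 3 items")
  Xm <- as.matrix(X[selected])
  center <- colMeans(Xm)
  scale <- apply(Xm, 2, stats::sd)
  scale[scale == 0] <- 1
  Z <- sweep(sweep(Xm, 2, center), 2, scale, "/")
  K <- Z %*% t(Z)
  fit <- smo_solve(K, target, C, epsilon, tol)
  if (fit$gap > max(tol, 1e-3) * 10)
    voq_stop("voq_convergence_error",
             "SMO failed to converge (duality gap %.3g)", fit$gap)
  w <- as.numeric(t(Z) %*% fit$beta)
  structure(list(feature_names = selected, weights = stats::setNames(w, selected),
                 intercept = fit$b, center = center, scale = scale,
                 C = C, epsilon = epsilon, objective = fit$objective,
                 dual_gap = fit$gap, n = n),
            class = "voq_svr")
}

#' @export
coef.voq_svr <- function(object, units = c("original", "standardized"), ...) {
  units <- match.arg(units)
  if (units == "standardized")
    return(c(object$weights, `(Intercept)` = object$intercept))
  w <- object$weights / object$scale
  b <- object$intercept - sum(object$weights * object$center / object$scale)
  c(w, `(Intercept)` = b)
}

#' Predict from a fitted SVR or a published preset
#'
#' For a `voq_svr`, applies the training standardization and the affine
#' model. For a `voq_preset` (published weight set without intercept) the
#' features are z-scored within the supplied table and the weighted sum is
#' returned as a relative score.
#'
#' @param object a `voq_svr` or `voq_preset`.
#' @param table feature table containing all model features.
#' @param ... unused.
#' @export
predict.voq_svr <- function(object, table, ...) {
  X <- as.data.frame(table)
  miss <- setdiff(object$feature_names, names(X))
  if (length(miss))
    voq_stop("voq_validation_error", "missing feature column(s): %s",
             paste(miss, collapse = ", "))
  Z <- sweep(sweep(as.matrix(X[object$feature_names]), 2, object$center),
             2, object$scale, "/")
  as.numeric(Z %*% object$weights + object$intercept)
}

#' @export
print.voq_svr <- function(x, ...) {
  cat(sprintf("Linear eps-SVR (SMO): %d features, n = %d, C = %g, eps = %g\n",
              length(x$weights), x$n, x$C, x$epsilon))
  cat("Standardized weights:\n")
  print(round(x$weights, 4))
  cat(sprintf("Intercept: %.4f  (dual gap %.2g)\n", x$intercept, x$dual_gap))
  invisible(x)
}

#' Evaluate predictions against averaged perceptual ratings
#'
#' @param predictions numeric model outputs.
#' @param reference per-item averaged ratings.
#' @return list(r, p_r, rho, p_rho, n).
#' @export
evaluate_predictions <- function(predictions, reference) {
  pe <- pearson(predictions, reference)
  sp <- spearman(predictions, reference)
  list(r = pe$r, p_r = pe$p, rho = sp$rho, p_rho = sp$p, n = pe$n)
}
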