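#' @include AllClasses.R AllGenerics.R
NULL

#' Fit a principal component model by NIPALS
#'
#' Sequential NIPALS with deflation: each component is extracted by
#' alternating score/loading regressions until the relative change of the
#' score vector falls below \code{tol}, then the rank-one contribution is
#' removed. Columns are mean-centred first; unit-variance scaling is
#' available but off by default (wavelet coefficients share a scale, and
#' centring-only matches the reference analyses). Determinism: the start
#' vector is the column of largest variance, and each component's sign is
#' fixed so its largest-magnitude loading entry is positive.
#'
#' @param X numeric matrix (n x p) or a [FeatureTable-class]; finite,
#'   n >= 2.
#' @param k number of components; default 2 (the score-plot convention of
#'   the reference analyses). Must satisfy \code{k <= min(n - 1, p)}.
#' @param tol convergence tolerance on the relative score change; default
#'   1e-10.
#' @param maxIter iteration cap per component; default 2000 (unstructured
#'   tables with near-degenerate leading singular values converge slowly;
#'   the cap is generous because each iteration is cheap).
#' @param scale logical; divide columns by their standard deviation before
#'   fitting (constant columns are left unscaled).
#' @return a [PcaModel-class].
#' @examples
#' X <- matrix(rnorm(20 * 30), 20, 30)
#' m <- fitPca(X, k = 3)
#' explainedVariance(m)
#' @export
fitPca <- function(X, k = 2L, tol = 1e-10, maxIter = 2000L, scale = FALSE) {
  if (is(X, "FeatureTable")) X <- X@X
  stopifnot(is.matrix(X))
  if (!all(is.finite(X))) stop("X must be finite")
  n <- nrow(X); p <- ncol(X); k <- as.integer(k)
  if (n < 2L || p < 1L) stop("need n >= 2 and p >= 1")
  if (k < 1L || k > min(n - 1L, p))
    stop(sprintf("rank error: k = %d must be in [1, min(n - 1, p) = %d]",
                 k, min(n - 1L, p)))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  scl <- rep(1, p)
  if (scale) {
    s <- sqrt(colSums(Xc^2) / (n - 1L))
    scl <- ifelse(s > 0, s, 1)
    Xc <- sweep(Xc, 2L, scl, "/")
  }
  totalSsq <- sum(Xc^2)
  Tm <- matrix(0, n, k); Pm <- matrix(0, p, k); r2 <- numeric(k)
  E <- Xc
  if (totalSsq == 0) stop("degenerate data: zero centred variance")
  for (a in seq_len(k)) {
    cv <- colSums(E^2)
    t_ <- E[, which.max(cv)]
    if (sum(t_^2) == 0) stop(sprintf(
      "rank error: residual is zero before component %d", a))
    for (it in seq_len(maxIter)) {
      p_ <- crossprod(E, t_)[, 1L] / sum(t_^2)
      p_ <- p_ / sqrt(sum(p_^2))
      t_new <- E %*% p_
      delta <- sqrt(sum((t_new - t_)^2)) / sqrt(sum(t_new^2))
      t_ <- t_new[, 1L]
      if (delta < tol) break
      if (it == maxIter)
        stop(sprintf("convergence error: component %d did not converge in %d iterations",
                     a, maxIter))
    }
    imax <- which.max(abs(p_))
    if (p_[imax] < 0) { p_ <- -p_; t_ <- -t_ }
    Tm[, a] <- t_; Pm[, a] <- p_
    r2[a] <- sum(t_^2) / totalSsq
    E <- E - tcrossprod(t_, p_)
  }
  new("PcaModel", center = ctr, scale = scl, scores = Tm, loadings = Pm,
      r2x = r2, k = k, n = as.integer(n), p = as.integer(p),
      residualSsq = sum(E^2), totalSsq = totalSsq)
}

#' @describeIn fitPca score matrix T.
#' @param x a [PcaModel-class].
#' @export
setMethod("scores", "PcaModel", function(x) x@scores)

#' @describeIn fitPca loading matrix P.
#' @param ... unused.
#' @export
setMethod("loadings", "PcaModel", function(x, ...) x@loadings)

#' @describeIn fitPca per-component explained-variance fractions.
#' @export
setMethod("explainedVariance", "PcaModel", function(x) x@r2x)

setMethod("show", "PcaModel", function(object) {
  cat(sprintf("PcaModel (NIPALS): %d components of a %d x %d table\n",
              object@k, object@n, object@p))
  cat(sprintf("  R2X per component: %s (cumulative %.3f)\n",
              paste(sprintf("%.3f", object@r2x), collapse = ", "),
              sum(object@r2x)))
})

#' Centre (and scale) new data the way the model was fitted
#' @keywords internal
.preprocess <- function(model, X) {
  if (ncol(X) != model@p)
    stop(sprintf("X has %d columns, model expects %d", ncol(X), model@p))
  sweep(sweep(X, 2L, model@center), 2L, model@scale, "/")
}

#' Project observations onto a fitted model
#'
#' @param model a [PcaModel-class].
#' @param X numeric matrix with the model's p columns (or a
#'   [FeatureTable-class]).
#' @return numeric score matrix (nrow(X) x k).
#' @export
projectScores <- function(model, X) {
  if (is(X, "FeatureTable")) X <- X@X
  .preprocess(model, X) %*% model@loadings
}

#' Distance to the model in X (DModX)
#'
#' Normalized residual standard deviation per observation after projection
#' onto the model plane. For observation i with residual row e_i over p
#' variables and k components,
#' \deqn{s_i = \sqrt{\sum_j e_{ij}^2 / (p - k)},\quad
#'       s_0 = \sqrt{\sum_{ij} e_{ij}^2 / ((n - k - 1)(p - k))},}
#' and DModX_i = (s_i / s_0) multiplied, for training observations, by the
#' correction factor \eqn{\sqrt{n / (n - k - 1)}} (the chemometric
#' convention for centred models, under which the training mean of DModX^2
#' is exactly 1). The critical limit is
#' \eqn{D_{crit} = \sqrt{F_{1-\alpha}(p - k,\ (n - k - 1)(p - k))}}, the
#' conventional F-approximation for flagging observations outside the
#' stated significance level.
#'
#' @param model a [PcaModel-class].
#' @param X the data matrix (or [FeatureTable-class]) to diagnose;
#'   residuals are computed by re-projection onto the model.
#' @param alpha significance level for the critical limit; default 0.05
#'   (the "5\% level").
#' @param training logical; apply the training-set correction factor
#'   (default TRUE).
#' @return a [DmodxResult-class].
#' @examples
#' X <- matrix(rnorm(50 * 8), 50, 8)
#' m <- fitPca(X, k = 2)
#' mean(dmodx(m, X)@dmodx^2)  # == 1 by construction
#' @export
dmodx <- function(model, X, alpha = 0.05, training = TRUE) {
  if (is(X, "FeatureTable")) X <- X@X
  n <- model@n; k <- model@k; p <- model@p
  if (p <= k) stop("degenerate-residual error: p must exceed k")
  Xc <- .preprocess(model, X)
  E <- Xc - (Xc %*% model@loadings) %*% t(model@loadings)
  si <- sqrt(rowSums(E^2) / (p - k))
  s0 <- sqrt(model@residualSsq / ((n - k - 1) * (p - k)))
  cf <- if (training) sqrt(n / (n - k - 1)) else 1
  # a residual that is numerically zero relative to the data scale is an
  # exact fit; without this guard the s_i / s_0 normalisation would blow
  # floating-point noise up to O(1)
  eps <- 1e-8 * sqrt(model@totalSsq / max(1, (n - 1) * p))
  si[si < eps] <- 0
  dm <- if (s0 >= eps) cf * si / s0 else rep(0, length(si))
  dm[si == 0] <- 0
  dcrit <- cf * sqrt(stats::qf(1 - alpha, p - k, (n - k - 1) * (p - k)))
  new("DmodxResult", dmodx = as.numeric(dm), s0 = s0, dcrit = dcrit,
      alpha = alpha)
}

setMethod("show", "DmodxResult", function(object)
  cat(sprintf(
    "DModX over %d observations: mean %.3f, max %.3f; Dcrit(%.0f%%) = %.3f (%d above)\n",
    length(object@dmodx), mean(object@dmodx), max(object@dmodx),
    100 * object@alpha, object@dcrit, sum(object@dmodx > object@dcrit))))

#' Per-component and cumulative explained variance
#'
#' @param model a [PcaModel-class].
#' @return data.frame with columns \code{component}, \code{r2x},
#'   \code{r2xCum}.
#' @export
r2xReport <- function(model) {
  stopifnot(is(model, "PcaModel"))
  data.frame(component = seq_len(model@k), r2x = model@r2x,
             r2xCum = cumsum(model@r2x))
}

#' Persist a PCA model as a JSON + CSV bundle
#'
#' @param model a [PcaModel-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writePcaModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(frame = seq_len(model@n), model@scores),
                   file.path(dir, "scores.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(model@loadings),
                   file.path(dir, "loadings.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(k = model@k, n = model@n, p = model@p, r2x = model@r2x,
         residualSsq = model@residualSsq, totalSsq = model@totalSsq,
         center = model@center, scale = model@scale),
    file.path(dir, "model.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
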