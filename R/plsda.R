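## PCA / PLS-DA profiling and VIP-based differential-metabolite selection.
## Columns are mean-centered and unit-variance scaled before either
## decomposition (the metabonomics default; makes VIP scale-free).

.uvScale <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  zero <- which(sdv == 0)
  if (length(zero))
    stop("constant column(s) cannot be unit-variance scaled: ",
         paste(colnames(X)[zero], collapse = ", "))
  list(X = sweep(sweep(X, 2, mu), 2, sdv, "/"), center = mu, scale = sdv)
}

#' Principal component analysis of a sample table
#'
#' PCA of the mean-centered, unit-variance-scaled RPA matrix.
#'
#' @param cohort a \linkS4class{MetaboCohort}
#' @param n_components number of components, at most min(n - 1, p).
#' @return list with \code{scores} (n x A) and \code{explained_variance}
#'   (fractions, non-increasing).
#' @export
fitPCA <- function(cohort, n_components = 2L) {
  X <- rpaMatrix(cohort)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least 2 samples")
  if (n_components > min(n - 1L, p))
    stop("n_components must be <= min(n - 1, p) = ", min(n - 1L, p))
  sc <- .uvScale(X)
  pc <- stats::prcomp(sc$X, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained_variance = ev[seq_len(n_components)])
}

#' Fit a two-group PLS-DA model
#'
#' Partial least squares regression of a centered binary class indicator
#' (control = 0, case = 1) on the scaled metabolite matrix, extracted by
#' sequential NIPALS deflation with deterministic initialization from the
#' response. With a single response column each component's weight vector
#' has a closed form; the iteration is still run to a relative tolerance of
#' 1e-10 (at most 500 iterations per component).
#'
#' @param cohort a labeled \linkS4class{MetaboCohort}
#' @param comparison character(2): (control group, case group); groups may be
#'   HEALTHY, ELS_MDD, NON_ELS_MDD or the derived union MDD_ALL.
#' @param n_components requested number of latent components (default 2).
#'   When the X or y residual is numerically exhausted first, the model is
#'   returned with fewer components and \code{short_rank = TRUE} plus a
#'   warning.
#' @return a \linkS4class{PLSDAModel}
#' @export
fitPLSDA <- function(cohort, comparison, n_components = 2L) {
  cd <- .comparisonData(cohort, comparison)
  sc <- .uvScale(cd$X)
  X <- sc$X
  y <- cd$y - mean(cd$y)
  n <- nrow(X); p <- ncol(X)
  A <- as.integer(n_components)
  if (A < 1L) stop("n_components must be >= 1")
  W <- matrix(0, p, A); Tm <- matrix(0, n, A); P <- matrix(0, p, A)
  q <- numeric(A); ssy <- numeric(A)
  ss_tot <- sum(y^2)
  if (ss_tot <= 0) stop("degenerate response: only one class present")
  a <- 0L
  Xr <- X; yr <- y
  tol_x <- 1e-12 * sum(X^2)
  while (a < A) {
    if (sum(Xr^2) <= tol_x || sum(yr^2) <= 1e-12 * ss_tot) break
    u <- yr
    w <- crossprod(Xr, u)[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) break
    w <- w / nw
    for (it in seq_len(500L)) {
      tt <- Xr %*% w
      qq <- sum(yr * tt) / sum(tt^2)
      u <- yr * qq            # single-column response: u stays proportional to yr
      w_new <- crossprod(Xr, u)[, 1L]
      w_new <- w_new / sqrt(sum(w_new^2))
      if (sqrt(sum((w_new - w)^2)) < 1e-10) { w <- w_new; break }
      w <- w_new
    }
    tt <- (Xr %*% w)[, 1L]
    tt2 <- sum(tt^2)
    if (tt2 <= 1e-300) break
    qq <- sum(yr * tt) / tt2
    pl <- crossprod(Xr, tt)[, 1L] / tt2
    a <- a + 1L
    W[, a] <- w; Tm[, a] <- tt; P[, a] <- pl; q[a] <- qq
    ssy[a] <- qq^2 * tt2
    Xr <- Xr - tcrossprod(tt, pl)
    yr <- yr - qq * tt
  }
  short <- a < A
  if (short) {
    warning("only ", a, " of ", A, " components extractable; returning ",
            a, "-component model")
    if (a == 0L) stop("no PLS component extractable")
    W <- W[, seq_len(a), drop = FALSE]; Tm <- Tm[, seq_len(a), drop = FALSE]
    P <- P[, seq_len(a), drop = FALSE]; q <- q[seq_len(a)]; ssy <- ssy[seq_len(a)]
  }
  rownames(W) <- rownames(P) <- colnames(X)
  rownames(Tm) <- rownames(cd$X)
  new("PLSDAModel", n_components = a, x_weights = W, x_scores = Tm,
      x_loadings = P, y_loadings = q, y_ss_explained = ssy,
      center = sc$center, scale = sc$scale,
      feature_names = colnames(X), comparison = as.character(comparison),
      short_rank = short)
}

#' Variable importance in projection (VIP)
#'
#' VIP_j = sqrt( p * sum_a[ SSY_a * (w_ja / ||w_a||)^2 ] / sum_a SSY_a ),
#' where SSY_a is component a's explained sum of squares of the class
#' indicator. The scaling makes the mean squared VIP equal 1, so VIP > 1
#' marks an above-average contributor.
#'
#' @param model a fitted \linkS4class{PLSDAModel}
#' @return a \linkS4class{VIPResult}
#' @export
computeVIP <- function(model) {
  stopifnot(is(model, "PLSDAModel"), model@n_components >= 1L)
  ssy <- model@y_ss_explained
  if (sum(ssy) <= 0) stop("degenerate response: all-zero explained SSY")
  W <- model@x_weights
  p <- nrow(W)
  wn2 <- sweep(W, 2, sqrt(colSums(W^2)), "/")^2
  vip <- sqrt(p * as.numeric(wn2 %*% ssy) / sum(ssy))
  new("VIPResult", metabolite_names = model@feature_names, vip = vip)
}

#' Select differential metabolites by VIP threshold
#'
#' Metabolites with VIP strictly above the threshold (the conventional
#' cutoff of 1 by default), ordered by descending VIP. An empty selection is
#' allowed and returns NULL.
#'
#' @param vip a \linkS4class{VIPResult}
#' @param comparison character(2) recorded in the returned panel.
#' @param threshold strict lower VIP bound (default 1.0; ties at the
#'   threshold are excluded).
#' @return a \linkS4class{PanelDefinition} with method "differential", or
#'   NULL when nothing exceeds the threshold.
#' @export
selectDifferential <- function(vip, comparison, threshold = 1.0) {
  stopifnot(is(vip, "VIPResult"))
  keep <- vip@vip > threshold
  if (!any(keep)) return(NULL)
  ord <- order(vip@vip[keep], decreasing = TRUE)
  PanelDefinition(comparison, "differential",
                  vip@metabolite_names[keep][ord])
}
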