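#' Principal coordinates analysis (PCoA)
#'
#' Gower double-centering of the squared distance matrix,
#' `-1/2 J D^2 J`, followed by eigendecomposition. Axes with eigenvalues
#' above `tol * max(eigenvalue)` are returned, scaled by the square root of
#' their eigenvalue so that Euclidean distances among scores reproduce the
#' input distances when the matrix is Euclidean.
#'
#' @param D square symmetric distance matrix, zero diagonal.
#' @param tol relative eigenvalue tolerance (default 1e-8).
#' @return list with `vectors` (n x k score matrix), `values` (positive
#'   eigenvalues), `negative` (sum of negative eigenvalues, diagnostic).
#' @export
pcoa <- function(D, tol = 1e-8) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("need >= 3 objects")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), 1e-300)
  vec <- e$vectors[, keep, drop = FALSE]
  val <- e$values[keep]
  scores <- sweep(vec, 2, sqrt(val), `*`)
  rownames(scores) <- rownames(D)
  list(vectors = scores, values = val,
       negative = sum(e$values[e$values < 0]))
}

# Core RDA statistics of PCoA axes on a centered predictor matrix.
.rda_stats <- function(Yax, Xc) {
  n <- nrow(Yax)
  m <- ncol(Xc)
  qx <- qr(Xc)
  m_eff <- qx$rank
  fitted <- qr.fitted(qx, Yax)
  expl <- sum(fitted^2)
  total <- sum(Yax^2)
  resid <- total - expl
  df2 <- n - m_eff - 1
  r2 <- if (total == 0) 0 else expl / total
  Fv <- if (resid <= 1e-300) Inf else (expl / m_eff) / (resid / df2)
  list(r2 = r2, F = Fv, m = m_eff, df2 = df2)
}

#' Distance-based redundancy analysis (dbRDA)
#'
#' PCoA axes of the response distance matrix (all positive-eigenvalue axes)
#' are regressed on centered per-cell predictors; explained inertia is the
#' trace of the projected variance. `R2 = explained / total positive
#' inertia`; `pseudo-F = (explained/m) / (residual/(n-m-1))`; the p-value
#' permutes predictor rows; adjusted R-squared is Ezekiel's
#' `1 - (1-R2)(n-1)/(n-m-1)`.
#'
#' @param D square symmetric response distance matrix over cells.
#' @param predictors data.frame or matrix of per-cell explanatory variables,
#'   rows matching the cells of `D` (same order).
#' @param n_perm permutations (0 = no p-value).
#' @param seed integer seed.
#' @return object of class `dbrda_fit`: `r2`, `adj_r2`, `F`, `p`,
#'   `predictors`, `n`, `m`.
#' @export
dbrda <- function(D, predictors, n_perm = 10000, seed = 1) {
  D <- as.matrix(D)
  n <- nrow(D)
  X <- as.matrix(predictors)
  if (nrow(X) != n) stop("predictors must be indexed by the same cells")
  m <- ncol(X)
  if (m >= n - 1) stop("too many predictors: m must be < n - 1")
  ax <- pcoa(D)
  Yax <- ax$vectors
  Xc <- scale(X, center = TRUE, scale = FALSE)
  obs <- .rda_stats(Yax, Xc)
  p <- NULL
  if (n_perm > 0) {
    perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      .rda_stats(Yax, Xc[sample(n), , drop = FALSE])$F, 0))
    p <- perm_p(obs$F, perm)
  }
  adj <- 1 - (1 - obs$r2) * (n - 1) / (n - obs$m - 1)
  structure(list(r2 = obs$r2, adj_r2 = adj, F = obs$F, p = p,
                 predictors = colnames(X), n = n, m = obs$m,
                 n_perm = n_perm, eig = ax$values,
                 negative_inertia = ax$negative),
            class = "dbrda_fit")
}

#' @export
print.dbrda_fit <- function(x, ...) {
  if (!length(x$predictors)) {
    cat("dbRDA: null model (no predictors selected)\n")
    return(invisible(x))
  }
  cat(sprintf("dbRDA fit: %s on %d cells\n",
              paste(x$predictors, collapse = " + "), x$n))
  cat(sprintf("  R2 = %.4f (adj %.4f), pseudo-F = %.3f", x$r2, x$adj_r2, x$F))
  if (!is.null(x$p)) cat(sprintf(", perm p = %.4g", x$p))
  cat("\n")
  invisible(x)
}

#' Forward selection of dbRDA predictors
#'
#' The model with all candidates is first tested globally; when its
#' permutation p-value exceeds `alpha` the null model is returned outright
#' (the standard guard against the inflated type-I error of unconditional
#' forward selection). Otherwise selection starts from the empty model; at
#' each step the candidate with the smallest permutation p-value of its
#' marginal pseudo-F given the current model enters if `p <= alpha`, and
#' selection stops when no candidate qualifies.
#'
#' @inheritParams dbrda
#' @param candidates data.frame/matrix of candidate per-cell variables.
#' @param alpha entry threshold (and level of the global gate).
#' @return object of class `dbrda_fit` for the selected model; `selected`
#'   holds the entry order (empty = null model, `r2 = 0`).
#' @export
dbrda_forward_select <- function(D, candidates, alpha = 0.05,
                                 n_perm = 10000, seed = 1) {
  D <- as.matrix(D)
  n <- nrow(D)
  X <- as.matrix(candidates)
  ax <- pcoa(D)
  Yax <- ax$vectors
  Xc <- scale(X, center = TRUE, scale = FALSE)
  selected <- integer(0)
  step <- 0L
  if (ncol(X) < n - 1) {
    glob <- dbrda(D, X, n_perm = n_perm, seed = child_seed(seed, "global"))
    if (is.null(glob$p) || glob$p > alpha)
      return(structure(list(r2 = 0, adj_r2 = 0, F = NA_real_, p = glob$p,
                            predictors = character(0),
                            selected = character(0),
                            n = n, m = 0, n_perm = n_perm,
                            eig = ax$values,
                            negative_inertia = ax$negative),
                       class = "dbrda_fit"))
  }
  repeat {
    step <- step + 1L
    remaining <- setdiff(seq_len(ncol(X)), selected)
    if (!length(remaining) || length(selected) >= n - 2) break
    # marginal F of each candidate given the current model: partial out the
    # current predictors from both response axes and candidate, then test.
    if (length(selected)) {
      qs <- qr(Xc[, selected, drop = FALSE])
      Yr <- qr.resid(qs, Yax)
      Xr <- qr.resid(qs, Xc)
    } else {
      Yr <- Yax
      Xr <- Xc
    }
    ps <- fs <- rep(NA_real_, length(remaining))
    for (ri in seq_along(remaining)) {
      j <- remaining[ri]
      xj <- Xr[, j, drop = FALSE]
      if (sum(xj^2) < 1e-12) { ps[ri] <- 1; fs[ri] <- 0; next }
      st <- .rda_stats(Yr, xj)
      fperm <- with_seed(child_seed(seed, paste0("fw", step, "_", j)),
        vapply(seq_len(n_perm), function(i)
          .rda_stats(Yr, xj[sample(n), , drop = FALSE])$F, 0))
      ps[ri] <- perm_p(st$F, fperm)
      fs[ri] <- st$F
    }
    best <- which.min(ps)
    if (ps[best] > alpha) break
    selected <- c(selected, remaining[best])
  }
  if (!length(selected)) {
    return(structure(list(r2 = 0, adj_r2 = 0, F = NA_real_, p = NA_real_,
                          predictors = character(0), selected = character(0),
                          n = n, m = 0, n_perm = n_perm,
                          eig = ax$values, negative_inertia = ax$negative),
                     class = "dbrda_fit"))
  }
  fit <- dbrda(D, X[, selected, drop = FALSE], n_perm = n_perm,
               seed = child_seed(seed, "final"))
  fit$selected <- colnames(X)[selected]
  fit
}
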