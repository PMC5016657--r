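#' Multiple regression on distance matrices (MRDM)
#'
#' OLS of the vectorized upper triangle of a response distance matrix on the
#' upper triangles of predictor matrices. Significance of R-squared, the
#' overall F and each coefficient comes from `n_perm` joint row/column
#' permutations of the response matrix only (the predictors stay fixed);
#' coefficient p-values compare `|t|`, using the add-one convention
#' `p = (1 + #[perm >= obs]) / (n_perm + 1)`. Predictors are standardized
#' (z-score over pairs) before fitting so coefficients are comparable across
#' models; raw-scale coefficients are also reported.
#'
#' @param Y square symmetric response matrix (genetic distances).
#' @param X named list of square symmetric predictor matrices.
#' @param n_perm number of permutations (0 = estimates only, no p-values).
#' @param seed integer seed.
#' @return object of class `mrdm`: coefficients (standardized and raw), `r2`,
#'   adjusted R-squared, `F`, permutation p-values, residual df.
#' @export
mrdm <- function(Y, X, n_perm = 10000, seed = 1) {
  Y <- as.matrix(Y)
  if (!length(X)) stop("need at least one predictor matrix")
  if (is.null(names(X)) || any(!nzchar(names(X))))
    names(X) <- paste0("X", seq_along(X))
  n <- nrow(Y)
  y <- ut(Y)
  Xm <- vapply(X, function(m) ut(as.matrix(m)), numeric(length(y)))
  Xm <- as.matrix(Xm)
  m <- ncol(Xm)
  if (length(y) < m + 2) stop("need >= 2 more pairs than predictors")
  sds <- apply(Xm, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance predictor: ", paste(names(X)[sds == 0], collapse = ", "))
  Z <- scale(Xm)
  if (m > 1) {
    cn <- kappa(crossprod(cbind(1, Z)), exact = TRUE)
    if (cn > 1e10) {
      cm <- abs(stats::cor(Z))
      diag(cm) <- 0
      worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      stop("collinear predictors: ", names(X)[worst[1]], " and ",
           names(X)[worst[2]])
    }
  }
  Xfull <- cbind(`(Intercept)` = 1, Z)
  qx <- qr(Xfull)
  dXtXi <- pmax(0, diag(chol2inv(qr.R(qx))))
  fit_stats <- function(yv) {
    cf <- qr.coef(qx, yv)
    rss <- sum(qr.resid(qx, yv)^2)
    tss <- sum((yv - mean(yv))^2)
    r2 <- if (tss == 0) 0 else 1 - rss / tss
    df2 <- length(yv) - m - 1
    Fv <- if (rss == 0) Inf else (r2 / m) / ((1 - r2) / df2)
    se <- sqrt(dXtXi * rss / df2)
    tv <- ifelse(se == 0, Inf * sign(cf), cf / se)
    list(coef = cf, r2 = r2, F = Fv, t = tv)
  }
  obs <- fit_stats(y)
  p_r2 <- p_coef <- NULL
  if (n_perm > 0) {
    perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        pp <- sample(n)
        s <- fit_stats(ut(Y[pp, pp]))
        c(s$r2, abs(s$t[-1]))
      }, numeric(1 + m))
    })
    if (m + 1 == 2) perm <- matrix(perm, nrow = 2)
    p_r2 <- perm_p(obs$r2, perm[1, ])
    p_coef <- vapply(seq_len(m), function(j)
      perm_p(abs(obs$t[j + 1]), perm[j + 1, ]), 0)
    names(p_coef) <- names(X)
  }
  raw <- obs$coef
  raw[-1] <- raw[-1] / sds
  raw[1] <- obs$coef[1] - sum(raw[-1] * colMeans(Xm))
  adj <- 1 - (1 - obs$r2) * (length(y) - 1) / (length(y) - m - 1)
  structure(list(coefficients = stats::setNames(obs$coef[-1], names(X)),
                 intercept = obs$coef[1],
                 coefficients_raw = stats::setNames(raw[-1], names(X)),
                 intercept_raw = raw[1],
                 r2 = obs$r2, adj_r2 = adj, F = obs$F,
                 p_r2 = p_r2, p_coef = p_coef,
                 n = n, n_pairs = length(y), n_perm = n_perm,
                 predictors = names(X)),
            class = "mrdm")
}

#' @export
print.mrdm <- function(x, ...) {
  cat(sprintf("MRDM fit: %d predictors on %d pairs (%d labels)\n",
              length(x$predictors), x$n_pairs, x$n))
  cat(sprintf("  R2 = %.4f (adj %.4f), F = %.3f", x$r2, x$adj_r2, x$F))
  if (!is.null(x$p_r2)) cat(sprintf(", perm p = %.4g", x$p_r2))
  cat("\n")
  tab <- data.frame(coef = x$coefficients,
                    raw = x$coefficients_raw)
  if (!is.null(x$p_coef)) tab$p <- x$p_coef
  print(tab)
  invisible(x)
}

#' @export
coef.mrdm <- function(object, raw = FALSE, ...) {
  if (raw) object$coefficients_raw else object$coefficients
}

#' Backward elimination of MRDM predictors
#'
#' The full candidate model is first tested globally (permutation p of its
#' R-squared); when that test is not significant at `alpha` the empty model
#' is returned outright, which keeps the selection's type-I error at the
#' nominal level instead of the inflated rate of unconditional stepwise
#' search. Otherwise predictors are repeatedly dropped - largest permutation
#' p-value above `alpha` first - and the model refit until every retained
#' predictor satisfies `p <= alpha`. The resistance-distance predictor
#' competes like any other; the final model may still end empty.
#'
#' @inheritParams mrdm
#' @param alpha retention threshold on coefficient permutation p-values (and
#'   the level of the global gate).
#' @return object of class `mrdm` for the reduced model, with `dropped`
#'   listing eliminated predictors in drop order; an empty final model is an
#'   `mrdm` with zero predictors (`r2 = 0`).
#' @export
mrdm_reduce <- function(Y, X, alpha = 0.05, n_perm = 10000, seed = 1) {
  dropped <- character(0)
  cur <- X
  step <- 0L
  global_ok <- FALSE
  while (length(cur)) {
    step <- step + 1L
    fit <- mrdm(Y, cur, n_perm = n_perm, seed = child_seed(seed, paste0("s", step)))
    if (step == 1L) {
      global_ok <- !is.null(fit$p_r2) && fit$p_r2 <= alpha
      if (!global_ok) { dropped <- names(cur); cur <- list(); break }
    }
    worst <- which.max(fit$p_coef)
    if (fit$p_coef[worst] <= alpha) {
      fit$dropped <- dropped
      return(fit)
    }
    dropped <- c(dropped, names(cur)[worst])
    cur <- cur[-worst]
  }
  structure(list(coefficients = numeric(0), coefficients_raw = numeric(0),
                 intercept = mean(ut(as.matrix(Y))), intercept_raw = NA,
                 r2 = 0, adj_r2 = 0, F = NA_real_, p_r2 = NA_real_,
                 p_coef = numeric(0), n = nrow(as.matrix(Y)),
                 n_pairs = length(ut(as.matrix(Y))), n_perm = n_perm,
                 predictors = character(0), dropped = dropped),
            class = "mrdm")
}

#' Cell-pair predictor matrix from a per-cell metric
#'
#' MRDM needs pairwise predictors; a within-cell complexity metric is lifted
#' to pairs as the arithmetic mean of the two cells' values (default) or the
#' absolute difference.
#'
#' @param values named numeric vector over cells.
#' @param mode `"mean"` (default) or `"absdiff"`.
#' @return symmetric matrix with zero diagonal.
#' @export
pairwise_metric <- function(values, mode = c("mean", "absdiff")) {
  mode <- match.arg(mode)
  v <- as.numeric(values)
  m <- if (mode == "mean") outer(v, v, `+`) / 2 else abs(outer(v, v, `-`))
  diag(m) <- 0
  dimnames(m) <- list(names(values), names(values))
  m
}
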