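#' Bootstrap confidence intervals for reduced MRDM and dbRDA models
#'
#' Resamples individuals with replacement within each study cell (cell sizes
#' preserved), recomputes the genetic differentiation matrix, and refits the
#' supplied reduced models on every replicate. By default the reduced-model
#' structure is fixed from the point estimate and only coefficients / fit
#' statistics are re-estimated per replicate; `reselect = TRUE` re-runs
#' variable selection inside each replicate instead.
#'
#' @param d a [genotype_dataset()].
#' @param measure `"fst"` or `"jost"` - the response recomputed per replicate.
#' @param mrdm_X named list of predictor matrices (candidates); `mrdm_vars`
#'   names the retained structure refit per replicate (may be empty).
#' @param dbrda_X per-cell predictor data.frame (candidates); `dbrda_vars`
#'   names the retained structure (may be empty).
#' @param n_boot bootstrap replicates (reference analysis: 1000).
#' @param seed integer seed.
#' @param reselect rerun `mrdm_reduce` / `dbrda_forward_select` per
#'   replicate (slower; off by default).
#' @param alpha,n_perm selection parameters used only when `reselect`.
#' @param max_fail_frac abort when more than this fraction of replicates
#'   fails (default 0.05).
#' @return list with components `mrdm` and `dbrda`, each holding `mean`,
#'   `ci` (2.5/97.5 percentiles) for F, R2, adjusted R2 (and MRDM
#'   coefficients); `n_fail`; `degenerate` flag for zero-width intervals;
#'   `draws` matrices of per-replicate values.
#' @export
bootstrap_models <- function(d, measure = c("fst", "jost"),
                             mrdm_X = NULL, mrdm_vars = NULL,
                             dbrda_X = NULL, dbrda_vars = NULL,
                             n_boot = 1000, seed = 1, reselect = FALSE,
                             alpha = 0.05, n_perm = 999,
                             max_fail_frac = 0.05) {
  measure <- match.arg(measure)
  cells <- sort(unique(d$cell))
  if (any(table(d$cell) < 2)) stop("every cell needs >= 2 individuals")
  dt <- dosage_tables(d)
  by_cell <- split(seq_along(d$cell), d$cell)[cells]
  do_mrdm <- !is.null(mrdm_X) && (reselect || length(mrdm_vars))
  do_db <- !is.null(dbrda_X) && (reselect || length(dbrda_vars))
  one_rep <- function(b) {
    idx <- unlist(lapply(by_cell, function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]))
    Dm <- diff_matrix_from_tables(dt, d$cell, idx, measure)
    out <- list()
    if (do_mrdm) {
      fit <- if (reselect)
        mrdm_reduce(Dm, mrdm_X, alpha = alpha, n_perm = n_perm,
                    seed = seed + b)
      else if (length(mrdm_vars))
        mrdm(Dm, mrdm_X[mrdm_vars], n_perm = 0)
      out$mrdm <- c(F = if (length(fit$predictors)) fit$F else NA_real_,
                    r2 = fit$r2, adj_r2 = fit$adj_r2,
                    stats::setNames(fit$coefficients, paste0("b_", fit$predictors)))
    }
    if (do_db) {
      fit <- if (reselect)
        dbrda_forward_select(Dm, dbrda_X, alpha = alpha, n_perm = n_perm,
                             seed = seed + b)
      else
        dbrda(Dm, dbrda_X[, dbrda_vars, drop = FALSE], n_perm = 0)
      out$dbrda <- c(F = fit$F, r2 = fit$r2, adj_r2 = fit$adj_r2)
    }
    out
  }
  draws_m <- list(); draws_d <- list()
  n_fail <- 0L
  with_seed(child_seed(seed, "boot"), {
    for (b in seq_len(n_boot)) {
      rep_b <- tryCatch(one_rep(b), error = function(e) NULL)
      if (is.null(rep_b)) { n_fail <- n_fail + 1L; next }
      if (do_mrdm) draws_m[[length(draws_m) + 1L]] <- rep_b$mrdm
      if (do_db) draws_d[[length(draws_d) + 1L]] <- rep_b$dbrda
    }
  })
  if (n_fail > max_fail_frac * n_boot)
    stop(n_fail, " of ", n_boot, " bootstrap replicates failed")
  summarize <- function(draws) {
    if (!length(draws)) return(NULL)
    M <- do.call(rbind, draws)
    ci <- apply(M, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    wid <- ci[2, ] - ci[1, ]
    list(mean = colMeans(M, na.rm = TRUE), ci = ci,
         degenerate = all(wid[is.finite(wid)] == 0), draws = M)
  }
  list(mrdm = summarize(draws_m), dbrda = summarize(draws_d),
       n_fail = n_fail, n_boot = n_boot)
}

#' Compare resistance-surface models by adjusted-R2 confidence intervals
#'
#' The winner is the surface with the largest point adjusted R-squared. A
#' non-null surface is `distinct` when its bootstrap CI overlaps neither the
#' IBD nor the IBB null-surface CI (the strong-evidence rule); otherwise
#' `overlapping`. Surfaces whose CI overlaps the winner's are additionally
#' flagged `competing`.
#'
#' @param fits data.frame with columns `surface`, `adj_r2`, `ci_low`,
#'   `ci_high`; must contain rows for `IBD` and `IBB`.
#' @return data.frame with added `relation`, `winner`, `competing` columns.
#' @export
compare_surfaces <- function(fits) {
  need <- c("surface", "adj_r2", "ci_low", "ci_high")
  stopifnot(all(need %in% names(fits)))
  if (anyNA(fits$ci_low) || anyNA(fits$ci_high))
    stop("missing CI for at least one surface")
  if (!all(c("IBD", "IBB") %in% fits$surface))
    stop("fits must include the IBD and IBB null surfaces")
  overlap <- function(a, b) fits$ci_low[a] <= fits$ci_high[b] &
    fits$ci_low[b] <= fits$ci_high[a]
  nulls <- match(c("IBD", "IBB"), fits$surface)
  win <- which.max(fits$adj_r2)
  fits$relation <- vapply(seq_len(nrow(fits)), function(i) {
    if (i %in% nulls) return("null")
    if (!overlap(i, nulls[1]) && !overlap(i, nulls[2])) "distinct"
    else "overlapping"
  }, "")
  fits$winner <- seq_len(nrow(fits)) == win
  fits$competing <- vapply(seq_len(nrow(fits)), function(i)
    i != win && overlap(i, win), logical(1))
  fits
}
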