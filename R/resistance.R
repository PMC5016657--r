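#' Surface hypothesis: a per-class resistance map
#'
#' A named resistance hypothesis mapping every land-cover class code to a
#' resistance value >= 1 (or `Inf` = impassable). The two null hypotheses are
#' built in: `"IBD"` (all pixels 1: distance alone) and `"IBB"` (open water
#' 500, everything else 1: distance plus a water barrier). Parameterized
#' surfaces keep forest at resistance 1 and scale other classes by
#' movement/mortality factors.
#'
#' @param name hypothesis label.
#' @param resistance named numeric vector: names are class codes (as
#'   character) or class names matching [landcover_classes()], values >= 1.
#' @return object of class `surface_hypothesis`.
#' @export
surface_hypothesis <- function(name, resistance) {
  if (!is.null(names(resistance))) {
    cls <- landcover_classes()
    nm <- names(resistance)
    named <- nm %in% names(cls)
    nm[named] <- as.character(cls[nm[named]])
    names(resistance) <- nm
  }
  stopifnot(all(resistance >= 1))
  structure(list(name = name, resistance = resistance),
            class = "surface_hypothesis")
}

#' Read surface hypothesis parameter tables from CSV
#'
#' One CSV per hypothesis with columns `class` (code or class name) and
#' `resistance`.
#'
#' @param path CSV path.
#' @param name hypothesis label (default: file name sans extension).
#' @return a [surface_hypothesis()].
#' @export
read_surface_params <- function(path, name = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("class", "resistance") %in% names(df)))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  surface_hypothesis(name, stats::setNames(df$resistance,
                                           as.character(df$class)))
}

#' Build a resistance surface from a land-cover raster
#'
#' Pixel-wise lookup of per-class resistance. `hyp = "IBD"` returns a
#' constant-1 surface; `hyp = "IBB"` assigns 500 to water pixels and 1
#' elsewhere; any other hypothesis must map every class present.
#'
#' @param landcover a [land_raster()] of integer class codes.
#' @param hyp a [surface_hypothesis()], or `"IBD"` / `"IBB"`.
#' @return a [land_raster()] of resistances (class `resistance_surface`
#'   prepended), with attributes `hypothesis` and `params_hash`.
#' @export
build_resistance_surface <- function(landcover, hyp) {
  if (is.character(hyp)) {
    cls <- landcover_classes()
    hyp <- switch(hyp,
      IBD = {
        codes <- sort(unique(stats::na.omit(as.vector(landcover$values))))
        surface_hypothesis("IBD", stats::setNames(rep(1, length(codes)),
                                                  as.character(codes)))
      },
      IBB = {
        codes <- sort(unique(stats::na.omit(as.vector(landcover$values))))
        rv <- stats::setNames(rep(1, length(codes)), as.character(codes))
        rv[as.character(cls["water"])] <- 500
        surface_hypothesis("IBB", rv)
      },
      stop("unknown built-in hypothesis: ", hyp))
  }
  codes <- sort(unique(stats::na.omit(as.vector(landcover$values))))
  unmapped <- setdiff(as.character(codes), names(hyp$resistance))
  if (length(unmapped))
    stop("unmapped land-cover codes: ", paste(unmapped, collapse = ", "))
  v <- landcover$values
  out <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v)
  out[ok] <- hyp$resistance[as.character(v[ok])]
  r <- land_raster(out, landcover$cell_size, landcover$xll, landcover$yll)
  class(r) <- c("resistance_surface", class(r))
  attr(r, "hypothesis") <- hyp$name
  attr(r, "params_hash") <- sum(hyp$resistance[is.finite(hyp$resistance)]^2)
  r
}

# Sparse graph Laplacian over the raster's finite pixels. Edge conductance
# between adjacent pixels i,j = 1 / (0.5 * (r_i + r_j) * w) with w = 1 for
# cardinal and sqrt(2) for diagonal neighbours (geometric length weighting).
# Infinite-resistance and nodata pixels are excluded from the graph.
.raster_laplacian <- function(surface, neighbors = 8) {
  stopifnot(neighbors %in% c(4, 8))
  v <- surface$values
  nr <- nrow(v); ncl <- ncol(v)
  keep <- is.finite(v)
  id <- matrix(NA_integer_, nr, ncl)
  id[keep] <- seq_len(sum(keep))
  offs <- list(c(0, 1, 1), c(1, 0, 1))
  if (neighbors == 8)
    offs <- c(offs, list(c(1, 1, sqrt(2)), c(1, -1, sqrt(2))))
  ii <- jj <- integer(0); ww <- numeric(0)
  for (o in offs) {
    dr <- o[1]; dc <- o[2]; w <- o[3]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(ncl - dc) else seq(1 - dc, ncl)
    A <- id[r1, c1, drop = FALSE]
    B <- id[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(A) & !is.na(B)
    if (!any(ok)) next
    ra <- v[r1, c1, drop = FALSE][ok]
    rb <- v[r1 + dr, c1 + dc, drop = FALSE][ok]
    ii <- c(ii, A[ok]); jj <- c(jj, B[ok])
    ww <- c(ww, 1 / (0.5 * (ra + rb) * w))
  }
  nnode <- sum(keep)
  Wm <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                             dims = c(nnode, nnode))
  L <- Matrix::Diagonal(x = Matrix::rowSums(Wm)) - Wm
  list(L = L, id = id, n = nnode, edges = cbind(ii, jj))
}

#' Circuit-theory effective resistance between study-cell focal points
#'
#' Builds a conductance graph over all finite pixels of the resistance
#' surface (8-neighbour by default, diagonal edges down-weighted by sqrt(2)
#' for geometric length) and computes the pairwise effective resistance
#' between the pixels containing each cell's focal coordinate via sparse
#' Cholesky solves of the grounded graph Laplacian. Integrates all pathways,
#' not a single least-cost route.
#'
#' @param surface a resistance surface ([build_resistance_surface()]).
#' @param focal data.frame with columns `cell`, `x`, `y` (focal coordinates
#'   in world units).
#' @param neighbors 8 (default) or 4.
#' @return a `dist_matrix` of kind `"resistance"`; a disconnected pair is
#'   `Inf` with a warning.
#' @export
resistance_distance <- function(surface, focal, neighbors = 8) {
  g <- .raster_laplacian(surface, neighbors)
  px <- world_to_pixel(surface, focal$x, focal$y)
  if (anyNA(px)) stop("focal points outside raster extent")
  nodes <- g$id[px]
  if (anyNA(nodes)) stop("focal points fall on nodata/impassable pixels")
  k <- length(nodes)
  gr <- igraph::make_graph(t(g$edges), n = g$n, directed = FALSE)
  memb <- igraph::components(gr)$membership
  D <- matrix(Inf, k, k, dimnames = list(focal$cell, focal$cell))
  diag(D) <- 0
  # per connected component: ground the first focal node, solve the reduced
  # Laplacian for the others; R_ij = S_ii + S_jj - 2 S_ij with S the reduced
  # inverse restricted to focal nodes (grounded node row/col = 0).
  for (cm in unique(memb[nodes])) {
    f_idx <- which(memb[nodes] == cm)
    if (length(f_idx) < 2) next
    cnodes <- which(memb == cm)
    sub <- match(nodes[f_idx], cnodes)
    Lc <- g$L[cnodes, cnodes, drop = FALSE]
    others <- setdiff(seq_along(cnodes), sub[1])
    pos <- match(sub[-1], others)
    rhs <- Matrix::sparseMatrix(i = pos, j = seq_along(pos), x = 1,
                                dims = c(length(others), length(pos)))
    sol <- as.matrix(Matrix::solve(Lc[others, others, drop = FALSE], rhs))
    S <- matrix(0, length(f_idx), length(f_idx))
    S[-1, -1] <- sol[pos, , drop = FALSE]
    for (a in seq_along(f_idx)) for (b in seq_along(f_idx)) {
      if (a < b)
        D[f_idx[a], f_idx[b]] <- D[f_idx[b], f_idx[a]] <-
          S[a, a] + S[b, b] - 2 * S[a, b]
    }
  }
  if (any(!is.finite(D[upper.tri(D)])))
    warning("disconnected focal pairs: infinite resistance entries")
  dist_matrix(D, "resistance")
}

#' Connectivity index from a resistance-distance matrix
#'
#' `S_i = sum_{j != i} exp(-alpha * d_ij)`: per-cell accessibility with
#' exponential distance decay; `alpha` plays the role of an inverse mean
#' dispersal distance on the resistance scale. Infinite distances contribute
#' zero. With `alpha = NULL` the default `1 / median(off-diagonal d)` is
#' used and recorded in the result's attributes.
#'
#' @param D a `dist_matrix` of kind `"resistance"` (any symmetric distance
#'   matrix is accepted).
#' @param alpha non-negative decay scalar, or `NULL` for the median rule.
#' @return named numeric vector of per-cell indices, attribute `alpha`.
#' @export
connectivity_index <- function(D, alpha = NULL) {
  D <- as.matrix(D)
  off <- D[row(D) != col(D)]
  if (is.null(alpha)) {
    med <- stats::median(off[is.finite(off)])
    alpha <- if (is.finite(med) && med > 0) 1 / med else 0
  }
  if (alpha < 0) stop("alpha must be non-negative")
  E <- exp(-alpha * D)
  E[!is.finite(D)] <- 0
  diag(E) <- 0
  s <- rowSums(E)
  names(s) <- rownames(D)
  attr(s, "alpha") <- alpha
  s
}
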