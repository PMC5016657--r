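# Within-cell landscape pattern metrics: proportion of focal class, patch
# density, and the CLUMPY aggregation index. Metrics are computed on a
# clipped study-cell raster (cell extent plus buffer); buffer pixels count.

#' Clip a raster to a square window around a focal point
#'
#' @param r a [land_raster()].
#' @param x,y focal world coordinates.
#' @param half_width_m half the window edge, in metres (study-cell half-size
#'   plus buffer; the reference design is a 23 km^2 cell with a 1.6 km
#'   buffer).
#' @return a [land_raster()] clipped to the window intersected with `r`.
#' @export
clip_raster <- function(r, x, y, half_width_m) {
  cs <- r$cell_size
  px <- world_to_pixel(r, x, y)
  if (anyNA(px)) stop("focal point outside raster")
  hw <- ceiling(half_width_m / cs)
  r1 <- max(1, px[1] - hw); r2 <- min(nrow(r$values), px[1] + hw)
  c1 <- max(1, px[2] - hw); c2 <- min(ncol(r$values), px[2] + hw)
  land_raster(r$values[r1:r2, c1:c2, drop = FALSE], cs,
              r$xll + (c1 - 1) * cs,
              r$yll + (nrow(r$values) - r2) * cs)
}

#' Proportion of a focal class
#'
#' Focal-class pixels divided by all non-nodata pixels.
#'
#' @param r a [land_raster()] of class codes.
#' @param class_code focal class (default: forest).
#' @return fraction in \[0, 1\].
#' @export
proportion_class <- function(r, class_code = landcover_classes()["forest"]) {
  v <- r$values
  ok <- !is.na(v)
  if (!any(ok)) stop("all-nodata raster")
  sum(v[ok] == class_code) / sum(ok)
}

# Connected-component labeling of a logical matrix under the 4- or
# 8-neighbour rule (iterative flood fill, no recursion).
.label_patches <- function(mask, rule = 8) {
  nr <- nrow(mask); ncl <- ncol(mask)
  lab <- matrix(0L, nr, ncl)
  cur <- 0L
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (rule == 8)
    offs <- rbind(offs, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  todo <- which(mask & lab == 0L)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pr <- (p - 1L) %% nr + 1L
      pc <- (p - 1L) %/% nr + 1L
      for (o in seq_len(nrow(offs))) {
        qr <- pr + offs[o, 1]; qc <- pc + offs[o, 2]
        if (qr < 1 || qr > nr || qc < 1 || qc > ncl) next
        q <- (qc - 1L) * nr + qr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          stack <- c(stack, q)
        }
      }
    }
  }
  list(labels = lab, n = cur)
}

#' Patch density of a focal class
#'
#' Connected components of focal-class pixels (8-neighbour rule by default,
#' so diagonally touching blocks merge) divided by the landscape area,
#' expressed as patches per 100 ha.
#'
#' @param r a [land_raster()] of class codes.
#' @param class_code focal class (default forest).
#' @param rule 8 (default) or 4.
#' @return patches per 100 hectares (0 when the class is absent).
#' @export
patch_density <- function(r, class_code = landcover_classes()["forest"],
                          rule = 8) {
  mask <- !is.na(r$values) & r$values == class_code
  n_patch <- .label_patches(mask, rule)$n
  area_ha <- sum(!is.na(r$values)) * r$cell_size^2 / 1e4
  100 * n_patch / area_ha
}

#' CLUMPY aggregation index of a focal class
#'
#' FRAGSTATS-style clumpiness: from the double-count rook (4-neighbour)
#' adjacency table of the focal class, `G = g_ii / (sum_k g_ik - min_e)`
#' where `g_ik` counts adjacencies between the class and class `k`
#' (landscape-boundary segments excluded) and `min_e` is the class-edge
#' correction applied when the class proportion `P >= 0.5`. Then
#' `CLUMPY = (G - P) / (1 - P)`, except `(G - P) / P` when `G < P` and
#' `P < 0.5`. Values span -1 (maximally disaggregated, e.g. a checkerboard
#' at P = 0.5) to +1 (a single compact clump).
#'
#' @param r a [land_raster()] of class codes.
#' @param class_code focal class (default forest).
#' @return index in \[-1, 1\]; `NA` with a warning when the class is absent.
#' @export
clumpy <- function(r, class_code = landcover_classes()["forest"]) {
  v <- r$values
  ok <- !is.na(v)
  if (!any(ok)) stop("all-nodata raster")
  mask <- ok & v == class_code
  P <- sum(mask) / sum(ok)
  if (P == 0) {
    warning("focal class absent: CLUMPY undefined")
    return(NA_real_)
  }
  if (P == 1) return(1)
  # double-count rook adjacencies among non-nodata pixels
  # (landscape-boundary segments excluded: only interior pixel pairs count)
  gii <- 0; gik <- 0
  H <- list(v[, -ncol(v), drop = FALSE], v[, -1, drop = FALSE])
  V <- list(v[-nrow(v), , drop = FALSE], v[-1, , drop = FALSE])
  for (pp in list(H, V)) {
    A <- pp[[1]]; B <- pp[[2]]
    okp <- !is.na(A) & !is.na(B)
    gii <- gii + 2 * sum(okp & A == class_code & B == class_code)
    gik <- gik + sum(okp & A == class_code) + sum(okp & B == class_code)
  }
  # min-edge correction: the perimeter (in cell edges) a maximally compact
  # clump of a pixels cannot avoid; subtracted from the denominator so a
  # single square block attains G = 1.
  a <- sum(mask)
  nside <- floor(sqrt(a))
  m <- a - nside^2
  min_e <- if (m == 0) 4 * nside
  else if (m <= nside) 4 * nside + 2
  else 4 * nside + 4
  denom <- gik - min_e
  G <- if (denom <= 0) { if (gii > 0) 1 else 0 } else gii / denom
  G <- min(1, G)
  val <- if (G < P && P < 0.5) (G - P) / P else (G - P) / (1 - P)
  max(-1, min(1, val))
}

#' Pattern-metric table over study cells
#'
#' Clips the land-cover raster around each study cell's focal point (cell
#' half-width plus buffer) and computes `prFor`, `PD` and `Clumpy` of the
#' focal class.
#'
#' @param landcover a [land_raster()] of class codes.
#' @param cells data.frame with `cell`, `x`, `y`.
#' @param half_width_m clip half-width in metres (default 2398: half of a
#'   23 km^2 square cell, ~2398 m when buffered below; supply
#'   `sqrt(23e6)/2 + 1600` for the reference design).
#' @param class_code focal class (default forest).
#' @return data.frame: `cell`, `prFor`, `PD`, `Clumpy`.
#' @export
complexity_metrics <- function(landcover, cells,
                               half_width_m = sqrt(23e6) / 2 + 1600,
                               class_code = landcover_classes()["forest"]) {
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cl <- clip_raster(landcover, cells$x[i], cells$y[i], half_width_m)
    data.frame(cell = as.character(cells$cell[i]),
               prFor = proportion_class(cl, class_code),
               PD = patch_density(cl, class_code),
               Clumpy = suppressWarnings(clumpy(cl, class_code)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
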