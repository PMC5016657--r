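surfaceify <- function(values, cell_size = 1) {
  r <- land_raster(values, cell_size, 0, 0)
  class(r) <- c("resistance_surface", class(r))
  r
}

test_that("ESRI ASCII grids round-trip including nodata", {
  withr::with_seed(2, {
    v <- matrix(sample(c(1:6, NA), 48, TRUE), 6, 8)
    r <- land_raster(v, 30, 1000, 2000)
    f <- tempfile(fileext = ".asc")
    write_ascii_grid(r, f)
    r2 <- read_ascii_grid(f)
    expect_equal(r2$values, v)
    expect_equal(r2$cell_size, 30)
    expect_equal(r2$xll, 1000)
    expect_equal(r2$yll, 2000)
  })
})

test_that("world/pixel mapping uses half-pixel-center registration", {
  r <- land_raster(matrix(0, 4, 5), 10, 100, 200)
  # centre of top-left pixel: x = 105, y = 200 + 3.5*10 = 235
  w <- pixel_to_world(r, 1, 1)
  expect_equal(unname(w), cbind(105, 235))
  px <- world_to_pixel(r, 105, 235)
  expect_equal(unname(px), cbind(1, 1))
  # round-trip for every pixel
  g <- expand.grid(row = 1:4, col = 1:5)
  w2 <- pixel_to_world(r, g$row, g$col)
  px2 <- world_to_pixel(r, w2[, 1], w2[, 2])
  expect_equal(unname(px2), unname(as.matrix(g)))
  expect_true(all(is.na(world_to_pixel(r, -5, 0))))
})

test_that("resistance surfaces follow their hypothesis tables", {
  cls <- landcover_classes()
  v <- matrix(cls[c("forest", "water", "agriculture", "wetland")], 2, 2)
  land <- land_raster(v, 30, 0, 0)
  ibd <- build_resistance_surface(land, "IBD")
  expect_true(all(ibd$values == 1))
  ibb <- build_resistance_surface(land, "IBB")
  expect_equal(ibb$values[v == cls["water"]], 500)
  expect_true(all(ibb$values[v != cls["water"]] == 1))
  # movement surface: wetland five times forest
  mv <- build_resistance_surface(land, default_hypotheses()$MoveL)
  expect_equal(unique(mv$values[v == cls["wetland"]]), 5)
  expect_equal(unique(mv$values[v == cls["forest"]]), 1)
  # unmapped code errors with the code listed
  bad <- surface_hypothesis("partial", c(forest = 1))
  expect_error(build_resistance_surface(land, bad), "unmapped.*codes")
})

test_that("series and parallel resistor laws hold exactly", {
  r3 <- surfaceify(matrix(1, 1, 3))
  D <- resistance_distance(r3, data.frame(cell = c("a", "b"),
                                          x = c(0.5, 2.5), y = c(0.5, 0.5)),
                           neighbors = 4)
  expect_equal(D["a", "b"], 2)
  r22 <- surfaceify(matrix(1, 2, 2))
  D2 <- resistance_distance(r22, data.frame(cell = c("a", "b"),
                                            x = c(0.5, 1.5), y = c(1.5, 0.5)),
                            neighbors = 4)
  expect_equal(D2["a", "b"], 1)
})

test_that("sparse solves match the dense pseudoinverse oracle", {
  for (s in 1:5) {
    withr::with_seed(800 + s, {
      nr <- sample(3:6, 1); nc <- sample(3:6, 1)
      v <- matrix(runif(nr * nc, 1, 10), nr, nc)
      surf <- surfaceify(v)
      focal <- data.frame(cell = c("a", "b", "c"),
                          x = c(0.5, nc - 0.5, floor(nc / 2) + 0.5),
                          y = c(nr - 0.5, 0.5, floor(nr / 2) + 0.5))
      D <- resistance_distance(surf, focal, neighbors = 8)
      oracle <- resistance_oracle(v, neighbors = 8)
      px <- world_to_pixel(surf, focal$x, focal$y)
      for (i in 1:2) for (j in (i + 1):3) {
        expect_equal(D[i, j],
                     oracle(px[i, 1], px[i, 2], px[j, 1], px[j, 2]),
                     tolerance = 1e-8)
      }
    })
  }
})

test_that("effective resistance behaves as a metric with Rayleigh monotonicity", {
  withr::with_seed(77, {
    v <- matrix(runif(25, 1, 5), 5, 5)
    surf <- surfaceify(v)
    focal <- data.frame(cell = c("a", "b", "c"),
                        x = c(0.5, 4.5, 2.5), y = c(0.5, 4.5, 0.5))
    D <- resistance_distance(surf, focal)
    expect_true(all(D >= 0))
    expect_equal(unname(D), unname(t(D)))
    expect_lte(D["a", "b"], D["a", "c"] + D["c", "b"] + 1e-12)
    # raising one pixel's resistance cannot decrease any distance
    v2 <- v; v2[3, 3] <- v2[3, 3] * 10
    D2 <- resistance_distance(surfaceify(v2), focal)
    expect_true(all(D2 - D >= -1e-9))
    # scaling the surface scales every distance
    Dk <- resistance_distance(surfaceify(3 * v), focal)
    expect_equal(unname(Dk), unname(3 * D), tolerance = 1e-9)
    # more neighbours = more parallel paths = smaller distances
    D4 <- resistance_distance(surf, focal, neighbors = 4)
    expect_true(all(D[upper.tri(D)] <= D4[upper.tri(D4)] + 1e-12))
  })
})

test_that("disconnected components yield infinite distances with a warning", {
  v <- matrix(1, 3, 3)
  v[, 2] <- NA                         # nodata wall
  surf <- surfaceify(v)
  focal <- data.frame(cell = c("a", "b"), x = c(0.5, 2.5), y = c(1.5, 1.5))
  expect_warning(D <- resistance_distance(surf, focal), "disconnected")
  expect_identical(D["a", "b"], Inf)
})

test_that("connectivity index sums exponentially decayed distances", {
  D2 <- dist_matrix(matrix(c(0, 1, 1, 0), 2, 2,
                           dimnames = list(c("a", "b"), c("a", "b"))),
                    "resistance")
  s <- connectivity_index(D2, alpha = 1)
  expect_equal(unname(s), rep(exp(-1), 2), ignore_attr = TRUE)
  # alpha = 0 counts the other cells
  expect_equal(unname(connectivity_index(D2, alpha = 0)), c(1, 1), ignore_attr = TRUE)
  # hand sums on three cells
  D3 <- matrix(0, 3, 3); D3[1, 2] <- D3[2, 1] <- 1
  D3[1, 3] <- D3[3, 1] <- 2; D3[2, 3] <- D3[3, 2] <- 3
  dimnames(D3) <- list(letters[1:3], letters[1:3])
  s3 <- connectivity_index(dist_matrix(D3, "resistance"), alpha = 0.5)
  expect_equal(unname(s3[1]), exp(-0.5) + exp(-1))
  expect_equal(unname(s3[2]), exp(-0.5) + exp(-1.5))
  expect_equal(unname(s3[3]), exp(-1) + exp(-1.5))
  # strictly decreasing in any d_ij for alpha > 0; Inf contributes 0
  D3b <- D3; D3b[1, 2] <- D3b[2, 1] <- 1.5
  s3b <- connectivity_index(dist_matrix(D3b, "resistance"), alpha = 0.5)
  expect_lt(s3b[1], s3[1])
  D3c <- D3; D3c[1, 2] <- D3c[2, 1] <- Inf
  s3c <- connectivity_index(dist_matrix(D3c, "resistance"), alpha = 0.5)
  expect_equal(unname(s3c[1]), exp(-1))
  expect_error(connectivity_index(D3, alpha = -1), "non-negative")
})
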