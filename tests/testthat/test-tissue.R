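# Tissue construction: fibrosis generators, ACh patch placement, diffusion.

test_that("uniform fibrosis matches the requested density and seed", {
  expect_true(all(uniform_fibrosis(40, 40, 0, seed = 1) == 0L))
  lab <- uniform_fibrosis(251, 251, 0.2, seed = 7)
  n <- length(lab)
  frac <- mean(lab)
  sigma <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(frac - 0.2), 3 * sigma)
  expect_identical(lab, uniform_fibrosis(251, 251, 0.2, seed = 7))
  expect_false(identical(lab, uniform_fibrosis(251, 251, 0.2, seed = 8)))
  expect_error(uniform_fibrosis(10, 10, 1.2), "density")
})

test_that("density estimator is unbiased across seeds", {
  fr <- vapply(1:100, function(s)
    mean(uniform_fibrosis(63, 63, 0.2, seed = s)), numeric(1))
  expect_lt(abs(mean(fr) - 0.2), 0.005)
})

test_that("patchy fibrosis confines fibroblasts to the circles", {
  nx <- ny <- 101; dx <- 0.02
  patches <- tibble::tibble(x = 1, y = 1, r = 0.5)
  lab <- patchy_fibrosis(nx, ny, dx, patches, 0.2, seed = 3)
  xg <- (seq_len(nx) - 1) * dx; yg <- (seq_len(ny) - 1) * dx
  inside <- outer(yg, xg, function(y, x) sqrt((x - 1)^2 + (y - 1)^2) <= 0.5)
  expect_true(all(lab[!inside] == 0L))
  expect_lt(abs(mean(lab[inside]) - 0.2), 3 * sqrt(0.2 * 0.8 / sum(inside)))
  # node exactly on the boundary counts as inside (<= r convention);
  # dx = 0.25 keeps all coordinates exactly representable
  patches2 <- tibble::tibble(x = 0.5, y = 1, r = 0.5)
  lab2 <- patchy_fibrosis(9, 9, 0.25, patches2, 1, seed = 1)
  expect_identical(lab2[5, 5], 1L)   # node (1, 1): distance exactly r
  # a circle covering the whole tissue behaves like uniform fibrosis
  big <- patchy_fibrosis(63, 63, 0.04, tibble::tibble(x = 1.24, y = 1.24, r = 5),
                         0.4, seed = 2)
  expect_lt(abs(mean(big) - 0.4), 3 * sqrt(0.4 * 0.6 / length(big)))
  expect_error(patchy_fibrosis(10, 10, 0.02, NULL, 0.2), "patch")
})

test_that("ACh patches rasterize to the registered geometry", {
  tis <- tissue_model(nx = 101, ny = 101, dx = 0.02)
  expect_true(all(tis$ach == 0))   # no patches, zero dose everywhere
  tis <- place_ach_patches(tis, radii = 0.5, n_per_radius = 2, seed = 11)
  expect_equal(nrow(tis$registry), 2)
  expect_setequal(unique(as.vector(tis$ach)), c(0, 0.1))
  # the registry reproduces the stored map exactly
  expect_identical(rasterize_ach(tis), tis$ach)
  # area fraction close to the analytic circle area
  area_frac <- mean(tis$ach > 0)
  lx <- (101 - 1) * 0.02
  expect_equal(area_frac, 2 * pi * 0.5^2 / lx^2, tolerance = 0.05)
  # reproducible under the seed
  tis2 <- place_ach_patches(tissue_model(nx = 101, ny = 101, dx = 0.02),
                            radii = 0.5, n_per_radius = 2, seed = 11)
  expect_identical(tis$registry, tis2$registry)
  expect_error(place_ach_patches(tissue_model(nx = 21, ny = 21, dx = 0.02),
                                 radii = 0.5, n_per_radius = 2),
               "fit|overlap")
})

test_that("edge diffusion map composes anisotropy and fibroblast factors", {
  tis <- tissue_model(nx = 5, ny = 5, dx = 0.02, d_long = 0.003)
  d <- build_diffusion(tis)
  expect_true(all(d$Dy == 0.003))          # fiber axis y -> longitudinal
  expect_true(all(d$Dx == 0.0015))         # transverse = 0.5 * d_long
  # insert one fibroblast at (3, 3)
  tis$label[3, 3] <- 1L
  d2 <- build_diffusion(tis)
  expect_equal(d2$Dy[2, 3], 0.25 * 0.003)  # myocyte-fibroblast along fiber
  expect_equal(d2$Dy[3, 3], 0.25 * 0.003)
  expect_equal(d2$Dx[3, 2], 0.25 * 0.0015) # perpendicular edge
  expect_equal(d2$Dx[1, 1], 0.0015)        # untouched edge
  # fibroblast-fibroblast edge perpendicular to the fiber
  tis$label[3, 4] <- 1L
  d3 <- build_diffusion(tis)
  expect_equal(d3$Dx[3, 3], 0.25 * 0.0015)
})

test_that("tissue serialization round-trips through plain text", {
  tis <- tissue_model(nx = 21, ny = 21, dx = 0.04, condition = "PxAF")
  tis$label <- uniform_fibrosis(21, 21, 0.2, seed = 1)
  tis <- place_ach_patches(tis, radii = 0.24, n_per_radius = 1, seed = 2)
  path <- file.path(tempdir(), "tissue-roundtrip")
  write_tissue(tis, path)
  back <- read_tissue(path)
  expect_identical(back$label, tis$label)
  expect_equal(back$ach, tis$ach)
  expect_equal(back$registry$x, tis$registry$x)
  expect_equal(back$d_long, tis$d_long)
  unlink(path, recursive = TRUE)
})

test_that("preset fibrotic layouts scale with the domain", {
  t1 <- tissue_model(nx = 63, ny = 63, dx = 0.04)
  t2 <- tissue_model(nx = 251, ny = 251, dx = 0.02)
  p1 <- fnu_preset(t1, "Fnu1"); p2 <- fnu_preset(t2, "Fnu1")
  expect_equal(p2$r / p1$r, rep(5 / 2.48, nrow(p1)), tolerance = 1e-6)
  expect_equal(nrow(fnu_preset(t1, "Fnu2")), 4)
})
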