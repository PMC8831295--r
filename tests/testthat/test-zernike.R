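test_that("the (n, l) index set enumerates even n - l pairs up to the order", {
  for (ord in c(4L, 6L, 10L, 12L)) {
    nl <- zernike_nl_pairs(ord)
    # independent enumeration
    ref <- do.call(rbind, lapply(0:ord, function(n) {
      ls <- seq(n %% 2, n, by = 2)
      data.frame(n = n, l = ls)
    }))
    expect_identical(nrow(nl), nrow(ref))
    expect_identical(nl$n, ref$n)
    expect_identical(nl$l, ref$l)
  }
  expect_identical(nrow(zernike_nl_pairs(10L)), 36L)
})

test_that("radial polynomials are orthonormal under the r^2 weight", {
  # independent check through stats::integrate, not the package quadrature
  pairs <- list(c(0, 0, 2, 0), c(4, 2, 4, 2), c(10, 4, 10, 4),
                c(6, 2, 8, 2), c(10, 10, 10, 10), c(3, 1, 9, 1))
  for (p in pairs) {
    v <- stats::integrate(function(r) {
      radial_polynomial(p[1], p[2], r) * radial_polynomial(p[3], p[4], r) * r^2
    }, 0, 1, rel.tol = 1e-10)$value
    expect_equal(v, as.numeric(p[1] == p[3]), tolerance = 1e-8)
  }
})

test_that("moments obey the conjugate symmetry of a real-valued field", {
  cl <- make_shape("blob", n_points = 1500, seed = 9)
  g <- voxelize(cl, 32)
  mo <- compute_moments(g, 6)
  for (r in seq_along(mo$values)) {
    m <- mo$m[r]
    if (m <= 0) next
    r_neg <- which(mo$n == mo$n[r] & mo$l == mo$l[r] & mo$m == -m)
    expect_equal(mo$values[r_neg], (-1)^m * Conj(mo$values[r]),
                 tolerance = 1e-12)
  }
})

test_that("a lattice-symmetric ball has vanishing l = 1..3 descriptors", {
  L <- 48
  ctr <- -1 + (seq_len(L) - 0.5) * (2 / L)
  vals <- array(0, c(L, L, L))
  for (i in seq_len(L)) for (j in seq_len(L)) {
    vals[i, j, ] <- as.numeric(ctr[i]^2 + ctr[j]^2 + ctr^2 <= 0.36)
  }
  g <- structure(list(values = vals, L = L, fill_fraction = 0.6),
                 class = "zp_grid")
  d <- zernike_invariants(compute_moments(g, 10))
  d00 <- d$values[d$n == 0 & d$l == 0]
  expect_gt(d00, 0.1)
  expect_lt(max(d$values[d$l %in% 1:3]), 1e-12)
})

test_that("trilinear deposition conserves unit mass", {
  cl <- make_shape("torus", n_points = 2000, seed = 3)
  g <- voxelize(cl, 32)
  h <- 2 / g$L
  expect_equal(sum(g$values) * h^3, 1, tolerance = 1e-12)
})

test_that("binary deposition produces a 0/1 shell and solid mode fills it", {
  cl <- make_shape("ellipsoid", n_points = 3000, seed = 4)
  gb <- voxelize(cl, 32, deposition = "binary")
  expect_setequal(unique(as.numeric(gb$values)), c(0, 1))
  gs <- voxelize(cl, 32, mode = "solid")
  expect_gt(sum(gs$values), sum(gb$values))
})

test_that("voxelize rejects degenerate input and bad parameters", {
  expect_error(voxelize(matrix(1, 5, 3)), "degenerate")
  expect_error(voxelize(matrix(rnorm(30), 10, 3), grid_side = 8), "at least 16")
  expect_error(voxelize(matrix(rnorm(30), 10, 3), fill_fraction = 1.2),
               "fill_fraction")
})

test_that("reconstruction error does not increase with expansion order", {
  g <- voxelize(make_shape("ellipsoid", n_points = 3000, seed = 2), 32)
  errs <- vapply(seq(2, 10, by = 2), function(o) {
    rec <- reconstruct(compute_moments(g, o), grid_side = 32)
    sqrt(sum((rec$values - g$values)^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("moments are a projection: re-expanding a reconstruction is stable", {
  g <- voxelize(make_shape("ellipsoid", n_points = 3000, seed = 2), 32)
  mo <- compute_moments(g, 6)
  mo2 <- compute_moments(reconstruct(mo, grid_side = 32), 6)
  expect_lt(max(Mod(mo$values - mo2$values)) / max(Mod(mo$values)), 0.05)
})

test_that("descriptors round-trip through the text format", {
  d <- zernike_descriptor(make_shape("helix", n_points = 2000, seed = 5),
                          grid_side = 32)
  f <- withr::local_tempfile(fileext = ".txt")
  write_descriptor(d, f, source = "unit-test")
  d2 <- read_descriptor(f)
  expect_equal(d2$order, d$order)
  expect_equal(d2$n, d$n, ignore_attr = TRUE)
  expect_equal(d2$l, d$l, ignore_attr = TRUE)
  expect_equal(d2$values, d$values, tolerance = 1e-14)
})

test_that("explicit radial coefficients match the recurrence evaluation", {
  r <- seq(0.05, 0.95, by = 0.1)
  for (p in list(c(10, 4), c(8, 0), c(7, 3), c(10, 10))) {
    expect_equal(radial_polynomial(p[1], p[2], r),
                 zpocket:::radial_jacobi(p[1], p[2], r), tolerance = 1e-10)
  }
})
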