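#' Valid (n, l) index pairs of the 3D Zernike basis
#'
#' The radial order n and angular degree l must satisfy 0 <= l <= n with
#' n - l even. At order 10 there are 36 pairs, hence 36 invariants.
#'
#' @param order maximum expansion order n_max.
#' @return data.frame with columns `n`, `l`, lexicographically ordered.
#' @export
zernike_nl_pairs <- function(order) {
  stopifnot(order >= 0)
  out <- do.call(rbind, lapply(0:order, function(n) {
    l <- seq(n %% 2, n, by = 2)
    data.frame(n = n, l = l)
  }))
  out[order(out$n, out$l), , drop = FALSE]
}

# generalized binomial coefficient via gamma functions
gchoose <- function(a, k) exp(lgamma(a + 1) - lgamma(k + 1) - lgamma(a - k + 1))

#' Monomial coefficients of the Zernike radial polynomial
#'
#' Coefficients N_nlk of R_nl(r) = sum_k N_nlk r^(n-2k), k = 0..(n-l)/2,
#' normalized so that the radial functions satisfy
#' `integral_0^1 R_nl R_n'l r^2 dr = delta_nn'` and hence the full basis
#' Z_nlm = R_nl Y_lm is orthonormal on the unit ball. Built from the Jacobi
#' polynomial representation R_nl(r) = sqrt(2n+3) r^l P_s^(0, l+1/2)(2r^2-1)
#' with s = (n-l)/2.
#'
#' @param n,l radial order and angular degree (n - l even, both >= 0).
#' @return numeric vector of length (n-l)/2 + 1; element k+1 multiplies
#'   r^(n-2k).
#' @export
zernike_radial_coefficients <- function(n, l) {
  if (n < 0 || l < 0 || l > n || (n - l) %% 2 != 0) {
    stop("invalid (n, l): need 0 <= l <= n with n - l even")
  }
  s <- (n - l) / 2
  b <- l + 0.5
  co <- numeric(s + 1)                # coefficient of r^(l + 2p), p = 0..s
  for (j in 0:s) {
    c1 <- choose(s, j) * gchoose(s + b, s - j)
    for (t in 0:(s - j)) {
      p <- j + t
      co[p + 1] <- co[p + 1] + c1 * choose(s - j, t) * (-1)^(s - j - t)
    }
  }
  co <- sqrt(2 * n + 3) * co
  rev(co)                             # k = s - p so that element k+1 is r^(n-2k)
}

#' Evaluate the Zernike radial polynomial R_nl(r)
#'
#' @inheritParams zernike_radial_coefficients
#' @param r radii in [0, 1] (vectorized).
#' @return numeric vector of R_nl(r).
#' @export
radial_polynomial <- function(n, l, r) {
  co <- zernike_radial_coefficients(n, l)
  s <- (n - l) / 2
  out <- numeric(length(r))
  for (k in 0:s) out <- out + co[k + 1] * r^(n - 2 * k)
  out
}

# independent radial evaluation through the Jacobi three-term recurrence;
# used only by the naive-oracle moment computation
radial_jacobi <- function(n, l, r) {
  s <- (n - l) / 2
  x <- 2 * r^2 - 1
  a <- 0; b <- l + 0.5
  p0 <- rep(1, length(x))
  if (s == 0) return(sqrt(2 * n + 3) * r^l * p0)
  p1 <- (a - b) / 2 + (a + b + 2) / 2 * x
  if (s > 1) {
    for (k in 2:s) {
      c1 <- 2 * k * (k + a + b) * (2 * k + a + b - 2)
      c2 <- (2 * k + a + b - 1) * (a^2 - b^2)
      c3 <- (2 * k + a + b - 2) * (2 * k + a + b - 1) * (2 * k + a + b)
      c4 <- 2 * (k + a - 1) * (k + b - 1) * (2 * k + a + b)
      p2 <- ((c2 + c3 * x) * p1 - c4 * p0) / c1
      p0 <- p1; p1 <- p2
    }
  }
  sqrt(2 * n + 3) * r^l * p1
}

ylm_norm <- function(l, m) {
  sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
}

# Spherical harmonic values Y_l^m for m = -l..l at given angles.
# Returns a complex matrix with 2l+1 rows (m = -l..l) and one column per
# point. Orthonormal convention, Condon-Shortley phase (inherited from
# pracma::legendre, MATLAB convention).
ylm_values <- function(l, cos_theta, phi) {
  P <- pracma::legendre(l, cos_theta)          # (l+1) x N, orders m = 0..l
  if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
  N <- length(cos_theta)
  out <- matrix(0 + 0i, nrow = 2 * l + 1, ncol = N)
  for (m in 0:l) {
    Y <- ylm_norm(l, m) * P[m + 1, ] * exp(1i * m * phi)
    out[l + 1 + m, ] <- Y
    if (m > 0) out[l + 1 - m, ] <- (-1)^m * Conj(Y)
  }
  out
}

new_moments <- function(order, idx, values) {
  structure(list(order = order, n = idx$n, l = idx$l, m = idx$m,
                 values = values),
            class = "zp_moments")
}

#' @export
print.zp_moments <- function(x, ...) {
  cat(sprintf("<zp_moments> order %d, %d coefficients C_nlm\n",
              x$order, length(x$values)))
  invisible(x)
}

moment_index <- function(order) {
  nl <- zernike_nl_pairs(order)
  do.call(rbind, lapply(seq_len(nrow(nl)), function(i) {
    data.frame(n = nl$n[i], l = nl$l[i], m = seq(-nl$l[i], nl$l[i]))
  }))
}

# voxel-center coordinates, field values and voxel volume of the non-zero
# voxels inside the unit ball
grid_support <- function(grid) {
  L <- grid$L
  centers <- (2 * seq_len(L) - 1) / L - 1
  nz <- which(grid$values != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) {
    return(list(xyz = matrix(0, 0, 3), f = numeric(0), dV = (2 / L)^3))
  }
  xyz <- cbind(centers[nz[, 1]], centers[nz[, 2]], centers[nz[, 3]])
  f <- grid$values[nz]
  r <- sqrt(rowSums(xyz^2))
  keep <- r <= 1
  list(xyz = xyz[keep, , drop = FALSE], f = f[keep], dV = (2 / L)^3)
}

#' Compute 3D Zernike moments of a voxel grid
#'
#' Approximates C_nlm = integral over the unit ball of f(r) conj(Z_nlm(r)) dV
#' by a Riemann sum over the centers of the grid's non-zero voxels (voxels
#' outside the unit ball are ignored). Deterministic. The computation is
#' vectorized over voxels; [compute_moments_naive()] provides an independent
#' triple-loop implementation used as a cross-check oracle.
#'
#' @param grid a `zp_grid` from [voxelize()].
#' @param order maximum expansion order (default 10; a warning is emitted
#'   above 20 where the monomial radial form loses numerical stability).
#' @return a `zp_moments` object.
#' @export
compute_moments <- function(grid, order = 10) {
  stopifnot(inherits(grid, "zp_grid"), order >= 0)
  if (order > 20) warning("order ", order, " exceeds the numerical stability bound (20)")
  sup <- grid_support(grid)
  idx <- moment_index(order)
  vals <- complex(nrow(idx))
  if (length(sup$f) > 0L) {
    xyz <- sup$xyz
    r <- sqrt(rowSums(xyz^2))
    ct <- ifelse(r > 0, xyz[, 3] / r, 1)
    ct <- pmin(1, pmax(-1, ct))
    phi <- atan2(xyz[, 2], xyz[, 1])
    nl <- zernike_nl_pairs(order)
    row0 <- 0L
    for (l in unique(nl$l)) {
      Y <- ylm_values(l, ct, phi)
      for (n in nl$n[nl$l == l]) {
        Rv <- radial_polynomial(n, l, r) * sup$f
        sel <- which(idx$n == n & idx$l == l)
        for (j in seq_along(sel)) {
          m <- idx$m[sel[j]]
          vals[sel[j]] <- sum(Rv * Conj(Y[l + 1 + m, ])) * sup$dV
        }
      }
    }
  }
  new_moments(order, idx, vals)
}

#' Naive triple-loop Zernike moment computation (validation oracle)
#'
#' Re-derives every C_nlm by looping voxel-by-voxel over the grid and
#' evaluating the basis from first principles (Jacobi recurrence for the
#' radial part, per-voxel Legendre evaluation for the angular part). Slow by
#' construction; exists to cross-check [compute_moments()].
#'
#' @inheritParams compute_moments
#' @return a `zp_moments` object.
#' @export
compute_moments_naive <- function(grid, order = 10) {
  stopifnot(inherits(grid, "zp_grid"))
  L <- grid$L
  centers <- (2 * seq_len(L) - 1) / L - 1
  idx <- moment_index(order)
  vals <- complex(nrow(idx))
  dV <- (2 / L)^3
  nl <- zernike_nl_pairs(order)
  # rows of idx are contiguous per (n, l) block with m ascending from -l
  block_start <- vapply(seq_len(nrow(nl)), function(i)
    min(which(idx$n == nl$n[i] & idx$l == nl$l[i])), integer(1))
  names(block_start) <- paste(nl$n, nl$l)
  for (i in seq_len(L)) for (j in seq_len(L)) for (k in seq_len(L)) {
    f <- grid$values[i, j, k]
    if (f == 0) next
    x <- centers[i]; y <- centers[j]; z <- centers[k]
    r <- sqrt(x^2 + y^2 + z^2)
    if (r > 1) next
    ct <- if (r > 0) max(-1, min(1, z / r)) else 1
    phi <- atan2(y, x)
    for (l in unique(nl$l)) {
      P <- pracma::legendre(l, ct)
      for (n in nl$n[nl$l == l]) {
        Rv <- radial_jacobi(n, l, r)
        base <- block_start[[paste(n, l)]]
        for (m in seq(-l, l)) {
          Y <- ylm_norm(l, abs(m)) * P[abs(m) + 1] * exp(1i * abs(m) * phi)
          if (m < 0) Y <- (-1)^abs(m) * Conj(Y)
          vals[base + m + l] <- vals[base + m + l] + f * Rv * Conj(Y) * dV
        }
      }
    }
  }
  new_moments(order, idx, vals)
}

#' Rotation-invariant Zernike descriptors
#'
#' D_nl = sqrt(sum_m |C_nlm|^2), the per-(n, l) norm of the moments over m,
#' ordered lexicographically in (n, l). Invariant under rotations of the
#' underlying shape. At order 10 the descriptor has 36 entries.
#'
#' @param moments a `zp_moments` object.
#' @return a `zp_descriptor`: list with `order`, `n`, `l` and non-negative
#'   `values`.
#' @export
zernike_invariants <- function(moments) {
  stopifnot(inherits(moments, "zp_moments"))
  nl <- zernike_nl_pairs(moments$order)
  vals <- vapply(seq_len(nrow(nl)), function(i) {
    sel <- moments$n == nl$n[i] & moments$l == nl$l[i]
    sqrt(sum(Mod(moments$values[sel])^2))
  }, numeric(1))
  structure(list(order = moments$order, n = nl$n, l = nl$l, values = vals),
            class = "zp_descriptor")
}

#' @export
print.zp_descriptor <- function(x, ...) {
  cat(sprintf("<zp_descriptor> order %d, %d invariants D_nl (max %.4g)\n",
              x$order, length(x$values), max(x$values)))
  invisible(x)
}

#' Evaluate the truncated Zernike expansion on a lattice
#'
#' Reconstructs the real field sum_nlm C_nlm Z_nlm at the voxel centers of an
#' L x L x L grid mapped to [-1, 1]^3 (zero outside the unit ball). Used for
#' validation: reconstruction error decreases with order, and moments of a
#' reconstruction reproduce the input moments.
#'
#' @param moments a `zp_moments` object.
#' @param grid_side lattice side L.
#' @return a `zp_grid` whose mapping is the identity unit-ball frame.
#' @export
reconstruct <- function(moments, grid_side = 32) {
  stopifnot(inherits(moments, "zp_moments"))
  L <- as.integer(grid_side)
  centers <- (2 * seq_len(L) - 1) / L - 1
  xyz <- as.matrix(expand.grid(x = centers, y = centers, z = centers))
  r <- sqrt(rowSums(xyz^2))
  inside <- which(r <= 1)
  field <- numeric(nrow(xyz))
  rr <- r[inside]
  ct <- ifelse(rr > 0, xyz[inside, 3] / rr, 1)
  ct <- pmin(1, pmax(-1, ct))
  phi <- atan2(xyz[inside, 2], xyz[inside, 1])
  acc <- complex(length(inside))
  nl <- zernike_nl_pairs(moments$order)
  for (l in unique(nl$l)) {
    Y <- ylm_values(l, ct, phi)
    for (n in nl$n[nl$l == l]) {
      Rv <- radial_polynomial(n, l, rr)
      for (m in seq(-l, l)) {
        C <- moments$values[moments$n == n & moments$l == l & moments$m == m]
        if (Mod(C) == 0) next
        acc <- acc + C * Rv * Y[l + 1 + m, ]
      }
    }
  }
  field[inside] <- Re(acc)
  vals <- array(field, dim = c(L, L, L))
  structure(list(values = vals, L = L, translation = c(0, 0, 0), scale = 1,
                 fill_fraction = 1),
            class = "zp_grid")
}

#' Gram matrix of the Zernike basis on the unit ball
#'
#' Numerically integrates `<Z_nlm, Z_n'l'm'>` over the unit ball for every
#' pair of basis functions up to `order`, using a separable product
#' quadrature (Gauss-Legendre in the radius and in cos(theta), uniform
#' midpoints in phi) that is exact for the polynomial integrands involved.
#' For an orthonormal basis the result is the identity matrix; the maximum
#' absolute deviation is the orthonormality defect of the implementation.
#'
#' @param order maximum expansion order.
#' @param n_r,n_theta number of Gauss-Legendre nodes (defaults exact through
#'   order 10).
#' @param n_phi number of uniform phi nodes (default 2*order + 2).
#' @return list with `gram` (complex matrix) and `max_deviation` from the
#'   identity.
#' @export
zernike_gram <- function(order = 10, n_r = 2 * order + 2,
                         n_theta = 2 * order + 2, n_phi = 2 * order + 2) {
  glr <- pracma::gaussLegendre(n_r, 0, 1)
  glt <- pracma::gaussLegendre(n_theta, -1, 1)
  phi <- (2 * seq_len(n_phi) - 1) * pi / n_phi
  wphi <- 2 * pi / n_phi

  nodes <- expand.grid(ir = seq_len(n_r), it = seq_len(n_theta),
                       ip = seq_len(n_phi))
  r <- glr$x[nodes$ir]
  ct <- glt$x[nodes$it]
  ph <- phi[nodes$ip]
  w <- glr$w[nodes$ir] * r^2 * glt$w[nodes$it] * wphi

  idx <- moment_index(order)
  B <- matrix(0 + 0i, nrow = length(r), ncol = nrow(idx))
  nl <- zernike_nl_pairs(order)
  for (l in unique(nl$l)) {
    Y <- ylm_values(l, ct, ph)
    for (n in nl$n[nl$l == l]) {
      Rv <- radial_polynomial(n, l, r)
      sel <- which(idx$n == n & idx$l == l)
      for (j in seq_along(sel)) {
        B[, sel[j]] <- Rv * Y[l + 1 + idx$m[sel[j]], ]
      }
    }
  }
  G <- crossprod(Conj(B), w * B)
  dev <- max(Mod(G - diag(nrow(idx))))
  list(gram = G, max_deviation = dev, index = idx)
}
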