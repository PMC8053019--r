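test_that("premise variables take their defining values", {
  p <- tp()
  x <- c(X = 321, Xr = 1234, S = 47, Co = 3.3)
  z <- premise_eval(x, p)
  expect_equal(unname(z[c(2, 3, 6, 4)]), unname(x[c(1, 2, 3, 4)]))
  # z1 at the double half-saturation point: mu = mumax/4
  z_hs <- premise_eval(c(10, 10, p$Ks, p$Kc), p)
  expect_equal(unname(z_hs[1]), 0.0375 - 100)
  # z5 * Co recovers mu * X (the factorization contract for the z5 rows)
  mu <- growth_rate(47, 3.3, p)
  expect_equal(unname(z[5] * 3.3), mu * 321)
})

test_that("the factorization identity A(z(x)) x = reaction terms holds", {
  p <- tp()
  io <- rand_inputs(1000)
  for (fac in c("coupled", "tracking")) {
    worst <- 0
    for (k in seq_len(nrow(io$x))) {
      x <- io$x[k, ]
      z <- premise_eval(x, p)
      A <- nonlinear_matrices(z, p, fac)$A
      mu <- growth_rate(x[3], x[4], p)
      reac <- c(mu * x[1], 0, -mu * x[1] / p$Y, -p$K0 * mu * x[1] / p$Y)
      worst <- max(worst, max(abs(A %*% x - reac)) / max(1, max(abs(reac))))
    }
    expect_lt(worst, 1e-9)
  }
})

test_that("A(z), B(z) reproduce the plant flow exactly in-domain", {
  p <- tp()
  io <- rand_inputs(1000)
  G <- as.vector(ts_G())
  for (fac in c("coupled", "tracking")) {
    worst <- 0
    for (k in seq_len(nrow(io$x))) {
      x <- io$x[k, ]; u <- io$u[k, ]; ds <- io$ds[k]
      z <- premise_eval(x, p)
      m <- nonlinear_matrices(z, p, fac)
      lhs <- as.vector(m$A %*% x + m$B %*% u) + G * u[1] * ds
      rhs <- plant_rhs(x, u, ds, p)
      worst <- max(worst, max(abs(lhs - rhs)) / max(1, max(abs(rhs))))
    }
    expect_lt(worst, 1e-9)
  }
  # structural checks forced by the mass balances
  z <- premise_eval(c(500, 1000, 50, 4), p)
  m <- nonlinear_matrices(z, p)
  expect_equal(unname(m$A[2, ] %*% c(500, 1000, 50, 4))[1, 1], 0)
  expect_equal(unname(m$B[, 2]), c(0, 0, 0, p$Cs - 4))
})

test_that("premise bounds enclose all in-domain premise values", {
  p <- tp()
  dom <- tdom()
  b <- tbounds()
  expect_equal(unname(b[2, ]), dom$X)
  expect_equal(unname(b[3, ]), dom$Xr)
  expect_equal(unname(b[4, ]), dom$Co)
  expect_equal(unname(b[6, ]), dom$S)
  set.seed(2)
  xs <- sample_domain(1e4, dom)
  for (k in seq_len(nrow(xs))) {
    z <- premise_eval(xs[k, ], p)
    expect_true(all(z >= b[, 1] & z <= b[, 2]))
  }
  # shrinking the domain never widens a bound
  half <- operating_domain(X = c(180, 240), Xr = c(350, 450),
                           S = c(40, 70), Co = c(2, 6))
  bh <- premise_bounds(half, p)
  expect_true(all(bh[, 1] >= b[, 1] - 1e-12))
  expect_true(all(bh[, 2] <= b[, 2] + 1e-12))
  expect_error(premise_bounds(operating_domain(X = c(500, 500))), "lower")
})

test_that("vertex enumeration yields 2^6 submodels with shared structure", {
  p <- tp()
  ts <- build_vertex_models(tbounds(), p)
  expect_identical(ts$nr, 64L)
  # entries not involving premises are identical across submodels
  expect_true(all(ts$A[3, 1:3, ] == 0))
  expect_true(all(ts$B[1, 2, ] == 0))
  # convex reconstruction of the nonlinear matrices
  set.seed(3)
  xs <- sample_domain(100, tdom())
  worst <- 0
  for (k in seq_len(nrow(xs))) {
    z <- premise_eval(xs[k, ], p)
    h <- membership(z, ts$bounds)
    bl <- blend_matrices(ts, h)
    m <- nonlinear_matrices(z, p)
    worst <- max(worst, max(abs(bl$A - m$A)), max(abs(bl$B - m$B)))
  }
  expect_lt(worst / max(abs(ts$A)), 1e-12)
})

test_that("membership weights live on the probability simplex", {
  p <- tp()
  b <- tbounds()
  # all-minimum corner activates the first vertex only
  h_corner <- membership(b[, 1], b)
  expect_equal(h_corner, c(1, rep(0, 63)))
  # midpoint gives the uniform weight 1/64
  h_mid <- membership(rowMeans(b), b)
  expect_equal(h_mid, rep(1 / 64, 64))
  # simplex property over many random states, including out-of-domain
  # states that exercise the clipping path
  set.seed(4)
  n <- 1e5
  xs <- cbind(runif(n, 0, 2500), runif(n, 0, 5000),
              runif(n, 0, 400), runif(n, 0.01, 20))
  for (k in seq_len(200)) {
    h <- membership(premise_eval(xs[k, ], p), b)
    expect_true(all(h >= 0 & h <= 1))
    expect_lt(abs(sum(h) - 1), 1e-12)
  }
  sums <- vapply(seq_len(n), function(k)
    sum(membership(premise_eval(xs[k, ], p), b)), numeric(1))
  expect_lt(max(abs(sums - 1)), 1e-12)
})

test_that("degenerate premises collapse the vertex count and stay exact", {
  p <- tp()
  br <- tbounds_reduced()
  ts <- build_vertex_models(br, p)
  expect_identical(ts$nr, 8L)
  # exactness on the slice where the collapsed premises sit at midpoint
  set.seed(5)
  G <- as.vector(ts_G())
  worst <- 0
  for (k in 1:200) {
    x <- c(mean(tdom()$X), mean(tdom()$Xr),
           runif(1, tdom()$S[1], tdom()$S[2]),
           mean(tdom()$Co))
    u <- c(runif(1, 0, 0.2), runif(1, 0, 10)); ds <- runif(1, -10, 10)
    z <- premise_eval(x, p)
    h <- membership(z, br)
    bl <- blend_matrices(ts, h)
    lhs <- as.vector(bl$A %*% x + bl$B %*% u) + G * u[1] * ds
    rhs <- plant_rhs(x, u, ds, p)
    worst <- max(worst, max(abs(lhs - rhs)) / max(1, max(abs(rhs))))
  }
  expect_lt(worst, 1e-8)
})

test_that("partition blocks are contiguous slices that reassemble exactly", {
  p <- tp()
  ts <- tts_track_reduced()
  pts <- partition(ts)
  for (i in seq_len(ts$nr)) {
    Ai <- rbind(cbind(pts$A11[, , i], pts$A12[, , i]),
                cbind(pts$A21[, , i], pts$A22[, , i]))
    Bi <- rbind(pts$B1[, , i], pts$B2[, , i])
    expect_identical(Ai, unname(ts$A[, , i]))
    expect_identical(Bi, unname(ts$B[, , i]))
  }
  expect_equal(unname(pts$G1), matrix(0, 2, 1))
  expect_equal(unname(pts$G2), matrix(c(1, 0), 2, 1))
  # aeration column of the controlled block carries Cs - z4 at the vertex
  b <- ts$bounds
  i <- 1  # all premises at lower bounds
  expect_equal(pts$B2[2, 2, i], p$Cs - b[4, 1])
})
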