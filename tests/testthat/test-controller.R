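test_that("synthesis settings enforce the theorem preconditions", {
  expect_error(controller_spec(alpha1 = 0.5, gamma1 = 0.4), "alpha1")
  expect_error(controller_spec(Ar = diag(c(1, -1))), "Hurwitz")
  # equality of the relaxation and budget scalars is admissible (the
  # benchmark itself uses alpha = gamma)
  expect_s3_class(controller_spec(alpha1 = 0.4, gamma1 = 0.4),
                  "controller_spec")
  expect_equal(tracking_attenuation_level(0.4, 0.4), sqrt(0.8))
})

test_that("diagonal LMI assembly matches a hand-placed block oracle", {
  pts <- toy_pts()
  spec <- controller_spec()
  set.seed(21)
  vals <- list(X1 = crossprod(matrix(rnorm(4), 2)) + diag(2),
               X2 = crossprod(matrix(rnorm(4), 2)) + diag(2),
               Y1 = matrix(rnorm(4), 2), Y2 = matrix(rnorm(4), 2),
               Qt11 = diag(c(2, 3)), Qt12 = diag(c(1, 4)),
               Qt21 = diag(2), Qt22 = diag(2))
  M <- assemble_lmi_single(1, pts, spec, vals)
  expect_equal(M, t(M))
  # independent placement by direct index assignment
  A11 <- pts$A11[, , 1]; A12 <- pts$A12[, , 1]
  A21 <- pts$A21[, , 1]; A22 <- pts$A22[, , 1]
  B1 <- pts$B1[, , 1]; B2 <- pts$B2[, , 1]
  O <- matrix(0, 16, 16)
  idx <- function(k) (2 * k - 1):(2 * k)
  put <- function(M, r, c, v) {
    M[idx(r), idx(c)] <- v
    if (r != c) M[idx(c), idx(r)] <- t(v)
    M
  }
  O <- put(O, 1, 1, A11 %*% vals$X1 + vals$X1 %*% t(A11) + vals$Qt11)
  O <- put(O, 1, 2, vals$X1 %*% t(A21) + A12 %*% vals$X2 + B1 %*% vals$Y1)
  O <- put(O, 1, 3, -B1 %*% vals$Y1)
  O <- put(O, 1, 4, A12)
  O <- put(O, 1, 6, diag(2))
  O <- put(O, 2, 2, A22 %*% vals$X2 + vals$X2 %*% t(A22) +
             B2 %*% vals$Y1 + t(B2 %*% vals$Y1) + vals$Qt12)
  O <- put(O, 2, 3, -B2 %*% vals$Y1)
  O <- put(O, 2, 4, A22 - spec$Ar)
  O <- put(O, 2, 5, -diag(2))
  O <- put(O, 2, 7, diag(2))
  O <- put(O, 3, 3, -2 * spec$alpha3 * vals$X2)
  O <- put(O, 3, 8, -spec$alpha3 * diag(2))
  for (k in 4:8) O <- put(O, k, k, -spec$alpha1 * diag(2))
  expect_equal(M, O)
  # spec'd block positions
  expect_equal(M[idx(2), idx(4)], A22 - spec$Ar)
  expect_equal(M[idx(2), idx(5)], -diag(2))
})

test_that("pair LMI reduces to the diagonal one for duplicated submodels", {
  pts <- toy_pts()
  # duplicate submodel 1 into slot 2
  for (nm in c("A11", "A12", "A21", "A22", "B1", "B2")) {
    pts[[nm]][, , 2] <- pts[[nm]][, , 1]
  }
  spec <- controller_spec(alpha2 = 0.4, alpha4 = 300)  # match alpha1/alpha3
  set.seed(22)
  vals <- list(X1 = crossprod(matrix(rnorm(4), 2)) + diag(2),
               X2 = crossprod(matrix(rnorm(4), 2)) + diag(2),
               Y1 = matrix(rnorm(4), 2))
  vals$Y2 <- vals$Y1
  vals$Qt11 <- diag(c(2, 3)); vals$Qt12 <- diag(c(1, 4))
  vals$Qt21 <- 2 * vals$Qt11; vals$Qt22 <- 2 * vals$Qt12
  Mp <- assemble_lmi_pair(1, 2, pts, spec, vals)
  Ms <- assemble_lmi_single(1, pts, spec, vals)
  expect_equal(Mp, t(Mp))
  # with i = j the doubled N-blocks cancel the global 1/2: the coupling
  # rows of the pair LMI coincide with the diagonal LMI's (the relaxation
  # and disturbance diagonals differ by construction, alpha3/alpha4 aside)
  idx <- function(k) (2 * k - 1):(2 * k)
  for (rc in list(c(1, 1), c(1, 2), c(1, 3), c(1, 4), c(1, 6),
                  c(2, 2), c(2, 3), c(2, 4), c(2, 5), c(2, 7))) {
    expect_equal(Mp[idx(rc[1]), idx(rc[2])], Ms[idx(rc[1]), idx(rc[2])],
                 tolerance = 1e-12)
  }
  expect_error(assemble_lmi_pair(2, 1, pts, spec, vals), "i < j")
})

test_that("pair count follows the combinatorial identity", {
  ts <- build_vertex_models(tbounds(), tp())
  expect_identical(ts$nr, 64L)
  expect_equal(ts$nr * (ts$nr - 1) / 2, 2016)
})

test_that("toy synthesis recovers certified gains", {
  pts <- toy_pts()
  spec <- controller_spec()
  cg <- solve_controller(pts, spec, scaling = NULL)
  expect_equal(cg$status, "feasible")
  expect_equal(dim(cg$K), c(2, 2, 2))
  expect_equal(cg$gamma, sqrt(0.8))
  # gain-recovery consistency Ki X2 = Yi
  for (i in 1:2) {
    expect_lt(norm(cg$Kn[, , i] %*% cg$X2 - cg$Y[, , i], "F") /
                max(norm(cg$Y[, , i], "F"), 1e-12), 1e-6)
  }
  cert <- verify_certificate(cg, pts)
  expect_true(cert$pass)
  # a large random gain perturbation must break the certificate
  set.seed(23)
  bad <- cg
  bad$Kn[, , 1] <- bad$Kn[, , 1] + 50 * matrix(rnorm(4), 2)
  expect_false(verify_certificate(bad, pts)$pass)
})

test_that("state rescaling leaves toy feasibility unchanged", {
  pts <- toy_pts()
  spec <- controller_spec()
  plain <- solve_controller(pts, spec, scaling = NULL)
  scaled <- solve_controller(pts, spec,
                             scaling = list(t1 = c(10, 10), t2 = c(10, 10)))
  expect_equal(plain$status, "feasible")
  expect_equal(scaled$status, "feasible")
  expect_true(verify_certificate(scaled, pts)$pass)
})

test_that("a vanishing attenuation budget is reported infeasible", {
  pts <- partition(tts_track_reduced())
  spec <- controller_spec(alpha1 = 1e-10, alpha2 = 1e-10,
                          gamma1 = 1e-9, gamma2 = 1e-9)
  expect_error(solve_controller(pts, spec),
               class = "fuzztrack_synthesis_error")
})

test_that("reduced benchmark synthesis is feasible with passing certificate", {
  pts <- partition(tts_track_reduced())
  cg <- tcgains_reduced()
  expect_true(cg$status %in% c("feasible", "optimal"))
  expect_equal(dim(cg$K)[3], 8)
  expect_true(all(cg$margins < 0))
  expect_equal(cg$gamma, sqrt(0.8))
  cert <- verify_certificate(cg, pts)
  expect_true(cert$pass)
  expect_lt(cert$worst_single, 0)
  expect_lt(cert$worst_pair, 0)
})
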