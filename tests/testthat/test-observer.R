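test_that("disturbance augmentation places the blocks exactly", {
  ts <- tts_obs_reduced()
  aug <- augment(ts)
  expect_equal(dim(aug$Abar), c(5, 5, ts$nr))
  expect_equal(dim(aug$Bbar), c(5, 2, ts$nr))
  expect_equal(unname(aug$Cbar), matrix(c(0, 0, 0, 1, 0), 1, 5))
  for (i in seq_len(ts$nr)) {
    expect_equal(aug$Abar[1:4, 1:4, i], unname(ts$A[, , i]))
    expect_equal(aug$Abar[1:4, 5, i], c(0, 0, 1, 0))
    expect_true(all(aug$Abar[5, , i] == 0))
    # singular by construction: the disturbance row is an integrator
    ev <- eigen(aug$Abar[, , i], only.values = TRUE)$values
    expect_true(any(abs(ev) < 1e-12))
  }
})

test_that("observer LMI assembly matches a direct numeric evaluation", {
  aug <- list(nr = 1L, Abar = array(-2 * diag(5), c(5, 5, 1)),
              Bbar = array(0, c(5, 2, 1)), Cbar = matrix(0, 1, 5))
  vals <- list(Po = diag(5), R = diag(5), Z1 = matrix(0, 5, 1), eta = 1)
  M <- assemble_observer_lmi(1, aug, vals)
  expect_equal(M, t(M))
  expect_equal(M, rbind(cbind(-3 * diag(5), diag(5)),
                        cbind(diag(5), -diag(5))))
  expect_lt(max(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  # off-diagonal block is Po itself (no gain term enters it)
  vals$Po <- diag(c(1, 2, 3, 4, 5))
  vals$Z1 <- matrix(rnorm(5), 5, 1)
  aug$Cbar <- matrix(c(0, 0, 0, 1, 0), 1, 5)
  M2 <- assemble_observer_lmi(1, aug, vals)
  expect_equal(M2[1:5, 6:10], vals$Po)
})

test_that("prescribed-level synthesis is feasible and certified", {
  aug <- augment(tts_obs_reduced())
  og <- togains_reduced()
  expect_equal(og$status, "feasible")
  expect_lt(og$eta, 1.0681^2)
  expect_equal(og$nu_effective, sqrt(og$eta))
  # gain recovery Li = Po^-1 Zi
  for (i in seq_len(aug$nr)) {
    resid <- og$Po %*% og$L[, , i] - og$Z[, , i]
    expect_lt(sqrt(sum(resid^2)) / max(sqrt(sum(og$Z[, , i]^2)), 1e-12),
              1e-6)
  }
  cert <- verify_observer_certificate(og, aug)
  expect_true(cert$pass)
  expect_true(all(cert$hurwitz))
})

test_that("solved LMIs and pre-Schur conditions agree (Schur equivalence)", {
  aug <- augment(tts_obs_reduced())
  og <- togains_reduced()
  # (a) solved gains: both formulations strictly negative
  expect_true(all(og$margins < 0))
  expect_lt(verify_observer_certificate(og, aug)$worst, 0)
  # (b) grossly perturbed gains: both formulations violated together
  set.seed(31)
  bad <- og
  bad$L[, , 1] <- bad$L[, , 1] + 10 * max(abs(og$L)) * matrix(rnorm(5), 5, 1)
  cert_bad <- verify_observer_certificate(bad, aug)
  expect_false(cert_bad$pass)
  Zbad <- og$Po %*% bad$L[, , 1]
  lmi_bad <- assemble_observer_lmi(1, aug,
                                   list(Po = og$Po, R = og$R, Z1 = Zbad,
                                        eta = og$eta))
  expect_gt(max(eigen(lmi_bad, symmetric = TRUE, only.values = TRUE)$values),
            0)
})

test_that("minimize-eta mode returns a certified level", {
  aug <- augment(tts_obs_reduced())
  og <- solve_observer(aug, observer_spec(mode = "min_eta"))
  expect_true(og$status %in% c("optimal", "max_outer"))
  expect_gt(og$eta, 0)
  expect_equal(og$nu_effective, sqrt(og$eta))
  expect_true(verify_observer_certificate(og, aug)$pass)
  # the identity floor on R makes the minimized eta scale meaningful
  expect_gte(min(eigen(og$R, symmetric = TRUE)$values), 1 - 1e-6)
})

test_that("an unobservable output map yields a synthesis failure", {
  ts <- tts_obs_reduced()
  aug <- augment(ts)
  aug$Cbar <- matrix(0, 1, 5)
  expect_error(solve_observer(aug, observer_spec(nu = 1.0681,
                                                 mode = "prescribed")),
               class = "fuzztrack_synthesis_error")
})
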