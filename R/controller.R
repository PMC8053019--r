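#' Controller synthesis settings
#'
#' Scalars of the reduced-order H-infinity PDC tracking synthesis. The
#' relaxation scalars must satisfy alpha1 < gamma1 and alpha2 < gamma2, and
#' the reference matrix Ar must be Hurwitz. Defaults are the benchmark
#' values used throughout this package.
#'
#' @param alpha1,alpha2 positive scalars bounding the disturbance cross
#'   terms of the diagonal (i = j) and pair (i < j) closed-loop conditions
#' @param alpha3,alpha4 positive scalars of the separation-lemma relaxation
#'   replacing the nonconvex -X2^-1 term in the two LMI families
#' @param gamma1,gamma2 positive scalars; the certified tracking attenuation
#'   level is gamma = sqrt(gamma1 + gamma2)
#' @param Ar 2x2 Hurwitz reference-model matrix (1/h)
#' @param fix_Qtilde_identity if `TRUE` the transformed weights
#'   Qtilde11..Qtilde22 are fixed to the identity instead of being decision
#'   variables (smaller problem; mirrors the benchmark's reported weights)
#' @param eps strictness margin used to encode strict inequalities
#' @return object of class `controller_spec`
#' @export
controller_spec <- function(alpha1 = 0.4, alpha2 = 0.4, alpha3 = 300,
                            alpha4 = 295, gamma1 = 0.4, gamma2 = 0.4,
                            Ar = diag(c(-11, -12)),
                            fix_Qtilde_identity = FALSE, eps = 1e-6) {
  if (any(c(alpha1, alpha2, alpha3, alpha4, gamma1, gamma2) <= 0)) {
    stop("all synthesis scalars must be strictly positive")
  }
  # alpha = gamma is admissible: the disturbance cross term then drops out
  # of the dissipation inequality, which still certifies the (non-strict)
  # energy bound; alpha > gamma is not
  if (alpha1 > gamma1 || alpha2 > gamma2) {
    stop("controller_spec: the synthesis requires alpha1 <= gamma1 and ",
         "alpha2 <= gamma2")
  }
  if (max(Re(eigen(Ar, only.values = TRUE)$values)) >= 0) {
    stop("controller_spec: Ar must be Hurwitz")
  }
  sp <- list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
             alpha4 = alpha4, gamma1 = gamma1, gamma2 = gamma2, Ar = Ar,
             fix_Qtilde_identity = fix_Qtilde_identity, eps = eps)
  class(sp) <- "controller_spec"
  sp
}

#' Certified tracking attenuation level
#'
#' gamma = sqrt(gamma1 + gamma2): the bound on the energy gain from the
#' lumped disturbance xi to the weighted augmented tracking state.
#'
#' @param gamma1,gamma2 the two prescribed H-infinity budget scalars
#' @return attenuation level gamma
#' @export
tracking_attenuation_level <- function(gamma1, gamma2) sqrt(gamma1 + gamma2)

#' Diagonal state normalization for LMI synthesis
#'
#' Similarity-scales the partitioned TS model to dimensionless states
#' x1' = T1^-1 x1, x2' = T2^-1 x2. The concentrations span two to three
#' decades (biomass near 1000 mg/l, dissolved oxygen near 2 mg/l), and the
#' synthesis LMIs mix those entries with fixed identity couplings, so
#' solving in physical units is numerically hopeless. With scaling, the
#' certified energy inequalities are stated for the normalized signals
#' (each state measured relative to its nominal magnitude), which is also
#' the physically sensible way to weigh a 1 mg/l oxygen error against a
#' 1 mg/l biomass error.
#'
#' @param pts [partition()]ed TS model
#' @param t1 length-2 positive vector: nominal magnitudes of (X, Xr)
#' @param t2 length-2 positive vector: nominal magnitudes of (S, Co)
#' @return rescaled `partitioned_ts` with attributes `t1`, `t2`
#' @export
scale_partition <- function(pts, t1, t2) {
  T1 <- diag(t1); T2 <- diag(t2)
  T1i <- diag(1 / t1); T2i <- diag(1 / t2)
  out <- pts
  for (i in seq_len(pts$nr)) {
    out$A11[, , i] <- T1i %*% pts$A11[, , i] %*% T1
    out$A12[, , i] <- T1i %*% pts$A12[, , i] %*% T2
    out$A21[, , i] <- T2i %*% pts$A21[, , i] %*% T1
    out$A22[, , i] <- T2i %*% pts$A22[, , i] %*% T2
    out$B1[, , i] <- T1i %*% pts$B1[, , i]
    out$B2[, , i] <- T2i %*% pts$B2[, , i]
  }
  out$G1 <- T1i %*% pts$G1
  out$G2 <- T2i %*% pts$G2
  attr(out, "t1") <- t1
  attr(out, "t2") <- t2
  out
}

#' Default state normalization derived from the premise bounds
#'
#' Geometric means of the identity-premise bounds (z2 = X, z3 = Xr,
#' z6 = S, z4 = Co) give the nominal magnitude of each state over the
#' operating domain.
#'
#' @param pts [partition()]ed TS model (carries the premise bounds)
#' @return list with `t1` (X, Xr) and `t2` (S, Co)
#' @export
default_scaling <- function(pts) {
  b <- pts$bounds
  if (is.null(b)) stop("partitioned TS model carries no premise bounds")
  gm <- function(r) sqrt(prod(pmax(r, 1e-12)))
  list(t1 = c(gm(b[2, ]), gm(b[3, ])), t2 = c(gm(b[6, ]), gm(b[4, ])))
}

# place 2x2 blocks (upper triangle given) into a symmetric 16x16 matrix
.place_blocks <- function(blocks) {
  M <- matrix(0, 16, 16)
  for (b in blocks) {
    r <- (b$r - 1) * 2 + 1:2
    c <- (b$c - 1) * 2 + 1:2
    M[r, c] <- b$v
    if (b$r != b$c) M[c, r] <- t(b$v)
  }
  M
}

.ctrl_qt <- function(spec, vals, which) {
  if (spec$fix_Qtilde_identity) diag(2) else vals[[which]]
}

#' Assemble one diagonal (i = i) controller LMI block
#'
#' The 16x16 symmetric matrix (8x8 grid of 2x2 blocks) whose strict
#' negativity, over all submodels, is the first LMI family of the tracking
#' synthesis. Affine in the decision values X1, X2, Yi and the Qtilde
#' blocks.
#'
#' @param i submodel index
#' @param pts [partition()]ed TS model
#' @param spec [controller_spec()]
#' @param vals named list with entries `X1`, `X2`, `Y<i>` (2x2 matrices) and,
#'   unless fixed, `Qt11`, `Qt12`
#' @return symmetric 16x16 numeric matrix
#' @export
assemble_lmi_single <- function(i, pts, spec, vals) {
  if (i < 1 || i > pts$nr) stop("submodel index out of range")
  A11 <- pts$A11[, , i]; A12 <- pts$A12[, , i]
  A21 <- pts$A21[, , i]; A22 <- pts$A22[, , i]
  B1 <- pts$B1[, , i]; B2 <- pts$B2[, , i]
  X1 <- vals$X1; X2 <- vals$X2; Yi <- vals[[paste0("Y", i)]]
  Qt11 <- .ctrl_qt(spec, vals, "Qt11")
  Qt12 <- .ctrl_qt(spec, vals, "Qt12")
  I2 <- diag(2)
  M1 <- A11 %*% X1 + X1 %*% t(A11) + Qt11
  M2 <- X1 %*% t(A21) + A12 %*% X2 + B1 %*% Yi
  M3 <- A22 %*% X2 + X2 %*% t(A22) + B2 %*% Yi + t(B2 %*% Yi) + Qt12
  .place_blocks(list(
    list(r = 1, c = 1, v = M1),
    list(r = 1, c = 2, v = M2),
    list(r = 1, c = 3, v = -B1 %*% Yi),
    list(r = 1, c = 4, v = A12),
    list(r = 1, c = 6, v = I2),
    list(r = 2, c = 2, v = M3),
    list(r = 2, c = 3, v = -B2 %*% Yi),
    list(r = 2, c = 4, v = A22 - spec$Ar),
    list(r = 2, c = 5, v = -I2),
    list(r = 2, c = 7, v = I2),
    list(r = 3, c = 3, v = -2 * spec$alpha3 * X2),
    list(r = 3, c = 8, v = -spec$alpha3 * I2),
    list(r = 4, c = 4, v = -spec$alpha1 * I2),
    list(r = 5, c = 5, v = -spec$alpha1 * I2),
    list(r = 6, c = 6, v = -spec$alpha1 * I2),
    list(r = 7, c = 7, v = -spec$alpha1 * I2),
    list(r = 8, c = 8, v = -spec$alpha1 * I2)))
}

#' Assemble one pair (i < j) controller LMI block
#'
#' The 16x16 symmetric matrix (including the overall factor 1/2, the doubled
#' identity couplings and the -2*Ar term) whose strict negativity over all
#' submodel pairs is the second LMI family of the tracking synthesis.
#'
#' @param i,j submodel indices with i < j
#' @inheritParams assemble_lmi_single
#' @param vals named list with `X1`, `X2`, `Y<i>`, `Y<j>` and, unless fixed,
#'   `Qt21`, `Qt22`
#' @return symmetric 16x16 numeric matrix
#' @export
assemble_lmi_pair <- function(i, j, pts, spec, vals) {
  if (!(i < j)) stop("assemble_lmi_pair requires i < j")
  if (j > pts$nr) stop("submodel index out of range")
  Ai11 <- pts$A11[, , i]; Aj11 <- pts$A11[, , j]
  Ai12 <- pts$A12[, , i]; Aj12 <- pts$A12[, , j]
  Ai21 <- pts$A21[, , i]; Aj21 <- pts$A21[, , j]
  Ai22 <- pts$A22[, , i]; Aj22 <- pts$A22[, , j]
  Bi1 <- pts$B1[, , i]; Bj1 <- pts$B1[, , j]
  Bi2 <- pts$B2[, , i]; Bj2 <- pts$B2[, , j]
  X1 <- vals$X1; X2 <- vals$X2
  Yi <- vals[[paste0("Y", i)]]; Yj <- vals[[paste0("Y", j)]]
  Qt21 <- .ctrl_qt(spec, vals, "Qt21")
  Qt22 <- .ctrl_qt(spec, vals, "Qt22")
  I2 <- diag(2)
  BY1 <- Bi1 %*% Yj + Bj1 %*% Yi
  BY2 <- Bi2 %*% Yj + Bj2 %*% Yi
  N1 <- (Ai11 + Aj11) %*% X1 + X1 %*% t(Ai11 + Aj11) + Qt21
  N2 <- X1 %*% t(Ai21 + Aj21) + (Ai12 + Aj12) %*% X2 + BY1
  N3 <- (Ai22 + Aj22) %*% X2 + X2 %*% t(Ai22 + Aj22) + BY2 + t(BY2) + Qt22
  0.5 * .place_blocks(list(
    list(r = 1, c = 1, v = N1),
    list(r = 1, c = 2, v = N2),
    list(r = 1, c = 3, v = -BY1),
    list(r = 1, c = 4, v = Ai12 + Aj12),
    list(r = 1, c = 6, v = 2 * I2),
    list(r = 2, c = 2, v = N3),
    list(r = 2, c = 3, v = -BY2),
    list(r = 2, c = 4, v = Ai22 + Aj22 - 2 * spec$Ar),
    list(r = 2, c = 5, v = -2 * I2),
    list(r = 2, c = 7, v = 2 * I2),
    list(r = 3, c = 3, v = -2 * spec$alpha4 * X2),
    list(r = 3, c = 8, v = -spec$alpha4 * I2),
    list(r = 4, c = 4, v = -spec$alpha2 * I2),
    list(r = 5, c = 5, v = -spec$alpha2 * I2),
    list(r = 6, c = 6, v = -spec$alpha2 * I2),
    list(r = 7, c = 7, v = -spec$alpha2 * I2),
    list(r = 8, c = 8, v = -spec$alpha2 * I2)))
}

# reference matrix expressed in the normalized x2 coordinates (a no-op for
# the diagonal benchmark Ar)
.spec_scaled <- function(spec, scaling) {
  if (is.null(scaling)) return(spec)
  T2 <- diag(scaling$t2); T2i <- diag(1 / scaling$t2)
  spec$Ar <- T2i %*% spec$Ar %*% T2
  spec
}

.controller_varset <- function(nr, fix_qt) {
  decls <- list(X1 = lmi_sym(2), X2 = lmi_sym(2))
  for (i in seq_len(nr)) decls[[paste0("Y", i)]] <- lmi_mat(2, 2)
  if (!fix_qt) {
    decls$Qt11 <- lmi_sym(2); decls$Qt12 <- lmi_sym(2)
    decls$Qt21 <- lmi_sym(2); decls$Qt22 <- lmi_sym(2)
  }
  do.call(lmi_varset, decls)
}

.controller_blocks <- function(pts, spec, vs) {
  nr <- pts$nr
  fix_qt <- spec$fix_Qtilde_identity
  blocks <- vector("list", 0)
  for (i in seq_len(nr)) {
    loc <- c("X1", "X2", paste0("Y", i), if (!fix_qt) c("Qt11", "Qt12"))
    f <- local({
      ii <- i
      function(vals) assemble_lmi_single(ii, pts, spec, vals)
    })
    blocks[[length(blocks) + 1L]] <- lmi_compile_block(f, vs, loc,
                                                       eps = spec$eps)
  }
  for (i in seq_len(nr - 1)) {
    for (j in seq((i + 1), nr)) {
      loc <- c("X1", "X2", paste0("Y", i), paste0("Y", j),
               if (!fix_qt) c("Qt21", "Qt22"))
      f <- local({
        ii <- i; jj <- j
        function(vals) assemble_lmi_pair(ii, jj, pts, spec, vals)
      })
      blocks[[length(blocks) + 1L]] <- lmi_compile_block(f, vs, loc,
                                                         eps = spec$eps)
    }
  }
  # positive definiteness of the Lyapunov blocks and weights
  pd_floor <- 1e-6
  blocks[[length(blocks) + 1L]] <- lmi_pd_block(vs, "X1", pd_floor)
  blocks[[length(blocks) + 1L]] <- lmi_pd_block(vs, "X2", pd_floor)
  if (!fix_qt) {
    for (nm in c("Qt11", "Qt12", "Qt21", "Qt22")) {
      blocks[[length(blocks) + 1L]] <- lmi_pd_block(vs, nm, pd_floor)
    }
  }
  blocks
}

.synthesis_error <- function(msg, status) {
  stop(errorCondition(paste0(msg, " (solver status: ", status, ")"),
                      class = c("fuzztrack_synthesis_error", "error")))
}

#' Solve the tracking-controller LMIs and recover the PDC gains
#'
#' Compiles the nr diagonal and nr(nr-1)/2 pair LMIs plus the
#' positive-definiteness constraints, solves the feasibility problem with
#' the interior-point barrier solver, recovers Ki = Yi X2^-1, gamma =
#' sqrt(gamma1+gamma2) and the tracking weight Q, and re-verifies all block
#' eigenvalues.
#'
#' @param pts [partition()]ed TS model
#' @param spec [controller_spec()]
#' @param objective `"feasibility"` (default, matching the theorem) or
#'   `"min_trace"` (adds trace(X1)+trace(X2) as a regularizing objective)
#' @param margin normalized feasibility margin passed to the solver
#' @param scaling state normalization used for the solve: a list with `t1`,
#'   `t2` (see [scale_partition()]), `NULL` for no scaling, or the default
#'   [default_scaling()] derived from the premise bounds. The Lyapunov
#'   variables, weights and certificates live in the normalized coordinates;
#'   the feedback gains `K` are returned in physical units (they multiply
#'   mg/l tracking errors).
#' @return object of class `controller_gains`: list with `X1`, `X2`, `Y`,
#'   `Kn` (2x2xnr, normalized coordinates), `K` (2x2xnr, physical units),
#'   `Qt` (list of the four 2x2 weights), `P` (4x4), `Q1`, `Q2`, `Q` (4x4),
#'   `gamma`, `scaling`, `spec`, `margins` (per-block max eigenvalues),
#'   `status`
#' @export
solve_controller <- function(pts, spec = controller_spec(),
                             objective = c("feasibility", "min_trace"),
                             margin = 1e-3, scaling = default_scaling(pts)) {
  objective <- match.arg(objective)
  nr <- pts$nr
  spts <- if (is.null(scaling)) pts else
    scale_partition(pts, scaling$t1, scaling$t2)
  sspec <- .spec_scaled(spec, scaling)
  vs <- .controller_varset(nr, spec$fix_Qtilde_identity)
  blocks <- .controller_blocks(spts, sspec, vs)
  if (objective == "feasibility") {
    sol <- lmi_feasibility(blocks, vs$nvar, margin = margin)
    if (sol$status != "feasible") {
      .synthesis_error("tracking-controller LMIs are infeasible or could not be solved to the requested margin",
                       sol$status)
    }
    x <- sol$x
  } else {
    cvec <- numeric(vs$nvar)
    for (nm in c("X1", "X2")) {
      d <- vs$vars[[nm]]
      diag_slots <- c(1L, 3L)  # (1,1) and (2,2) in lower-tri order for n=2
      cvec[d$offset + diag_slots] <- 1
    }
    sol <- lmi_minimize(blocks, vs$nvar, cvec, margin = margin)
    if (!sol$status %in% c("optimal", "max_outer")) {
      .synthesis_error("tracking-controller LMIs are infeasible or could not be solved",
                       sol$status)
    }
    x <- sol$x
  }
  vals <- lmi_vec_to_vals(vs, x)
  X1 <- vals$X1; X2 <- vals$X2
  Y <- array(0, c(2, 2, nr))
  Kn <- array(0, c(2, 2, nr))  # gains in normalized coordinates
  K <- array(0, c(2, 2, nr))   # gains acting on physical mg/l errors
  X2inv <- solve(X2)
  T2i <- if (is.null(scaling)) diag(2) else diag(1 / scaling$t2)
  for (i in seq_len(nr)) {
    Y[, , i] <- vals[[paste0("Y", i)]]
    Kn[, , i] <- Y[, , i] %*% X2inv
    K[, , i] <- Kn[, , i] %*% T2i
  }
  Qt <- if (spec$fix_Qtilde_identity) {
    list(Qt11 = diag(2), Qt12 = diag(2), Qt21 = diag(2), Qt22 = diag(2))
  } else {
    vals[c("Qt11", "Qt12", "Qt21", "Qt22")]
  }
  P1 <- solve(X1); P2 <- X2inv
  blkdiag <- function(a, b) rbind(cbind(a, matrix(0, 2, 2)),
                                  cbind(matrix(0, 2, 2), b))
  Q1 <- blkdiag(P1 %*% Qt$Qt11 %*% P1, P2 %*% Qt$Qt12 %*% P2)
  Q2 <- blkdiag(P1 %*% Qt$Qt21 %*% P1, P2 %*% Qt$Qt22 %*% P2)
  margins <- lmi_max_eigs(blocks, x)
  gains <- list(X1 = X1, X2 = X2, Y = Y, Kn = Kn, K = K, Qt = Qt,
                P = blkdiag(P1, P2), Q1 = Q1, Q2 = Q2, Q = Q1 + Q2,
                gamma = tracking_attenuation_level(spec$gamma1, spec$gamma2),
                scaling = scaling, spec = spec, margins = margins,
                status = sol$status, pts = pts)
  class(gains) <- "controller_gains"
  gains
}

# closed-loop block matrices of the augmented tracking system
.closed_loop_AD <- function(i, j, pts, spec, K) {
  A11 <- pts$A11[, , i]; A12 <- pts$A12[, , i]
  A21 <- pts$A21[, , i]; A22 <- pts$A22[, , i]
  B1 <- pts$B1[, , i]; B2 <- pts$B2[, , i]
  Kj <- K[, , j]
  Z <- matrix(0, 2, 2); I2 <- diag(2)
  Aij <- rbind(cbind(A11, A12 + B1 %*% Kj),
               cbind(A21, A22 + B2 %*% Kj))
  Dij <- rbind(cbind(-B1 %*% Kj, A12, Z, I2, Z),
               cbind(-B2 %*% Kj, A22 - spec$Ar, -I2, Z, I2))
  list(A = Aij, D = Dij)
}

#' Verify the closed-loop tracking certificate by direct eigenvalue checks
#'
#' Rebuilds P = blockdiag(X1^-1, X2^-1), the closed-loop blocks and the
#' pre-relaxation quadratic conditions (diagonal:
#' A'P + PA + Q1 + alpha1^-1 P D D' P < 0; pairs: the symmetrized, halved
#' analogue with Q2 and alpha2), and reports the worst eigenvalue. This is
#' an independent cross-check that the congruence/Schur-complement chain
#' behind the solved LMIs was assembled correctly.
#'
#' The check runs in the same normalized coordinates the gains were
#' synthesized in (see [scale_partition()]); the certified inequality is the
#' energy bound for the normalized signals.
#'
#' @param gains [solve_controller()] result (or any `controller_gains`)
#' @param pts [partition()]ed TS model (unscaled; the scaling stored in
#'   `gains` is applied internally)
#' @param spec [controller_spec()]; defaults to the spec stored in `gains`
#' @return list with `pass`, `worst_single`, `worst_pair` (maximum
#'   eigenvalues over the two condition families) and per-condition vectors
#' @export
verify_certificate <- function(gains, pts, spec = gains$spec) {
  nr <- pts$nr
  if (!is.null(gains$scaling)) {
    pts <- scale_partition(pts, gains$scaling$t1, gains$scaling$t2)
    spec <- .spec_scaled(spec, gains$scaling)
  }
  P <- gains$P
  single <- numeric(nr)
  for (i in seq_len(nr)) {
    cl <- .closed_loop_AD(i, i, pts, spec, gains$Kn)
    M <- t(cl$A) %*% P + P %*% cl$A + gains$Q1 +
      (1 / spec$alpha1) * P %*% cl$D %*% t(cl$D) %*% P
    single[i] <- max(eigen(0.5 * (M + t(M)), symmetric = TRUE,
                           only.values = TRUE)$values)
  }
  np <- nr * (nr - 1) / 2
  pair <- numeric(np)
  k <- 0
  for (i in seq_len(max(nr - 1, 0))) {
    for (j in seq(i + 1, nr)) {
      cij <- .closed_loop_AD(i, j, pts, spec, gains$Kn)
      cji <- .closed_loop_AD(j, i, pts, spec, gains$Kn)
      A <- cij$A + cji$A
      D <- cij$D + cji$D
      M <- 0.5 * (t(A) %*% P + P %*% A + gains$Q2 +
                    (1 / spec$alpha2) * P %*% D %*% t(D) %*% P)
      k <- k + 1
      pair[k] <- max(eigen(0.5 * (M + t(M)), symmetric = TRUE,
                           only.values = TRUE)$values)
    }
  }
  worst_single <- max(single)
  worst_pair <- if (np > 0) max(pair) else -Inf
  list(pass = worst_single < 0 && worst_pair < 0,
       worst_single = worst_single, worst_pair = worst_pair,
       single = single, pair = pair)
}
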