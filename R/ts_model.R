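#' Operating domain for the sector-nonlinearity construction
#'
#' Box bounds on the four concentrations over which the exact TS
#' representation is built. The default brackets the closed-loop operating
#' equilibria of the benchmark set-point schedule: at steady state the
#' settler balance pins Xr/X = (1+qr)/(beta+qr) = 2 and the substrate
#' balance gives X* = Y (Sin - (1+qr) S*) / ((1+qr) beta / (beta+qr)),
#' i.e. X* between roughly 165 and 220 mg/l for set-points S* in 45-60
#' mg/l, so the biomass boxes span those equilibria with generous transient
#' margin. The substrate and dissolved-oxygen boxes cover the set-point
#' schedule plus disturbance excursions. The dissolved-oxygen lower bound
#' is kept strictly positive because one premise variable has the form
#' mu*X/Co (finite as Co -> 0 and evaluated in a singularity-free product
#' form, but bounded away from the degenerate corner).
#'
#' @param X,Xr,S,Co numeric length-2 vectors c(lower, upper), mg/l
#' @return object of class `operating_domain`
#' @export
operating_domain <- function(X = c(120, 300), Xr = c(240, 600),
                             S = c(25, 90), Co = c(0.5, 9)) {
  dom <- list(X = X, Xr = Xr, S = S, Co = Co)
  for (nm in names(dom)) {
    b <- dom[[nm]]
    if (length(b) != 2 || any(!is.finite(b)) || b[1] >= b[2] || b[1] < 0) {
      stop("operating_domain: bounds for ", nm,
           " must be finite, non-negative and lower < upper")
    }
  }
  class(dom) <- "operating_domain"
  dom
}

#' Premise variables of the activated-sludge TS model
#'
#' Six scalar nonlinearities whose bound combinations generate the exact TS
#' representation (state order X, Xr, S, Co; mu is the double-Monod law):
#' z1 = mu(S,Co) - S, z2 = X, z3 = Xr, z4 = Co,
#' z5 = mumax*S*X / ((Ks+S)(Kc+Co))  (equal to mu*X/Co for Co > 0),
#' z6 = S.
#'
#' @param x state vector (X, Xr, S, Co)
#' @param p [asp_parameters()]
#' @return numeric premise vector z of length 6
#' @export
premise_eval <- function(x, p = asp_parameters()) {
  X <- x[[1]]; Xr <- x[[2]]; S <- x[[3]]; Co <- x[[4]]
  mu <- growth_rate(S, Co, p)
  c(z1 = mu - S,
    z2 = X,
    z3 = Xr,
    z4 = Co,
    z5 = p$mumax * S * X / ((p$Ks + S) * (p$Kc + Co)),
    z6 = S)
}

#' Nonlinear state-space matrices in premise form
#'
#' Factorization of the activated-sludge dynamics as
#' xdot = A(z) x + B(z) u + G d with z the premise vector, satisfying
#' A(z(x)) x + B(z(x)) u + G*D*delta_sin == [plant_rhs()] identically on the
#' non-negative orthant (Co > 0). Row by row: the biomass reaction is
#' (mu - S)X + X*S = mu*X; the recycled-biomass row carries the canceling
#' pair -Co*Xr + Xr*Co = 0, which supplies the strictly stable diagonal the
#' vertex models need; the substrate and oxygen reactions are carried by z5
#' (z5*Co = mu*X).
#'
#' A sector factorization is not unique, and the two synthesis problems pull
#' in opposite directions, so two exact variants are provided:
#' `"coupled"` adds the zero-sum pair -Xr*X + X*Xr = 0 to the oxygen row
#' (entries -z3, z2). That pair couples the biomass states into the measured
#' dissolved-oxygen row, without which no vertex model is observable from
#' the Co measurement alone -- the observer synthesis needs it.
#' `"tracking"` omits the pair: its state-magnitude entries inflate the
#' uncontrolled-block couplings of every vertex model in a way no shared
#' Lyapunov variable can absorb, which renders the tracking-synthesis LMIs
#' weakly infeasible (the feasibility margin approaches zero from below but
#' never attains it). Both variants reproduce the plant dynamics exactly;
#' they differ only in how the zero reaction term of the oxygen row is
#' distributed.
#'
#' @param z premise vector from [premise_eval()]
#' @param p [asp_parameters()]
#' @param factorization `"coupled"` (the observer-oriented form) or
#'   `"tracking"` (the controller-oriented form)
#' @return list with `A` (4x4) and `B` (4x2)
#' @export
nonlinear_matrices <- function(z, p = asp_parameters(),
                               factorization = c("coupled", "tracking")) {
  factorization <- match.arg(factorization)
  z1 <- z[[1]]; z2 <- z[[2]]; z3 <- z[[3]]
  z4 <- z[[4]]; z5 <- z[[5]]; z6 <- z[[6]]
  a41 <- if (factorization == "coupled") -z3 else 0
  a42 <- if (factorization == "coupled") z2 else 0
  A <- matrix(c(
    z1,   0,  z2,  0,
    0,  -z4,   0,  z3,
    0,    0,   0, -z5 / p$Y,
    a41, a42,  0, -p$K0 * z5 / p$Y), 4, 4, byrow = TRUE)
  B <- matrix(c(
    -(1 + p$qr) * z2 + p$qr * z3,          0,
    (1 + p$qr) * z2 - (p$beta + p$qr) * z3, 0,
    p$Sin - (1 + p$qr) * z6,               0,
    p$Coin - (1 + p$qr) * z4,              p$Cs - z4), 4, 2, byrow = TRUE)
  dimnames(A) <- list(c("X", "Xr", "S", "Co"), c("X", "Xr", "S", "Co"))
  dimnames(B) <- list(c("X", "Xr", "S", "Co"), c("D", "KLa"))
  list(A = A, B = B)
}

#' Disturbance input column of the TS model (enters the substrate balance)
#' @return 4x1 numeric matrix (0, 0, 1, 0)^T
#' @export
ts_G <- function() matrix(c(0, 0, 1, 0), 4, 1)

#' Output row of the TS model (dissolved oxygen is the measured output)
#' @return 1x4 numeric matrix (0, 0, 0, 1)
#' @export
ts_C <- function() matrix(c(0, 0, 0, 1), 1, 4)

#' Bounds of the premise variables over an operating domain
#'
#' Identity premises (z2 = X, z3 = Xr, z4 = Co, z6 = S) inherit the state
#' bounds. The two genuinely nonlinear premises are bounded by dense grid
#' evaluation: z1 = mu(S,Co) - S on an (S, Co) grid, and z5 = X * f(S,Co)
#' with f = mumax*S/((Ks+S)(Kc+Co)) > 0, whose range over the box is
#' [X_lo * min f, X_hi * max f]. Both grid ranges are widened by a relative
#' safety margin so the reported intervals enclose the true range.
#'
#' @param dom [operating_domain()]
#' @param p [asp_parameters()]
#' @param n_grid grid points per axis for the nonlinear premises
#' @param margin relative safety margin (fraction of the grid range added on
#'   each side)
#' @return object of class `premise_bounds`: 6x2 matrix (min, max) with rows
#'   z1..z6
#' @export
premise_bounds <- function(dom, p = asp_parameters(), n_grid = 200,
                           margin = 0.01) {
  S <- seq(dom$S[1], dom$S[2], length.out = n_grid)
  Co <- seq(dom$Co[1], dom$Co[2], length.out = n_grid)
  g <- expand.grid(S = S, Co = Co)
  mu <- growth_rate(g$S, g$Co, p)
  z1 <- mu - g$S
  f <- p$mumax * g$S / ((p$Ks + g$S) * (p$Kc + g$Co))
  widen <- function(lo, hi) {
    w <- margin * (hi - lo)
    c(lo - w, hi + w)
  }
  b <- rbind(
    z1 = widen(min(z1), max(z1)),
    z2 = c(dom$X[1], dom$X[2]),
    z3 = c(dom$Xr[1], dom$Xr[2]),
    z4 = c(dom$Co[1], dom$Co[2]),
    z5 = widen(dom$X[1] * min(f), dom$X[2] * max(f)),
    z6 = c(dom$S[1], dom$S[2]))
  colnames(b) <- c("min", "max")
  class(b) <- c("premise_bounds", class(b))
  b
}

#' Collapse selected premises to a degenerate (point) interval
#'
#' Fixing a premise at the midpoint of its interval halves the number of
#' vertex models per collapsed premise; used for a reduced synthesis mode
#' (e.g. collapsing z2, z3, z4 gives 2^3 = 8 submodels). The TS
#' representation is then exact only on the corresponding slice of the
#' domain.
#'
#' @param bounds [premise_bounds()]
#' @param which integer indices in 1..6 of premises to collapse
#' @return modified `premise_bounds`
#' @export
collapse_premises <- function(bounds, which = c(2, 3, 4)) {
  for (j in which) {
    m <- mean(bounds[j, ])
    bounds[j, ] <- c(m, m)
  }
  bounds
}

#' Build the vertex models of the TS representation
#'
#' One linear submodel per combination of each non-degenerate premise at its
#' lower or upper bound. Vertex enumeration is deterministic: premise j is
#' the fastest-varying bit (bit 0 = premise with the smallest index among
#' the non-degenerate ones), bit value 0 selects the lower bound.
#'
#' @param bounds [premise_bounds()]
#' @param p [asp_parameters()]
#' @param factorization passed to [nonlinear_matrices()]: `"coupled"` for
#'   observer design, `"tracking"` for controller design
#' @return object of class `ts_model`: list with `nr`, arrays `A` (4x4xnr)
#'   and `B` (4x2xnr), `G` (4x1), `C` (1x4), `bounds`, logical `nondeg`
#'   (length 6), `vertex_map` (nr x 6 matrix, 0 = lower bound, 1 = upper;
#'   degenerate premises marked 0) and `factorization`
#' @export
build_vertex_models <- function(bounds, p = asp_parameters(),
                                factorization = c("coupled", "tracking")) {
  factorization <- match.arg(factorization)
  nondeg <- bounds[, 2] > bounds[, 1]
  idx <- which(nondeg)
  nr <- as.integer(2^length(idx))
  vertex_map <- matrix(0L, nr, 6)
  for (k in seq_along(idx)) {
    vertex_map[, idx[k]] <- bitwAnd(seq_len(nr) - 1L, bitwShiftL(1L, k - 1L)) > 0L
  }
  A <- array(0, c(4, 4, nr))
  B <- array(0, c(4, 2, nr))
  for (i in seq_len(nr)) {
    z <- ifelse(vertex_map[i, ] == 1L, bounds[, 2], bounds[, 1])
    m <- nonlinear_matrices(z, p, factorization)
    A[, , i] <- m$A
    B[, , i] <- m$B
  }
  ts <- list(nr = nr, A = A, B = B, G = ts_G(), C = ts_C(),
             bounds = bounds, nondeg = nondeg, vertex_map = vertex_map,
             params = p, factorization = factorization)
  class(ts) <- "ts_model"
  ts
}

#' Membership weights of the TS model
#'
#' Product-form sector weights: for each non-degenerate premise j the lower
#' vertex receives weight (zj_max - zj)/(zj_max - zj_min) and the upper
#' vertex its complement; a submodel's weight is the product over premises
#' according to the vertex map. Premise values outside their bounds are
#' clipped first, so the weights always lie on the probability simplex.
#'
#' @param z premise vector (length 6)
#' @param bounds [premise_bounds()]
#' @return numeric vector h of length nr, non-negative, summing to one
#' @export
membership <- function(z, bounds) {
  nondeg <- bounds[, 2] > bounds[, 1]
  idx <- which(nondeg)
  h <- 1
  for (k in seq_along(idx)) {
    j <- idx[k]
    zj <- min(max(z[[j]], bounds[j, 1]), bounds[j, 2])
    w_lo <- (bounds[j, 2] - zj) / (bounds[j, 2] - bounds[j, 1])
    # bit k-1 of the vertex index selects lower (0) or upper (1) bound
    h <- as.vector(outer(h, c(w_lo, 1 - w_lo)))
  }
  h
}

#' Blend the vertex models with membership weights
#'
#' Returns sum_i h_i A_i and sum_i h_i B_i; with h = membership(z) this
#' reconstructs A(z), B(z) exactly for in-domain z (convexity of the sector
#' construction).
#'
#' @param ts [build_vertex_models()]
#' @param h membership vector
#' @return list with blended `A` (4x4) and `B` (4x2)
#' @export
blend_matrices <- function(ts, h) {
  n <- ts$nr
  A <- matrix(matrix(ts$A, 16, n) %*% h, 4, 4)
  B <- matrix(matrix(ts$B, 8, n) %*% h, 4, 2)
  list(A = A, B = B)
}

#' Partition the TS model for reduced-order tracking design
#'
#' Splits the state as x1 = (X, Xr) (uncontrolled part) and x2 = (S, Co)
#' (controlled part) and slices every vertex matrix conformably:
#' Ai = [Ai11 Ai12; Ai21 Ai22], Bi = [Bi1; Bi2], G = [G1; G2].
#'
#' @param ts [build_vertex_models()]
#' @return object of class `partitioned_ts`: arrays `A11`, `A12`, `A21`,
#'   `A22` (2x2xnr), `B1`, `B2` (2x2xnr), `G1`, `G2` (2x1), `nr`
#' @export
partition <- function(ts) {
  i1 <- 1:2; i2 <- 3:4
  pts <- list(nr = ts$nr,
              A11 = ts$A[i1, i1, , drop = FALSE],
              A12 = ts$A[i1, i2, , drop = FALSE],
              A21 = ts$A[i2, i1, , drop = FALSE],
              A22 = ts$A[i2, i2, , drop = FALSE],
              B1 = ts$B[i1, , , drop = FALSE],
              B2 = ts$B[i2, , , drop = FALSE],
              G1 = ts$G[i1, , drop = FALSE],
              G2 = ts$G[i2, , drop = FALSE],
              bounds = ts$bounds)
  class(pts) <- "partitioned_ts"
  pts
}

#' Draw uniform random states inside an operating domain
#'
#' @param n number of states
#' @param dom [operating_domain()]
#' @return n x 4 matrix with columns X, Xr, S, Co
#' @export
sample_domain <- function(n, dom = operating_domain()) {
  m <- cbind(X = stats::runif(n, dom$X[1], dom$X[2]),
             Xr = stats::runif(n, dom$Xr[1], dom$Xr[2]),
             S = stats::runif(n, dom$S[1], dom$S[2]),
             Co = stats::runif(n, dom$Co[1], dom$Co[2]))
  m
}
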