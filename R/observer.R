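#' Disturbance-augmented TS system
#'
#' Appends the (slowly varying) disturbance d as a fifth state with zero
#' nominal dynamics: for each submodel Abar_i = [Ai G; 0 0] (5x5),
#' Bbar_i = [Bi; 0] (5x2), Cbar = [C 0] = (0,0,0,1,0). The observer built on
#' this system estimates the four concentrations and d jointly from the
#' dissolved-oxygen measurement.
#'
#' @param ts [build_vertex_models()]
#' @return object of class `augmented_ts`: list with `nr`, `Abar` (5x5xnr),
#'   `Bbar` (5x2xnr), `Cbar` (1x5)
#' @export
augment <- function(ts) {
  nr <- ts$nr
  Abar <- array(0, c(5, 5, nr))
  Bbar <- array(0, c(5, 2, nr))
  for (i in seq_len(nr)) {
    Abar[1:4, 1:4, i] <- ts$A[, , i]
    Abar[1:4, 5, i] <- ts$G
    Bbar[1:4, , i] <- ts$B[, , i]
  }
  aug <- list(nr = nr, Abar = Abar, Bbar = Bbar,
              Cbar = cbind(ts$C, 0))
  class(aug) <- "augmented_ts"
  aug
}

#' Observer synthesis settings
#'
#' @param nu prescribed attenuation level (> 0); required when
#'   `mode = "prescribed"`, ignored in `"min_eta"` mode
#' @param mode `"min_eta"` (default): minimize the scalar eta entering the
#'   observer LMIs and report nu_effective = sqrt(eta); `"prescribed"`: pure
#'   feasibility with the additional constraint eta < nu^2. Without a
#'   normalization the minimum of eta is scale-degenerate (scaling Po, Zi, R
#'   and eta jointly preserves feasibility), hence the error-weight floor
#'   R >= I below.
#' @param R_identity if `TRUE`, fix R = I instead of leaving it a decision
#'   variable bounded below by the identity
#' @param eps strictness margin for the strict inequalities
#' @return object of class `observer_spec`
#' @export
observer_spec <- function(nu = NULL, mode = c("min_eta", "prescribed"),
                          R_identity = FALSE, eps = 1e-6) {
  mode <- match.arg(mode)
  if (mode == "prescribed") {
    if (is.null(nu) || nu <= 0) {
      stop("observer_spec: prescribed mode requires nu > 0")
    }
  }
  sp <- list(nu = nu, mode = mode, R_identity = R_identity, eps = eps)
  class(sp) <- "observer_spec"
  sp
}

#' Assemble one observer LMI block
#'
#' The 10x10 symmetric matrix
#' `[sym(Po Abar_i - Zi Cbar) + R, Po; Po, -eta I]` whose strict negativity
#' for every submodel, together with eta < nu^2, certifies the observer's
#' H-infinity error attenuation.
#'
#' @param i submodel index
#' @param aug [augment()]ed TS system
#' @param vals named list with `Po` (5x5 symmetric), `R` (5x5 symmetric),
#'   `Z<i>` (5x1) and `eta` (scalar)
#' @return symmetric 10x10 numeric matrix
#' @export
assemble_observer_lmi <- function(i, aug, vals) {
  if (i < 1 || i > aug$nr) stop("submodel index out of range")
  Po <- vals$Po
  R <- vals$R
  Zi <- vals[[paste0("Z", i)]]
  T11 <- Po %*% aug$Abar[, , i] - Zi %*% aug$Cbar
  rbind(cbind(T11 + t(T11) + R, Po),
        cbind(Po, -vals$eta * diag(5)))
}

.observer_varset <- function(nr, R_fixed) {
  decls <- list(Po = lmi_sym(5))
  if (!R_fixed) decls$R <- lmi_sym(5)
  for (i in seq_len(nr)) decls[[paste0("Z", i)]] <- lmi_mat(5, 1)
  decls$eta <- lmi_scalar()
  do.call(lmi_varset, decls)
}

.observer_blocks <- function(aug, spec, vs) {
  nr <- aug$nr
  blocks <- vector("list", 0)
  for (i in seq_len(nr)) {
    loc <- c("Po", if (!spec$R_identity) "R", paste0("Z", i), "eta")
    f <- local({
      ii <- i
      function(vals) {
        if (spec$R_identity) vals$R <- diag(5)
        assemble_observer_lmi(ii, aug, vals)
      }
    })
    blocks[[length(blocks) + 1L]] <- lmi_compile_block(f, vs, loc,
                                                       eps = spec$eps)
  }
  blocks[[length(blocks) + 1L]] <- lmi_pd_block(vs, "Po", 1e-8)
  if (!spec$R_identity) {
    # prescribed mode only needs R > 0; the identity floor is the scale
    # normalization that makes minimizing eta well posed
    R_floor <- if (spec$mode == "min_eta") diag(5) else diag(1e-6, 5)
    blocks[[length(blocks) + 1L]] <- lmi_pd_block(vs, "R", R_floor)
  }
  if (spec$mode == "prescribed") {
    # eta - nu^2 < 0 as a 1x1 block
    f <- function(vals) matrix(vals$eta - spec$nu^2, 1, 1)
    blocks[[length(blocks) + 1L]] <- lmi_compile_block(f, vs, "eta",
                                                       eps = spec$eps)
  }
  blocks
}

#' Solve the observer LMIs and recover the fuzzy Luenberger gains
#'
#' Solves the nr observer LMIs (plus Po > 0, R >= I and, in prescribed
#' mode, eta < nu^2), recovers Li = Po^-1 Zi, and re-verifies both the block
#' eigenvalues and that every error matrix Abar_i - Li Cbar is Hurwitz.
#'
#' @param aug [augment()]ed TS system
#' @param spec [observer_spec()]
#' @param margin normalized feasibility margin passed to the solver
#' @return object of class `observer_gains`: list with `Po`, `R`, `Z`
#'   (5x1xnr), `L` (5x1xnr), `eta`, `nu_effective = sqrt(eta)`, `spec`,
#'   `margins`, `status`
#' @export
solve_observer <- function(aug, spec = observer_spec(), margin = 1e-3) {
  nr <- aug$nr
  vs <- .observer_varset(nr, spec$R_identity)
  blocks <- .observer_blocks(aug, spec, vs)
  if (spec$mode == "min_eta") {
    cvec <- numeric(vs$nvar)
    cvec[.lmi_slots(vs, "eta")] <- 1
    sol <- lmi_minimize(blocks, vs$nvar, cvec, margin = margin)
    if (!sol$status %in% c("optimal", "max_outer")) {
      .synthesis_error("observer LMIs are infeasible or could not be solved",
                       sol$status)
    }
  } else {
    sol <- lmi_feasibility(blocks, vs$nvar, margin = margin)
    if (sol$status != "feasible") {
      .synthesis_error("observer LMIs are infeasible at the prescribed attenuation level",
                       sol$status)
    }
  }
  vals <- lmi_vec_to_vals(vs, sol$x)
  if (spec$R_identity) vals$R <- diag(5)
  Po <- vals$Po
  Poinv <- solve(Po)
  Z <- array(0, c(5, 1, nr)); L <- array(0, c(5, 1, nr))
  for (i in seq_len(nr)) {
    Z[, , i] <- vals[[paste0("Z", i)]]
    L[, , i] <- Poinv %*% Z[, , i]
  }
  eta <- as.numeric(vals$eta)
  hurwitz <- vapply(seq_len(nr), function(i) {
    E <- aug$Abar[, , i] - L[, , i] %*% aug$Cbar
    max(Re(eigen(E, only.values = TRUE)$values)) < 0
  }, logical(1))
  if (!all(hurwitz)) {
    .synthesis_error("solved observer gains leave a non-Hurwitz error matrix",
                     sol$status)
  }
  gains <- list(Po = Po, R = vals$R, Z = Z, L = L, eta = eta,
                nu_effective = sqrt(eta), spec = spec,
                margins = lmi_max_eigs(blocks, sol$x), status = sol$status)
  class(gains) <- "observer_gains"
  gains
}

#' Verify the observer certificate by direct eigenvalue checks
#'
#' Re-checks the pre-Schur quadratic condition
#' (Abar_i - Li Cbar)' Po + Po (Abar_i - Li Cbar) + R + eta^-1 Po Po < 0 for
#' every submodel, plus the Hurwitz property of each error matrix. Together
#' with the solved 10x10 LMIs this exercises the Schur-complement
#' equivalence numerically.
#'
#' @param gains [solve_observer()] result
#' @param aug [augment()]ed TS system
#' @return list with `pass`, `worst` (maximum eigenvalue over submodels),
#'   `cond` (per-submodel maximum eigenvalues), `hurwitz` (logical vector)
#' @export
verify_observer_certificate <- function(gains, aug) {
  nr <- aug$nr
  cond <- numeric(nr)
  hurwitz <- logical(nr)
  for (i in seq_len(nr)) {
    E <- aug$Abar[, , i] - gains$L[, , i] %*% aug$Cbar
    M <- t(E) %*% gains$Po + gains$Po %*% E + gains$R +
      (1 / gains$eta) * gains$Po %*% gains$Po
    cond[i] <- max(eigen(0.5 * (M + t(M)), symmetric = TRUE,
                         only.values = TRUE)$values)
    hurwitz[i] <- max(Re(eigen(E, only.values = TRUE)$values)) < 0
  }
  list(pass = max(cond) < 0 && all(hurwitz), worst = max(cond),
       cond = cond, hurwitz = hurwitz)
}
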