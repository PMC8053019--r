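## Small modelling layer over the compiled interior-point LMI solver.
## Decision variables (symmetric matrices, rectangular matrices, scalars) are
## flattened into one scalar vector; each affine matrix-inequality block is
## compiled to (F0, variable indices, basis matrices) by probing an R
## assembly function at unit values, which keeps the R-side assembly code a
## literal transcription of the printed block layouts.

#' Declare a set of LMI decision variables
#'
#' @param ... named declarations, each created by [lmi_sym()], [lmi_mat()]
#'   or [lmi_scalar()]
#' @return object of class `lmi_varset`
#' @export
lmi_varset <- function(...) {
  decls <- list(...)
  if (is.null(names(decls)) || any(names(decls) == "")) {
    stop("all LMI variables must be named")
  }
  offset <- 0L
  for (nm in names(decls)) {
    d <- decls[[nm]]
    d$offset <- offset
    decls[[nm]] <- d
    offset <- offset + d$nslots
  }
  vs <- list(vars = decls, nvar = offset)
  class(vs) <- "lmi_varset"
  vs
}

#' @rdname lmi_varset
#' @param n matrix order
#' @export
lmi_sym <- function(n) list(type = "sym", dim = c(n, n),
                            nslots = as.integer(n * (n + 1) / 2))

#' @rdname lmi_varset
#' @param r,c matrix dimensions
#' @export
lmi_mat <- function(r, c) list(type = "mat", dim = c(r, c),
                               nslots = as.integer(r * c))

#' @rdname lmi_varset
#' @export
lmi_scalar <- function() list(type = "scalar", dim = c(1, 1), nslots = 1L)

# indices of the lower triangle (column-major) of an n x n matrix
.lt_index <- function(n) which(lower.tri(matrix(0, n, n), diag = TRUE))

#' Zero-valued template for every variable in a varset
#' @param vs [lmi_varset()]
#' @return named list of zero matrices / scalars
#' @export
lmi_zero_vals <- function(vs) {
  lapply(vs$vars, function(d) {
    if (d$type == "scalar") 0 else matrix(0, d$dim[1], d$dim[2])
  })
}

#' Map a flat solver vector to named variable values
#' @param vs [lmi_varset()]
#' @param x numeric vector of length `vs$nvar`
#' @return named list of matrices / scalars
#' @export
lmi_vec_to_vals <- function(vs, x) {
  vals <- lmi_zero_vals(vs)
  for (nm in names(vs$vars)) {
    d <- vs$vars[[nm]]
    xs <- x[d$offset + seq_len(d$nslots)]
    if (d$type == "scalar") {
      vals[[nm]] <- xs
    } else if (d$type == "mat") {
      vals[[nm]] <- matrix(xs, d$dim[1], d$dim[2])
    } else {
      n <- d$dim[1]
      M <- matrix(0, n, n)
      M[.lt_index(n)] <- xs
      M <- M + t(M) - diag(diag(M), n)
      vals[[nm]] <- M
    }
  }
  vals
}

# global scalar-slot indices of one variable
.lmi_slots <- function(vs, name) {
  d <- vs$vars[[name]]
  if (is.null(d)) stop("unknown LMI variable: ", name)
  d$offset + seq_len(d$nslots)
}

# values with a single scalar slot of `name` set to one (symmetric slots set
# the mirrored entry too, matching the symmetric parametrization)
.lmi_unit_vals <- function(vs, name, slot) {
  vals <- lmi_zero_vals(vs)
  d <- vs$vars[[name]]
  if (d$type == "scalar") {
    vals[[name]] <- 1
  } else if (d$type == "mat") {
    M <- vals[[name]]
    M[slot] <- 1
    vals[[name]] <- M
  } else {
    n <- d$dim[1]
    M <- vals[[name]]
    M[.lt_index(n)[slot]] <- 1
    M <- M + t(M) - diag(diag(M), n)
    vals[[name]] <- M
  }
  vals
}

#' Compile an affine matrix-valued assembly function into solver form
#'
#' @param f function(vals) returning a symmetric numeric matrix, affine in
#'   the variable values
#' @param vs [lmi_varset()]
#' @param local character vector of the variable names `f` actually uses
#' @param eps strictness margin: the compiled block encodes F(x) + eps*I <= 0
#' @return list with `F0`, `vidx`, `bases` as consumed by the compiled solver
#' @export
lmi_compile_block <- function(f, vs, local, eps = 0) {
  F0 <- f(lmi_zero_vals(vs))
  F0 <- 0.5 * (F0 + t(F0))
  vidx <- integer(0)
  bas <- list()
  for (nm in local) {
    d <- vs$vars[[nm]]
    for (s in seq_len(d$nslots)) {
      Ai <- f(.lmi_unit_vals(vs, nm, s)) - F0
      Ai <- 0.5 * (Ai + t(Ai))
      vidx <- c(vidx, d$offset + s)
      bas[[length(bas) + 1L]] <- Ai
    }
  }
  n <- nrow(F0)
  bases <- array(unlist(bas), c(n, n, length(bas)))
  list(F0 = F0 + diag(eps, n), vidx = as.integer(vidx), bases = bases)
}

#' Compile a positive-definiteness constraint `X >= floor` (matrix sense)
#'
#' Encoded as floor - X <= 0 (with the solver-wide strictness margin applied
#' like any other block).
#'
#' @param vs [lmi_varset()]
#' @param name symmetric variable name
#' @param floor numeric matrix (or scalar multiple of identity) lower bound
#' @return compiled block
#' @export
lmi_pd_block <- function(vs, name, floor = 0) {
  d <- vs$vars[[name]]
  n <- d$dim[1]
  Fl <- if (is.matrix(floor)) floor else diag(floor, n)
  f <- function(vals) Fl - vals[[name]]
  lmi_compile_block(f, vs, name)
}

# divide each block by max(1, inf-norm of its fixed part) so that the
# phase-I slack is commensurate across blocks
.lmi_normalize <- function(blocks) {
  lapply(blocks, function(b) {
    s <- max(1, max(abs(b$F0)))
    b$F0 <- b$F0 / s
    b$bases <- b$bases / s
    b
  })
}

# box bounds |x_j| <= M as 1x1 blocks; they give the barrier an analytic
# center (the bare log-det barrier is unbounded along directions that expand
# every cone) and keep iterates at representable magnitudes
.lmi_box_blocks <- function(nvar, M) {
  out <- vector("list", 2L * nvar)
  for (j in seq_len(nvar)) {
    out[[2L * j - 1L]] <- list(F0 = matrix(-M, 1, 1), vidx = j,
                               bases = array(1, c(1, 1, 1)))
    out[[2L * j]] <- list(F0 = matrix(-M, 1, 1), vidx = j,
                          bases = array(-1, c(1, 1, 1)))
  }
  out
}

# append the phase-I slack variable (identity basis, index nvar+1)
.lmi_add_slack <- function(blocks, nvar) {
  lapply(blocks, function(b) {
    n <- nrow(b$F0)
    nb <- dim(b$bases)[3]
    bases <- array(0, c(n, n, nb + 1L))
    if (nb > 0) bases[, , seq_len(nb)] <- b$bases
    bases[, , nb + 1L] <- diag(n)
    b$bases <- bases
    b$vidx <- c(b$vidx, nvar + 1L)
    b
  })
}

#' Solve an LMI feasibility problem
#'
#' Finds x with F_k(x) strictly negative definite for all compiled blocks by
#' maximizing a common (normalized) negativity margin t with F_k(x) <= -t*I
#' using an interior-point barrier method, stopping once t is safely
#' positive.
#'
#' @param blocks list of compiled blocks (see [lmi_compile_block()])
#' @param nvar total number of scalar decision variables
#' @param x0 optional warm start (default zero)
#' @param margin stop once the normalized margin t exceeds `margin`
#' @param tol_gap barrier duality-gap tolerance used to declare
#'   infeasibility when the slack cannot be driven negative
#' @param box bound M on every scalar decision variable (|x_j| <= M),
#'   required for the barrier to have an analytic center; choose well above
#'   the expected solution magnitude
#' @param max_outer,max_newton iteration limits of the barrier method
#' @return list with `x`, `slack` (achieved normalized margin t), `status`
#'   (`"feasible"`, `"infeasible"` or `"inaccurate"`), `newton_iters`
#' @export
lmi_feasibility <- function(blocks, nvar, x0 = NULL, margin = 1e-3,
                            tol_gap = 1e-6, box = 1e9, max_outer = 60,
                            max_newton = 80) {
  nb <- .lmi_normalize(c(blocks, .lmi_box_blocks(nvar, box)))
  nb <- .lmi_add_slack(nb, nvar)
  if (is.null(x0)) x0 <- numeric(nvar)
  # constraints become F_k(x) + t*I <= 0, i.e. F_k(x) <= -t*I: maximize t
  # (minimize -t); t > 0 certifies strict feasibility of the original system
  t0 <- -(max(.lmi_maxeig_cpp(nb, c(x0, 0))) + 1)
  # floor the slack at its start: without it the first (low-tau) centering
  # drags t far negative just to inflate the barrier volume, and the path
  # then needs hundreds of Newton steps to crawl back
  floor_blk <- list(F0 = matrix(t0 - 1, 1, 1), vidx = nvar + 1L,
                    bases = array(-1, c(1, 1, 1)))
  res <- .lmi_barrier_cpp(c(nb, list(floor_blk)), nvar + 1L,
                          c = c(numeric(nvar), -1),
                          x0 = c(x0, t0),
                          tau0 = 1, mu = 10, tol_gap = tol_gap,
                          max_outer = max_outer, max_newton = max_newton,
                          early_stop_obj = -margin)
  slack <- res$x[nvar + 1L]
  status <- if (slack >= margin / 2) "feasible"
            else if (res$status == "optimal" && slack <= 0) "infeasible"
            else "inaccurate"
  list(x = as.vector(res$x)[seq_len(nvar)], slack = slack, status = status,
       solver_status = res$status, newton_iters = res$newton_iters)
}

#' Minimize a linear objective subject to LMI constraints
#'
#' Phase I ([lmi_feasibility()]) followed by barrier path following on the
#' objective from the strictly feasible start.
#'
#' @inheritParams lmi_feasibility
#' @param cvec objective coefficient vector (length `nvar`)
#' @param tol_gap absolute duality-gap tolerance on the objective
#' @return list with `x`, `obj`, `status`, `newton_iters`
#' @export
lmi_minimize <- function(blocks, nvar, cvec, x0 = NULL, margin = 1e-3,
                         tol_gap = 1e-5, box = 1e9, max_outer = 60,
                         max_newton = 80) {
  ph1 <- lmi_feasibility(blocks, nvar, x0 = x0, margin = margin, box = box,
                         max_outer = max_outer, max_newton = max_newton)
  if (ph1$status != "feasible") {
    return(list(x = ph1$x, obj = NA_real_, status = ph1$status,
                newton_iters = ph1$newton_iters))
  }
  nb <- .lmi_normalize(c(blocks, .lmi_box_blocks(nvar, box)))
  res <- .lmi_barrier_cpp(nb, nvar, c = cvec, x0 = ph1$x,
                          tau0 = 1, mu = 10, tol_gap = tol_gap,
                          max_outer = max_outer, max_newton = max_newton,
                          early_stop_obj = NA_real_)
  status <- if (res$status == "optimal") "optimal" else res$status
  list(x = as.vector(res$x), obj = res$obj, status = status,
       newton_iters = ph1$newton_iters + res$newton_iters)
}

#' Largest eigenvalue of each compiled LMI block at a point
#' @param blocks compiled blocks
#' @param x variable vector
#' @return numeric vector of per-block maximum eigenvalues
#' @export
lmi_max_eigs <- function(blocks, x) {
  as.vector(.lmi_maxeig_cpp(blocks, x))
}
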