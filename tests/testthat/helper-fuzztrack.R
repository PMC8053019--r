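## Shared fixtures. Syntheses are cached per test session: several files
## exercise the same reduced (8-submodel) design, and re-solving it each
## time would dominate the suite's runtime.

.cache <- new.env(parent = emptyenv())

.cached <- function(key, fn) {
  if (is.null(.cache[[key]])) .cache[[key]] <- fn()
  .cache[[key]]
}

tp <- function() asp_parameters()

tdom <- function() operating_domain()

tbounds <- function() .cached("bounds", function() {
  premise_bounds(tdom(), tp())
})

tbounds_reduced <- function() .cached("bounds_r", function() {
  collapse_premises(tbounds(), c(2, 3, 4))
})

tts_track_reduced <- function() .cached("ts_track_r", function() {
  build_vertex_models(tbounds_reduced(), tp(), factorization = "tracking")
})

tts_obs_reduced <- function() .cached("ts_obs_r", function() {
  build_vertex_models(tbounds_reduced(), tp(), factorization = "coupled")
})

tts_obs_full <- function() .cached("ts_obs_f", function() {
  build_vertex_models(tbounds(), tp(), factorization = "coupled")
})

tcgains_reduced <- function() .cached("cgains_r", function() {
  solve_controller(partition(tts_track_reduced()),
                   controller_spec(fix_Qtilde_identity = TRUE),
                   objective = "min_trace")
})

togains_reduced <- function() .cached("ogains_r", function() {
  solve_observer(augment(tts_obs_reduced()),
                 observer_spec(nu = 1.0681, mode = "prescribed"))
})

togains_full <- function() .cached("ogains_f", function() {
  solve_observer(augment(tts_obs_full()),
                 observer_spec(nu = 1.0681, mode = "prescribed"))
})

## a small 2-submodel partitioned system with benign, well-damped dynamics,
## for assembly oracles and synthesis sanity checks
toy_pts <- function(seed = 7, eps = 0.1) {
  set.seed(seed)
  nr <- 2L
  mk <- function() array(0, c(2, 2, nr))
  pts <- list(nr = nr, A11 = mk(), A12 = mk(), A21 = mk(), A22 = mk(),
              B1 = mk(), B2 = mk(),
              G1 = matrix(0, 2, 1), G2 = matrix(c(1, 0), 2, 1),
              bounds = NULL)
  for (i in 1:nr) {
    pts$A11[, , i] <- -diag(2) + eps * (i - 1) * matrix(runif(4, -1, 1), 2)
    pts$A22[, , i] <- -diag(2) - eps * (i - 1)
    pts$A12[, , i] <- eps * matrix(runif(4, -1, 1), 2)
    pts$A21[, , i] <- eps * matrix(runif(4, -1, 1), 2)
    pts$B2[, , i] <- diag(2) + eps * (i - 1)
  }
  class(pts) <- "partitioned_ts"
  pts
}

## random in-domain draws shared by exactness-style tests
rand_inputs <- function(n, seed = 1) {
  set.seed(seed)
  list(x = sample_domain(n, tdom()),
       u = cbind(D = runif(n, 0, 0.2), KLa = runif(n, 0, 10)),
       ds = runif(n, -10, 10))
}
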