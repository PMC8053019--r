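## Configuration, structured-text serialization and reports.
## Matrices are written as dense text with 17 significant digits so that
## synthesis and simulation can run as separate pipeline steps with
## bit-stable round-trips.

#' Default run configuration
#'
#' Nested list with every tunable of the pipeline and its default; units
#' are hours and mg/l throughout.
#'
#' @return named list (classes `run_config`)
#' @export
default_config <- function() {
  cfg <- list(
    parameters = unclass(asp_parameters()),
    domain = unclass(operating_domain()),
    premise = list(n_grid = 200, margin = 0.01),
    controller = list(alpha1 = 0.4, alpha2 = 0.4, alpha3 = 300,
                      alpha4 = 295, gamma1 = 0.4, gamma2 = 0.4,
                      Ar_diag = c(-11, -12), fix_Qtilde_identity = TRUE,
                      objective = "min_trace", margin = 1e-4,
                      reduced = TRUE),
    observer = list(mode = "prescribed", nu = 1.0681, R_identity = FALSE,
                    margin = 1e-3),
    reference = list(time = c(0, 20, 40) * 24,
                     S_ref = c(45, 60, 50),
                     Co_ref = c(2, 6, 4)),
    scenario = list(sin_amplitude_fraction = 0.05, sin_period = 24,
                    kinetic_events = list(
                      list(param = "mumax", change = 0.1,
                           start = 240, duration = 48),
                      list(param = "Kc", change = 0.1,
                           start = 1200, duration = 48))),
    simulation = list(horizon = 1440, output_step = 0.25, rtol = 1e-8,
                      atol = 1e-10, x0 = c(208, 416, 45, 2),
                      clamp_lower = 0, clamp_upper = Inf),
    seed = 1L)
  class(cfg) <- "run_config"
  cfg
}

# recursively merge user values into defaults, rejecting unknown keys
.merge_config <- function(def, usr, path = "") {
  for (nm in names(usr)) {
    here <- paste0(path, nm)
    if (!nm %in% names(def)) {
      stop("load_config: unknown configuration key: ", here)
    }
    if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
      if (!is.list(usr[[nm]])) {
        stop("load_config: key ", here, " must be a mapping")
      }
      def[[nm]] <- .merge_config(def[[nm]], usr[[nm]], paste0(here, "$"))
    } else {
      def[[nm]] <- usr[[nm]]
    }
  }
  def
}

#' Load a run configuration from a YAML file
#'
#' Defaults are applied for every omitted key; unknown keys are rejected.
#' An empty file yields the full default configuration.
#'
#' @param path YAML file
#' @return validated `run_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  usr <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(usr)) {
    if (!is.null(usr$scenario$kinetic_events)) {
      cfg$scenario$kinetic_events <- usr$scenario$kinetic_events
      usr$scenario$kinetic_events <- NULL
    }
    if (!is.null(usr$reference)) {
      cfg$reference <- .merge_config(cfg$reference, usr$reference,
                                     "reference$")
      usr$reference <- NULL
    }
    cfg <- .merge_config(unclass(cfg), usr)
    class(cfg) <- "run_config"
  }
  validate_config(cfg)
  cfg
}

#' Validate a run configuration (invariants of the synthesis and the plant)
#' @param cfg `run_config`
#' @return the configuration, invisibly; errors name the violated rule
#' @export
validate_config <- function(cfg) {
  ct <- cfg$controller
  if (ct$alpha1 > ct$gamma1 || ct$alpha2 > ct$gamma2) {
    stop("config: the tracking synthesis requires alpha1 <= gamma1 and ",
         "alpha2 <= gamma2")
  }
  do.call(asp_parameters, cfg$parameters)
  do.call(operating_domain, cfg$domain[c("X", "Xr", "S", "Co")])
  if (cfg$observer$mode == "prescribed" &&
      (is.null(cfg$observer$nu) || cfg$observer$nu <= 0)) {
    stop("config: prescribed observer mode requires nu > 0")
  }
  invisible(cfg)
}

#' Write a run configuration as YAML
#' @param cfg `run_config`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 17)
  invisible(path)
}

#' Instantiate package objects from a run configuration
#'
#' @param cfg `run_config`
#' @return list with `params`, `dom`, `bounds`, `cspec`, `ospec`, `ref`,
#'   `scenario`, `simcfg`
#' @export
config_objects <- function(cfg) {
  params <- do.call(asp_parameters, cfg$parameters)
  dom <- do.call(operating_domain, cfg$domain[c("X", "Xr", "S", "Co")])
  bounds <- premise_bounds(dom, params, n_grid = cfg$premise$n_grid,
                           margin = cfg$premise$margin)
  cspec <- controller_spec(
    alpha1 = cfg$controller$alpha1, alpha2 = cfg$controller$alpha2,
    alpha3 = cfg$controller$alpha3, alpha4 = cfg$controller$alpha4,
    gamma1 = cfg$controller$gamma1, gamma2 = cfg$controller$gamma2,
    Ar = diag(cfg$controller$Ar_diag),
    fix_Qtilde_identity = isTRUE(cfg$controller$fix_Qtilde_identity))
  ospec <- observer_spec(nu = cfg$observer$nu, mode = cfg$observer$mode,
                         R_identity = isTRUE(cfg$observer$R_identity))
  ref <- reference_model(Ar = diag(cfg$controller$Ar_diag),
                         schedule = data.frame(
                           time = cfg$reference$time,
                           S_ref = cfg$reference$S_ref,
                           Co_ref = cfg$reference$Co_ref))
  scenario <- disturbance_scenario(
    sin_amplitude_fraction = cfg$scenario$sin_amplitude_fraction,
    sin_period = cfg$scenario$sin_period,
    kinetic_events = cfg$scenario$kinetic_events)
  simcfg <- simulation_config(
    horizon = cfg$simulation$horizon,
    output_step = cfg$simulation$output_step,
    rtol = cfg$simulation$rtol, atol = cfg$simulation$atol,
    x0 = cfg$simulation$x0,
    clamp = c(cfg$simulation$clamp_lower, cfg$simulation$clamp_upper))
  list(params = params, dom = dom, bounds = bounds, cspec = cspec,
       ospec = ospec, ref = ref, scenario = scenario, simcfg = simcfg)
}

## ---- dense-text matrix serialization ------------------------------------

.fmt <- function(x) sprintf("%.17g", x)

.write_sections <- function(sections, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# fuzztrack ", header, " v1"), con)
  for (nm in names(sections)) {
    v <- sections[[nm]]
    if (is.character(v)) {
      writeLines(c(paste("@str", nm), v), con)
    } else {
      v <- as.matrix(v)
      writeLines(paste("@num", nm, nrow(v), ncol(v)), con)
      for (i in seq_len(nrow(v))) {
        writeLines(paste(.fmt(v[i, ]), collapse = " "), con)
      }
    }
  }
  invisible(path)
}

.read_sections <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 2L
  while (i <= length(lines)) {
    hd <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    if (hd[1] == "@str") {
      out[[hd[2]]] <- lines[i + 1L]
      i <- i + 2L
    } else if (hd[1] == "@num") {
      r <- as.integer(hd[3]); cc <- as.integer(hd[4])
      vals <- lines[i + seq_len(r)]
      m <- do.call(rbind, lapply(vals, function(s)
        as.numeric(strsplit(s, " ", fixed = TRUE)[[1]])))
      out[[hd[2]]] <- matrix(m, r, cc)
      i <- i + 1L + r
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Serialize a TS model to structured text
#' @param ts [build_vertex_models()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_ts_model <- function(ts, path) {
  sec <- list(factorization = ts$factorization,
              nr = matrix(ts$nr, 1, 1),
              bounds = unclass(ts$bounds),
              nondeg = matrix(as.numeric(ts$nondeg), 1),
              vertex_map = ts$vertex_map,
              A = matrix(ts$A, 16, ts$nr),
              B = matrix(ts$B, 8, ts$nr),
              G = ts$G, C = ts$C,
              params = matrix(unlist(ts$params), 1))
  .write_sections(sec, path, "ts_model")
}

#' Read a TS model written by [write_ts_model()]
#' @param path input file
#' @return `ts_model`
#' @export
read_ts_model <- function(path) {
  s <- .read_sections(path)
  nr <- as.integer(s$nr[1, 1])
  pn <- c("Y", "qr", "beta", "K0", "Cs", "Sin", "Coin", "mumax", "Ks", "Kc")
  params <- do.call(asp_parameters, as.list(stats::setNames(s$params[1, ], pn)))
  bounds <- s$bounds
  dimnames(bounds) <- list(paste0("z", 1:6), c("min", "max"))
  class(bounds) <- c("premise_bounds", class(bounds))
  ts <- list(nr = nr, A = array(s$A, c(4, 4, nr)),
             B = array(s$B, c(4, 2, nr)), G = s$G, C = s$C,
             bounds = bounds, nondeg = as.logical(s$nondeg[1, ]),
             vertex_map = matrix(as.integer(s$vertex_map), nr, 6),
             params = params, factorization = s$factorization)
  class(ts) <- "ts_model"
  ts
}

#' Serialize controller gains to structured text
#' @param gains [solve_controller()] result
#' @param path output file
#' @return `path`, invisibly
#' @export
write_controller_gains <- function(gains, path) {
  nr <- dim(gains$K)[3]
  sec <- list(status = gains$status,
              nr = matrix(nr, 1, 1),
              X1 = gains$X1, X2 = gains$X2,
              Y = matrix(gains$Y, 4, nr),
              Kn = matrix(gains$Kn, 4, nr),
              K = matrix(gains$K, 4, nr),
              Qt11 = gains$Qt$Qt11, Qt12 = gains$Qt$Qt12,
              Qt21 = gains$Qt$Qt21, Qt22 = gains$Qt$Qt22,
              P = gains$P, Q1 = gains$Q1, Q2 = gains$Q2, Q = gains$Q,
              gamma = matrix(gains$gamma, 1, 1),
              margins = matrix(gains$margins, 1),
              scaling = matrix(c(gains$scaling$t1, gains$scaling$t2), 1),
              cbounds = if (!is.null(gains$pts$bounds))
                unclass(gains$pts$bounds) else matrix(NA_real_, 6, 2),
              spec = matrix(c(gains$spec$alpha1, gains$spec$alpha2,
                              gains$spec$alpha3, gains$spec$alpha4,
                              gains$spec$gamma1, gains$spec$gamma2,
                              as.numeric(gains$spec$fix_Qtilde_identity),
                              gains$spec$eps), 1),
              Ar = gains$spec$Ar)
  .write_sections(sec, path, "controller_gains")
}

#' Read controller gains written by [write_controller_gains()]
#'
#' The partitioned vertex blocks are not serialized, but the premise bounds
#' of the controller's vertex set are (field `cbounds`); rebuild the blocks
#' with `partition(build_vertex_models(cbounds, params, "tracking"))` when
#' certificate re-verification or ratio computation is needed.
#'
#' @param path input file
#' @return `controller_gains` (without the `pts` field; `cbounds` attached)
#' @export
read_controller_gains <- function(path) {
  s <- .read_sections(path)
  nr <- as.integer(s$nr[1, 1])
  sp <- s$spec[1, ]
  spec <- controller_spec(alpha1 = sp[1], alpha2 = sp[2], alpha3 = sp[3],
                          alpha4 = sp[4], gamma1 = sp[5], gamma2 = sp[6],
                          Ar = s$Ar, fix_Qtilde_identity = sp[7] > 0,
                          eps = sp[8])
  gains <- list(X1 = s$X1, X2 = s$X2,
                Y = array(s$Y, c(2, 2, nr)),
                Kn = array(s$Kn, c(2, 2, nr)),
                K = array(s$K, c(2, 2, nr)),
                Qt = list(Qt11 = s$Qt11, Qt12 = s$Qt12,
                          Qt21 = s$Qt21, Qt22 = s$Qt22),
                P = s$P, Q1 = s$Q1, Q2 = s$Q2, Q = s$Q,
                gamma = s$gamma[1, 1],
                scaling = list(t1 = s$scaling[1, 1:2],
                               t2 = s$scaling[1, 3:4]),
                spec = spec, margins = s$margins[1, ],
                status = s$status, pts = NULL)
  if (!is.null(s$cbounds) && !anyNA(s$cbounds)) {
    cb <- s$cbounds
    dimnames(cb) <- list(paste0("z", 1:6), c("min", "max"))
    class(cb) <- c("premise_bounds", class(cb))
    gains$cbounds <- cb
  }
  class(gains) <- "controller_gains"
  gains
}

#' Serialize observer gains to structured text
#' @param gains [solve_observer()] result
#' @param path output file
#' @return `path`, invisibly
#' @export
write_observer_gains <- function(gains, path) {
  nr <- dim(gains$L)[3]
  sec <- list(status = gains$status, mode = gains$spec$mode,
              nr = matrix(nr, 1, 1), Po = gains$Po, R = gains$R,
              Z = matrix(gains$Z, 5, nr), L = matrix(gains$L, 5, nr),
              eta = matrix(gains$eta, 1, 1),
              nu = matrix(if (is.null(gains$spec$nu)) NA_real_ else
                gains$spec$nu, 1, 1),
              margins = matrix(gains$margins, 1))
  .write_sections(sec, path, "observer_gains")
}

#' Read observer gains written by [write_observer_gains()]
#' @param path input file
#' @return `observer_gains`
#' @export
read_observer_gains <- function(path) {
  s <- .read_sections(path)
  nr <- as.integer(s$nr[1, 1])
  nu <- s$nu[1, 1]
  spec <- observer_spec(nu = if (is.na(nu)) NULL else nu, mode = s$mode)
  gains <- list(Po = s$Po, R = s$R, Z = array(s$Z, c(5, 1, nr)),
                L = array(s$L, c(5, 1, nr)), eta = s$eta[1, 1],
                nu_effective = sqrt(s$eta[1, 1]), spec = spec,
                margins = s$margins[1, ], status = s$status)
  class(gains) <- "observer_gains"
  gains
}

#' Write a simulated trajectory as CSV
#'
#' Fixed leading column order (t_h, X, Xr, S, Co, D, KLa, delta_sin)
#' followed by the observer estimates and the reference states.
#'
#' @param traj [simulate_tracking()] result
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(t_h = traj$times,
                   X = traj$x[, 1], Xr = traj$x[, 2],
                   S = traj$x[, 3], Co = traj$x[, 4],
                   D = traj$u[, 1], KLa = traj$u[, 2],
                   delta_sin = traj$delta_sin,
                   X_hat = traj$xhat[, 1], Xr_hat = traj$xhat[, 2],
                   S_hat = traj$xhat[, 3], Co_hat = traj$xhat[, 4],
                   d_hat = traj$xhat[, 5],
                   S_ref = traj$x2r[, 1], Co_ref = traj$x2r[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#' @param path input file
#' @return data frame
#' @export
read_trajectory_csv <- function(path) utils::read.csv(path)

#' Write the performance report (plus provenance) as JSON
#'
#' @param report [hinf_ratios()] result
#' @param path output file
#' @param cgains,ogains optional gain sets; their attenuation levels,
#'   solver statuses and certificate margins are embedded
#' @param cfg optional `run_config`; its MD5 hash is embedded for
#'   provenance
#' @return `path`, invisibly
#' @export
write_report <- function(report, path, cgains = NULL, ogains = NULL,
                         cfg = NULL) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  out <- unclass(report)
  out$tracking_energy <- as.list(out$tracking_energy)
  out$observer_energy <- as.list(out$observer_energy)
  if (!is.null(cgains)) {
    out$gamma <- cgains$gamma
    out$controller_status <- cgains$status
    out$controller_worst_margin <- max(cgains$margins)
  }
  if (!is.null(ogains)) {
    out$eta <- ogains$eta
    out$nu_effective <- ogains$nu_effective
    out$observer_status <- ogains$status
    out$observer_worst_margin <- max(ogains$margins)
  }
  if (!is.null(cfg)) {
    tmp <- tempfile(fileext = ".yml")
    write_config(cfg, tmp)
    out$config_md5 <- unname(tools::md5sum(tmp))
    unlink(tmp)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
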