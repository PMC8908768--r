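#' Fluctuating-charge parameter set
#'
#' Per-atom-type electronegativity chi (hartree/e) and chemical hardness eta
#' (hartree/e^2), plus the choice of charge-charge interaction kernel.
#' `kernel = "ohno"` uses the shielded-Coulomb Ohno form (finite at contact,
#' 1/r at long range); `kernel = "coulomb"` uses the bare 1/r off-diagonal
#' and is intended for cross-checks against analytic results.
#'
#' @param chi named numeric vector of electronegativities, atomic units
#' @param eta named numeric vector of hardnesses, atomic units; all > 0
#' @param kernel `"ohno"` or `"coulomb"`
#' @return object of class `fq_parameter_set`
#' @export
fq_parameter_set <- function(chi, eta, kernel = c("ohno", "coulomb")) {
  kernel <- match.arg(kernel)
  if (is.null(names(chi)) || is.null(names(eta)) ||
      !setequal(names(chi), names(eta))) {
    stop("chi and eta must be named by the same FQ types")
  }
  if (any(eta <= 0)) stop("chemical hardness eta must be positive for every type")
  structure(list(chi = chi, eta = eta[names(chi)], kernel = kernel),
            class = "fq_parameter_set")
}

#' @export
print.fq_parameter_set <- function(x, ...) {
  cat(sprintf("<fq_parameter_set> kernel=%s; types: %s\n", x$kernel,
              paste(sprintf("%s(chi=%.4g, eta=%.4g)", names(x$chi), x$chi,
                            x$eta), collapse = ", ")))
  invisible(x)
}

#' Documented toy FQ parameters for 3-site water
#'
#' Water-like electronegativity/hardness values in atomic units, of the
#' magnitude used in charge-equilibration water models. They are a documented
#' toy set for self-contained runs and tests, not a published
#' parameterization.
#'
#' @param kernel interaction kernel selector, see [fq_parameter_set()]
#' @return an `fq_parameter_set` with types `O` and `H`
#' @export
toy_fq_water_params <- function(kernel = "ohno") {
  fq_parameter_set(chi = c(O = 0.18, H = 0.02),
                   eta = c(O = 0.60, H = 0.65),
                   kernel = kernel)
}

#' Read a run configuration file
#'
#' YAML with sections `paths` (geometry, partition, skf file map, output
#' directory), `fq` (per-type chi/eta, kernel), `scf`, `response`, `spectra`,
#' and `seed`. Missing settings fall back to the package defaults returned by
#' [default_settings()]. Relative paths are resolved against the directory of
#' the config file.
#'
#' @param path path to a YAML config
#' @return a list with class `run_config`
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  defaults <- default_settings()
  for (sec in names(defaults)) {
    cfg[[sec]] <- utils::modifyList(defaults[[sec]],
                                    if (is.null(cfg[[sec]])) list() else cfg[[sec]])
  }
  if (!is.null(cfg$paths)) {
    resolve <- function(p) {
      if (is.null(p)) return(NULL)
      if (grepl("^/", p)) p else file.path(base, p)
    }
    cfg$paths$geometry <- resolve(cfg$paths$geometry)
    cfg$paths$partition <- resolve(cfg$paths$partition)
    cfg$paths$output <- resolve(cfg$paths$output)
    if (!is.null(cfg$paths$skf)) cfg$paths$skf <- lapply(cfg$paths$skf, resolve)
  }
  if (!is.null(cfg$fq)) {
    cfg$fq_params <- fq_parameter_set(
      chi = unlist(cfg$fq$chi), eta = unlist(cfg$fq$eta),
      kernel = if (is.null(cfg$fq$kernel)) "ohno" else cfg$fq$kernel)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Package default settings
#'
#' @return nested list of defaults: `scf` (`mixing` 0.2, `tol_dq` 1e-7,
#'   `tol_e` 1e-9 hartree, `max_iter` 200), `response` (`n_states` 100,
#'   `f_threshold` 0, `solver` "reduced"), `spectra` (`fwhm_ev` 0.3, grid
#'   1-8 eV with 0.005 eV step, `normalize` TRUE), `embedding`
#'   (`kernel` "coulomb")
#' @export
default_settings <- function() {
  list(
    scf = list(mixing = 0.2, tol_dq = 1e-7, tol_e = 1e-9, max_iter = 200L),
    response = list(n_states = 100L, f_threshold = 0, solver = "reduced"),
    spectra = list(fwhm_ev = 0.3, grid_min_ev = 1.0, grid_max_ev = 8.0,
                   grid_step_ev = 0.005, normalize = TRUE),
    embedding = list(kernel = "coulomb")
  )
}
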