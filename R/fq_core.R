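#' Charge-charge interaction kernel between two FQ sites
#'
#' The Ohno form `J_ij(r) = eta_bar / sqrt(1 + eta_bar^2 r^2)` with
#' `eta_bar = (eta_i + eta_j)/2`: smooth, positive, equal to the (mean)
#' hardness at contact and decaying to `1/r` at long range. The `coulomb`
#' selector returns the bare `1/r` (hardness on the diagonal only), used for
#' analytic cross-checks.
#'
#' @param r distance in bohr (scalar or vector), `r >= 0`
#' @param eta_i,eta_j hardnesses of the two sites (hartree/e^2)
#' @param kernel `"ohno"` or `"coulomb"`
#' @return kernel value(s), hartree/e^2
#' @export
fq_kernel <- function(r, eta_i, eta_j, kernel = c("ohno", "coulomb")) {
  kernel <- match.arg(kernel)
  if (kernel == "ohno") {
    eb <- (eta_i + eta_j) / 2
    eb / sqrt(1 + (eb * r)^2)
  } else {
    ifelse(r == 0, (eta_i + eta_j) / 2, 1 / r)
  }
}

#' Assemble the constrained FQ matrix for a frame
#'
#' Builds the symmetric KKT matrix of the charge-equilibration functional:
#' the charge-charge block carries the hardness eta on the diagonal and the
#' pair kernel `J(r)` off-diagonal (all MM-MM pairs, also across fragments);
#' one Lagrangian row/column of 0/1 fragment-membership indicators per
#' fragment enforces its total charge. The matrix depends only on the
#' geometry and is factorized once per frame; the right-hand side changes
#' along the SCF.
#'
#' @param geom a [geometry()]
#' @param part a [partition()] with at least one MM fragment
#' @param params an [fq_parameter_set()]
#' @return object of class `fq_matrix` with fields `M` (dense symmetric),
#'   `n_mm`, `n_frag`, `mm_index` (atom indices into the frame), `chi`
#'   (per-MM-atom electronegativities), `Q` (per-fragment charges), `lu`
#'   (factorization)
#' @export
build_fq_matrix <- function(geom, part, params) {
  idx <- mm_atoms(part)
  n_mm <- length(idx)
  if (n_mm == 0L) stop("partition has no MM atoms; nothing to equilibrate")
  types <- fq_types_of(part, geom)
  unknown <- setdiff(unique(types), names(params$chi))
  if (length(unknown) > 0L) {
    stop(sprintf("no FQ parameters for type(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  eta <- unname(params$eta[types])
  chi <- unname(params$chi[types])
  xyz <- geom$coords[idx, , drop = FALSE]
  n_frag <- length(part$mm_fragments)
  dim_tot <- n_mm + n_frag
  M <- matrix(0, dim_tot, dim_tot)
  if (n_mm > 1L) {
    D <- as.matrix(stats::dist(xyz))
    coincident <- which(D < 1e-6 & upper.tri(D), arr.ind = TRUE)
    if (nrow(coincident) > 0L) {
      stop(sprintf("MM atoms %d and %d (frame indices %d, %d) coincide; FQ matrix singular",
                   coincident[1, 1], coincident[1, 2],
                   idx[coincident[1, 1]], idx[coincident[1, 2]]))
    }
    for (i in seq_len(n_mm - 1L)) {
      for (j in (i + 1L):n_mm) {
        M[i, j] <- M[j, i] <- fq_kernel(D[i, j], eta[i], eta[j], params$kernel)
      }
    }
  }
  diag(M)[seq_len(n_mm)] <- eta
  Q <- numeric(n_frag)
  pos <- stats::setNames(seq_along(idx), as.character(idx))
  for (f in seq_len(n_frag)) {
    rows <- pos[as.character(part$mm_fragments[[f]]$atoms)]
    M[n_mm + f, rows] <- 1
    M[rows, n_mm + f] <- 1
    Q[f] <- part$mm_fragments[[f]]$Q
  }
  fq_matrix_from_dense(M, n_mm, n_frag, chi = chi, Q = Q, mm_index = idx)
}

#' Build an `fq_matrix` from an explicit dense KKT matrix
#'
#' Low-level constructor used by the geometry-based builder and by tests
#' that specify the charge-charge kernel values directly.
#'
#' @param M dense symmetric (n_mm + n_frag) square matrix
#' @param n_mm,n_frag dimensions of the charge and constraint blocks
#' @param chi per-MM-atom electronegativities (optional, convenience)
#' @param Q per-fragment total charges (optional, convenience)
#' @param mm_index frame atom indices of the MM sites (optional)
#' @return an `fq_matrix`
#' @export
fq_matrix_from_dense <- function(M, n_mm, n_frag, chi = NULL, Q = NULL,
                                 mm_index = seq_len(n_mm)) {
  stopifnot(nrow(M) == n_mm + n_frag, isTRUE(all.equal(M, t(M))))
  lu <- tryCatch(qr(M, LAPACK = TRUE), error = function(e) {
    stop(sprintf("FQ matrix factorization failed: %s", conditionMessage(e)))
  })
  if (any(abs(diag(lu$qr)) < 1e-12 * max(abs(diag(lu$qr))))) {
    stop("FQ matrix is numerically singular")
  }
  structure(list(M = M, n_mm = n_mm, n_frag = n_frag, chi = chi, Q = Q,
                 mm_index = mm_index, lu = lu),
            class = "fq_matrix")
}

#' @export
print.fq_matrix <- function(x, ...) {
  cat(sprintf("<fq_matrix> %d MM sites, %d fragment constraints\n",
              x$n_mm, x$n_frag))
  invisible(x)
}

#' Solve the constrained charge-equilibration system
#'
#' Finds the stationary point of
#' `F(q, lambda) = chi.q + q'Jq/2 + q.V + sum_f lambda_f (sum_{i in f} q_i - Q_f)`
#' by solving the KKT system `M [q; lambda] = [-(chi + V); Q]`, i.e. the
#' source vector is `-(C_Q + V)` in the charge block. `V` is the external
#' electrostatic potential at the MM sites (zero for a pure FQ system).
#'
#' @param fqm an `fq_matrix`
#' @param chi per-MM-atom electronegativities; defaults to those stored at
#'   build time
#' @param Q per-fragment total charges; defaults to those stored at build time
#' @param V external potential per MM atom (hartree/e); default zeros
#' @return object of class `fq_solution` with `q` (charges, e), `lambda`
#'   (per-fragment multipliers), `residual` (stationarity residual norm),
#'   `chi`, `Q`, `V`
#' @export
solve_fq <- function(fqm, chi = fqm$chi, Q = fqm$Q, V = NULL) {
  n_mm <- fqm$n_mm
  if (is.null(chi) || length(chi) != n_mm) {
    stop("chi must have one entry per MM atom")
  }
  if (is.null(Q) || length(Q) != fqm$n_frag) {
    stop("Q must have one entry per fragment")
  }
  if (is.null(V)) V <- numeric(n_mm)
  if (length(V) != n_mm) stop("V must have one entry per MM atom")
  rhs <- c(-(chi + V), Q)
  x <- solve(fqm$lu, rhs)
  q <- x[seq_len(n_mm)]
  lambda <- x[n_mm + seq_len(fqm$n_frag)]
  residual <- sqrt(sum((fqm$M %*% x - rhs)^2))
  structure(list(q = q, lambda = lambda, residual = residual,
                 chi = chi, Q = Q, V = V),
            class = "fq_solution")
}

#' @export
print.fq_solution <- function(x, ...) {
  cat(sprintf("<fq_solution> %d charges in [%.4g, %.4g], residual %.2e\n",
              length(x$q), min(x$q), max(x$q), x$residual))
  invisible(x)
}

#' Value of the FQ energy functional at a solution
#'
#' Evaluates `chi.q + q'Jq/2 + q.V` (the Lagrangian terms vanish when the
#' constraints hold). The charge-charge block of the stored matrix supplies
#' the quadratic form.
#'
#' @param fqm the `fq_matrix` the solution was obtained from
#' @param sol an `fq_solution`
#' @param include_external if `FALSE`, the `q.V` interaction term is
#'   excluded, leaving the internal FQ energy
#' @return energy in hartree
#' @export
fq_energy <- function(fqm, sol, include_external = TRUE) {
  J <- fqm$M[seq_len(fqm$n_mm), seq_len(fqm$n_mm), drop = FALSE]
  e <- sum(sol$chi * sol$q) + 0.5 * sum(sol$q * (J %*% sol$q))
  if (include_external) e <- e + sum(sol$q * sol$V)
  e
}
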