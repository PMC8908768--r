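#' Mulliken atomic transition charges of one occupied-virtual pair
#'
#' Symmetrized Mulliken contraction of the transition density of the pair
#' `(i, a)`: `q^ia_a = 1/2 sum_{mu in a} [ c_mu_i (S c_a)_mu +
#' c_mu_a (S c_i)_mu ]`. Over all atoms the charges sum to the MO overlap
#' `<i|a> = 0`.
#'
#' @param C MO coefficient matrix (columns = MOs)
#' @param S overlap matrix
#' @param basis a [basis_map()]
#' @param i,a occupied and virtual MO indices
#' @return numeric vector of transition charges per atom
#' @export
transition_charges <- function(C, S, basis, i, a) {
  sci <- S %*% C[, i]
  sca <- S %*% C[, a]
  contrib <- 0.5 * (C[, i] * sca + C[, a] * sci)
  vapply(basis$ranges, function(rg) sum(contrib[rg]), numeric(1))
}

#' Single-orbital transition basis
#'
#' Enumerates all occupied -> virtual pairs of a converged ground state, with
#' orbital-energy differences, per-pair Mulliken transition charges, point
#' Mulliken transition dipoles and single-orbital oscillator strengths
#' `f_ia = (2/3) de_ia |d_ia|^2`.
#'
#' @param state an `scf_state`
#' @return object of class `transition_basis`: `pairs` (2-column matrix of
#'   (i, a)), `de` (hartree), `tq` (n_pair x n_atom transition charges),
#'   `dip` (n_pair x 3), `f_single`, plus the geometry rows `R` of the QM
#'   atoms (bohr)
#' @export
transition_basis <- function(state) {
  n_occ <- state$n_occ
  n_orb <- state$basis$n_orb
  if (n_occ >= n_orb) stop("no virtual orbitals: transition basis is empty")
  occ <- seq_len(n_occ)
  vir <- (n_occ + 1L):n_orb
  pairs <- as.matrix(expand.grid(i = occ, a = vir))
  de <- state$mo_energies[pairs[, "a"]] - state$mo_energies[pairs[, "i"]]
  ord <- order(de)
  pairs <- pairs[ord, , drop = FALSE]
  de <- de[ord]
  tq <- t(apply(pairs, 1L, function(p) {
    transition_charges(state$C, state$S, state$basis, p[1], p[2])
  }))
  R <- state$geom$coords[state$basis$atoms, , drop = FALSE]
  dip <- tq %*% R
  f_single <- (2 / 3) * de * rowSums(dip^2)
  structure(list(pairs = pairs, de = de, tq = tq, dip = dip,
                 f_single = f_single, R = R),
            class = "transition_basis")
}

#' @export
print.transition_basis <- function(x, ...) {
  cat(sprintf("<transition_basis> %d pairs, de in [%.4f, %.4f] Ha\n",
              length(x$de), min(x$de), max(x$de)))
  invisible(x)
}

#' Oscillator-strength truncation of the transition basis
#'
#' Retains the pairs whose single-orbital oscillator strength is at least
#' `f_threshold`. A threshold of 0 returns the basis unchanged.
#'
#' @param tb a [transition_basis()]
#' @param f_threshold non-negative truncation threshold
#' @return a `transition_basis` containing the retained pairs
#' @export
intensity_select <- function(tb, f_threshold = 0) {
  if (f_threshold <= 0) return(tb)
  keep <- which(tb$f_single >= f_threshold)
  if (length(keep) == 0L) {
    stop(sprintf("intensity threshold %g retains no transitions (max single-orbital f = %.3g); lower the threshold",
                 f_threshold, max(tb$f_single)))
  }
  tb$pairs <- tb$pairs[keep, , drop = FALSE]
  tb$de <- tb$de[keep]
  tb$tq <- tb$tq[keep, , drop = FALSE]
  tb$dip <- tb$dip[keep, , drop = FALSE]
  tb$f_single <- tb$f_single[keep]
  tb
}

#' Gamma-approximation coupling matrix
#'
#' `K_{ia,jb} = sum_{ab} q^ia_a gamma_ab q^jb_b`, with the ground-state
#' gamma kernel standing in for its response counterpart.
#'
#' @param tb a [transition_basis()]
#' @param gamma gamma matrix over the QM atoms (from [gamma_matrix()])
#' @return symmetric `n_pair` square matrix (hartree)
#' @export
build_coupling <- function(tb, gamma) {
  K <- tb$tq %*% gamma %*% t(tb$tq)
  (K + t(K)) / 2
}

#' FQ contribution to the response coupling matrix
#'
#' The induced-charge screening of each transition density:
#' `K^FQ_{ia,jb} = -(V^ia)' M^{-1} V^jb` with
#' `V^ia_i = sum_a G[a,i] q^ia_a`, padded with zeros on the constraint rows
#' so fragment total charges cannot change in response. Realized with one
#' factorized KKT solve per transition-basis column; negative semidefinite
#' on the charge-conserving subspace, so all diagonal elements are <= 0.
#'
#' @param tb a [transition_basis()]
#' @param fqm the frame's `fq_matrix`
#' @param G embedding kernel matrix ([embedding_kernel()])
#' @return symmetric `n_pair` square matrix (hartree)
#' @export
build_kfq <- function(tb, fqm, G) {
  n_pair <- length(tb$de)
  Vt <- tb$tq %*% G                          # n_pair x n_mm
  rhs <- rbind(t(Vt), matrix(0, fqm$n_frag, n_pair))
  X <- solve(fqm$lu, rhs)                    # KKT solve per column
  K <- -Vt %*% X[seq_len(fqm$n_mm), , drop = FALSE]
  (K + t(K)) / 2
}

#' Solve the Casida response problem
#'
#' With the coupling entering the `A` and `B` blocks identically (singlet
#' response in the gamma approximation), `A - B` is diagonal and the problem
#' reduces to the Hermitian half-size form
#' `[ de^2 + 4 sqrt(de) (K + K^FQ) sqrt(de) ] F = w^2 F`.
#' The full two-block non-Hermitian solve
#' (`[[A, B], [-B, -A]]` eigenproblem) is retained behind
#' `solver = "full"` as a cross-check.
#'
#' @param tb a [transition_basis()] (possibly intensity-selected)
#' @param K gamma coupling matrix from [build_coupling()]
#' @param Kfq FQ coupling matrix from [build_kfq()], or `NULL`/zeros
#' @param n_states number of lowest excitations to return (capped at the
#'   basis size; exceeding it is an error)
#' @param solver `"reduced"` (default) or `"full"`
#' @return object of class `excitation_set`: `omega` (hartree, ascending),
#'   `omega_ev`, `F` (eigenvectors over the transition basis, columns), `tb`
#' @export
solve_casida <- function(tb, K, Kfq = NULL, n_states = 100L,
                         solver = c("reduced", "full")) {
  solver <- match.arg(solver)
  n_pair <- length(tb$de)
  if (n_states > n_pair) {
    stop(sprintf("n_states = %d exceeds the transition-basis size %d",
                 n_states, n_pair))
  }
  Ktot <- K
  if (!is.null(Kfq)) Ktot <- Ktot + Kfq
  if (solver == "reduced") {
    sq <- sqrt(tb$de)
    Om <- diag(tb$de^2, n_pair) + 4 * Ktot * outer(sq, sq)
    Om <- (Om + t(Om)) / 2
    e <- eigen(Om, symmetric = TRUE)
    w2 <- rev(e$values)
    Fv <- e$vectors[, rev(seq_len(n_pair)), drop = FALSE]
    if (any(w2 < -1e-12)) {
      stop(sprintf("negative squared excitation energy (%.3e): response instability",
                   min(w2)))
    }
    omega <- sqrt(pmax(w2, 0))
  } else {
    A <- diag(tb$de, n_pair) + 2 * Ktot
    B <- 2 * Ktot
    Mbig <- rbind(cbind(A, B), cbind(-B, -A))
    e <- eigen(Mbig)
    ev <- Re(e$values)
    pos <- which(ev > 1e-12)
    ord <- order(ev[pos])
    omega <- ev[pos][ord]
    XY <- Re(e$vectors[, pos[ord], drop = FALSE])
    X <- XY[seq_len(n_pair), , drop = FALSE]
    Y <- XY[n_pair + seq_len(n_pair), , drop = FALSE]
    # map to the reduced-form eigenvectors: F ~ sqrt(de)^(-1) (X + Y), renormalized
    Fv <- (X + Y) / sqrt(tb$de)
    nrm <- sqrt(colSums(Fv^2))
    Fv <- sweep(Fv, 2L, ifelse(nrm > 0, nrm, 1), `/`)
  }
  sel <- seq_len(n_states)
  structure(list(omega = omega[sel], omega_ev = hartree_to_ev(omega[sel]),
                 F = Fv[, sel, drop = FALSE], tb = tb,
                 solver = solver),
            class = "excitation_set")
}

#' @export
print.excitation_set <- function(x, ...) {
  cat(sprintf("<excitation_set> %d states, lowest %.4f eV (%s solver)\n",
              length(x$omega), x$omega_ev[1], x$solver))
  invisible(x)
}

#' Oscillator strengths of solved excitations
#'
#' Point-charge (Mulliken) transition dipoles:
#' `q^I_a = sum_ia sqrt(de_ia / w_I) F^I_ia q^ia_a`,
#' `mu_I = sum_a R_a q^I_a`, `f_I = (2/3) w_I |mu_I|^2` (atomic units).
#' In the independent-particle limit this reduces to the single-orbital
#' oscillator strength of the pair.
#'
#' @param ex an `excitation_set`
#' @return the `excitation_set` with fields `f` (oscillator strengths) and
#'   `tdip` (n_state x 3 transition dipoles) added
#' @export
oscillator_strengths <- function(ex) {
  tb <- ex$tb
  w <- ex$omega
  scale <- sqrt(outer(tb$de, w, `/`))          # n_pair x n_state
  Wv <- ex$F * scale
  tdip <- t(Wv) %*% tb$dip                     # n_state x 3
  ex$f <- (2 / 3) * w * rowSums(tdip^2)
  ex$tdip <- tdip
  ex
}

#' Full response pipeline for one converged frame
#'
#' Builds the transition basis, applies the intensity filter, assembles the
#' gamma and (when an FQ layer is present) FQ coupling matrices, solves the
#' Casida problem and attaches oscillator strengths.
#'
#' @param state an `scf_state`
#' @param n_states number of excitations (capped at the basis size when
#'   `cap_states = TRUE`)
#' @param f_threshold intensity-selection threshold (0 = no filter)
#' @param solver `"reduced"` or `"full"`
#' @param cap_states if `TRUE` (default), `n_states` larger than the basis
#'   is silently capped; set `FALSE` to make it an error
#' @return an `excitation_set` with oscillator strengths
#' @export
tddftb_excitations <- function(state, n_states = 100L, f_threshold = 0,
                               solver = "reduced", cap_states = TRUE) {
  tb <- transition_basis(state)
  tb <- intensity_select(tb, f_threshold)
  if (cap_states) n_states <- min(n_states, length(tb$de))
  K <- build_coupling(tb, state$gamma)
  Kfq <- if (!is.null(state$fqm)) build_kfq(tb, state$fqm, state$G) else NULL
  ex <- solve_casida(tb, K, Kfq, n_states = n_states, solver = solver)
  oscillator_strengths(ex)
}
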