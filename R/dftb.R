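#' Assemble the zeroth-order Hamiltonian and overlap matrices
#'
#' Two-center blocks are built by the Slater-Koster rotation of the
#' tabulated sigma/pi channels (s and p shells). For atoms A, B with unit
#' direction `d` from A to B:
#' \preformatted{
#'   <s_A |O| s_B>   = V_ss_sigma^{AB}(r)
#'   <s_A |O| p_kB>  =  d_k V_sp_sigma^{AB}(r)
#'   <p_kA|O| s_B>   = -d_k V_sp_sigma^{BA}(r)
#'   <p_jA|O| p_kB>  = d_j d_k V_pp_sigma^{AB} + (delta_jk - d_j d_k) V_pp_pi^{AB}
#' }
#' On-site blocks carry the tabulated shell energies on the Hamiltonian
#' diagonal and the identity on the overlap diagonal.
#'
#' @param geom a [geometry()]
#' @param tables an [skf_set()] covering all element pairs present
#' @param basis a [basis_map()] for the same atoms
#' @return list with symmetric matrices `H0` and `S` (`basis$n_orb` square)
#' @export
build_h0_s <- function(geom, tables, basis) {
  n <- basis$n_orb
  H0 <- matrix(0, n, n)
  S <- diag(n)
  atoms <- basis$atoms
  for (k in seq_along(atoms)) {
    el <- basis$elements[k]
    tb <- skf_pair(tables, el, el)
    for (o in basis$ranges[[k]]) {
      sh <- if (basis$orb_type[o] == "s") "s" else "p"
      H0[o, o] <- tb$onsite[[sh]]
    }
  }
  if (length(atoms) > 1L) {
    for (ka in seq_len(length(atoms) - 1L)) {
      for (kb in (ka + 1L):length(atoms)) {
        blk <- sk_block(geom, tables, basis, ka, kb)
        ra <- basis$ranges[[ka]]; rb <- basis$ranges[[kb]]
        H0[ra, rb] <- blk$H; H0[rb, ra] <- t(blk$H)
        S[ra, rb] <- blk$S; S[rb, ra] <- t(blk$S)
      }
    }
  }
  list(H0 = H0, S = S)
}

# two-center block between basis atoms ka (bra) and kb (ket)
sk_block <- function(geom, tables, basis, ka, kb) {
  ea <- basis$elements[ka]; eb <- basis$elements[kb]
  ia <- basis$atoms[ka]; ib <- basis$atoms[kb]
  dvec <- geom$coords[ib, ] - geom$coords[ia, ]
  r <- sqrt(sum(dvec^2))
  d <- dvec / r
  tab_ab <- skf_pair(tables, ea, eb)
  tab_ba <- skf_pair(tables, eb, ea)
  la <- basis$orb_type[basis$ranges[[ka]]]
  lb <- basis$orb_type[basis$ranges[[kb]]]
  Hb <- matrix(0, length(la), length(lb))
  Sb <- matrix(0, length(la), length(lb))
  for (what in c("H", "S")) {
    ss <- skf_eval(tab_ab, "ss_sigma", r, what)
    sp_ab <- skf_eval(tab_ab, "sp_sigma", r, what)
    sp_ba <- skf_eval(tab_ba, "sp_sigma", r, what)
    pps <- skf_eval(tab_ab, "pp_sigma", r, what)
    ppp <- skf_eval(tab_ab, "pp_pi", r, what)
    blk <- matrix(0, length(la), length(lb))
    for (i in seq_along(la)) {
      for (j in seq_along(lb)) {
        blk[i, j] <- sk_element(la[i], lb[j], d, ss, sp_ab, sp_ba, pps, ppp)
      }
    }
    if (what == "H") Hb <- blk else Sb <- blk
  }
  list(H = Hb, S = Sb)
}

sk_element <- function(ta, tb, d, ss, sp_ab, sp_ba, pps, ppp) {
  comp <- c(px = 1L, py = 2L, pz = 3L)
  if (ta == "s" && tb == "s") return(ss)
  if (ta == "s") return(d[comp[[tb]]] * sp_ab)
  if (tb == "s") return(-d[comp[[ta]]] * sp_ba)
  j <- comp[[ta]]; k <- comp[[tb]]
  d[j] * d[k] * pps + ((j == k) - d[j] * d[k]) * ppp
}

#' Second-order charge-fluctuation kernel of SCC tight binding
#'
#' The analytic closed form for exponentially decaying spherical charge
#' fluctuations with decay constants `tau = (16/5) U`: the full Coulomb
#' `1/R` minus a short-range exponential correction, so that `gamma -> 1/R`
#' at long range and `gamma(0) = U` for equal Hubbard parameters.
#'
#' @param u_a,u_b Hubbard parameters of the two atoms (hartree/e^2), > 0
#' @param R distance in bohr (scalar or vector), `R >= 0`
#' @return kernel value(s), hartree/e^2
#' @export
gamma_pair <- function(u_a, u_b, R) {
  stopifnot(u_a > 0, u_b > 0)
  ta <- 3.2 * u_a
  tb <- 3.2 * u_b
  vapply(R, function(r) {
    if (r < 1e-10) return((u_a + u_b) / 2)
    if (abs(ta - tb) < 1e-5 * max(ta, tb)) {
      t <- (ta + tb) / 2
      s <- exp(-t * r) * (1 / r + 11 * t / 16 + 3 * t^2 * r / 16 +
                            t^3 * r^2 / 48)
    } else {
      f <- function(x, y) {
        exp(-x * r) * ((y^4 * x) / (2 * (x^2 - y^2)^2) -
                         (y^6 - 3 * y^4 * x^2) / ((x^2 - y^2)^3 * r))
      }
      s <- f(ta, tb) + f(tb, ta)
    }
    1 / r - s
  }, numeric(1))
}

#' Gamma kernel matrix over the QM atoms
#'
#' @param geom a [geometry()]
#' @param tables an [skf_set()]
#' @param basis a [basis_map()]
#' @return symmetric `n_atom` square matrix; diagonal = Hubbard parameters
#' @export
gamma_matrix <- function(geom, tables, basis) {
  atoms <- basis$atoms
  U <- vapply(basis$elements, function(el) {
    skf_pair(tables, el, el)$hubbard[["s"]]
  }, numeric(1))
  n <- length(atoms)
  G <- matrix(0, n, n)
  for (a in seq_len(n)) {
    G[a, a] <- U[a]
    if (a < n) for (b in (a + 1L):n) {
      r <- sqrt(sum((geom$coords[atoms[b], ] - geom$coords[atoms[a], ])^2))
      G[a, b] <- G[b, a] <- gamma_pair(U[a], U[b], r)
    }
  }
  G
}

#' Mulliken charge fluctuations
#'
#' `dq_a = sum_{mu in a} (P S)_mumu - n0_a`: the excess electron population
#' of atom `a` relative to the neutral free atom. The electrostatic partial
#' charge is `-dq_a`.
#'
#' @param P density matrix
#' @param S overlap matrix
#' @param basis a [basis_map()]
#' @return numeric vector of fluctuations per atom (electrons)
#' @export
mulliken <- function(P, S, basis) {
  ps_diag <- rowSums(P * S)   # diag(P %*% S) for symmetric S
  pop <- vapply(basis$ranges, function(rg) sum(ps_diag[rg]), numeric(1))
  pop - basis$n0
}

#' Assemble the self-consistent Hamiltonian
#'
#' `H_mn = H0_mn + 1/2 S_mn [ (g dq)_a + (g dq)_b - v_emb_a - v_emb_b ]`
#' for `m` on atom `a`, `n` on atom `b`, where `g` is the gamma matrix and
#' `v_emb` the FQ embedding potential. The embedding term carries a minus
#' sign because `dq` counts excess electrons while the FQ charges are true
#' charges; the sign pair is fixed by the variational identity
#' `H_mn = dE/dP_mn` of the total energy functional.
#'
#' @param H0,S zeroth-order Hamiltonian and overlap
#' @param gamma gamma matrix over QM atoms
#' @param dq Mulliken fluctuations per QM atom
#' @param v_emb embedding potential per QM atom (zeros for gas phase)
#' @param basis a [basis_map()]
#' @return symmetric Hamiltonian matrix
#' @export
build_hamiltonian <- function(H0, S, gamma, dq, v_emb, basis) {
  eps_site <- drop(gamma %*% dq) - v_emb
  eo <- eps_site[basis$orb_atom]
  H0 + 0.5 * S * outer(eo, eo, `+`)
}

#' Repulsive pair energy of the QM region
#'
#' Sum of the tabulated short-range repulsive potentials over all QM atom
#' pairs within their spline cutoffs.
#'
#' @param geom a [geometry()]
#' @param tables an [skf_set()] whose tables carry Spline blocks
#' @param qm_atoms atom indices to include (default: all)
#' @return energy in hartree
#' @export
repulsive_energy <- function(geom, tables, qm_atoms = seq_len(n_atoms(geom))) {
  e <- 0
  if (length(qm_atoms) < 2L) return(e)
  for (i in seq_len(length(qm_atoms) - 1L)) {
    for (j in (i + 1L):length(qm_atoms)) {
      a <- qm_atoms[i]; b <- qm_atoms[j]
      r <- sqrt(sum((geom$coords[b, ] - geom$coords[a, ])^2))
      tb <- skf_pair(tables, geom$elements[a], geom$elements[b])
      e <- e + skf_repulsive(tb, r)
    }
  }
  e
}

solve_roothaan <- function(H, S) {
  R <- chol(S)
  Rinv <- backsolve(R, diag(nrow(S)))
  Hp <- crossprod(Rinv, H) %*% Rinv
  Hp <- (Hp + t(Hp)) / 2
  e <- eigen(Hp, symmetric = TRUE)
  ord <- order(e$values)
  list(energies = e$values[ord], C = Rinv %*% e$vectors[, ord, drop = FALSE])
}

#' Self-consistent-charge ground state, optionally coupled to an FQ layer
#'
#' Iterates the SCC loop: assemble the Hamiltonian from the current Mulliken
#' fluctuations (and, when MM fragments are present, from the FQ charges
#' equilibrated against the current QM potential), solve the generalized
#' eigenproblem `H C = S C e`, occupy by aufbau with double occupation,
#' recompute the fluctuations, and mix linearly. Convergence requires both
#' `max|dq_change| < tol_dq` and `|energy change| < tol_e`.
#'
#' @param geom a [geometry()] (full frame)
#' @param tables an [skf_set()]
#' @param part optional [partition()]; `NULL` (or a partition without MM
#'   fragments) runs plain gas-phase SCC
#' @param fq_params an [fq_parameter_set()], required when MM fragments exist
#' @param settings list of SCF controls (see [default_settings()]`$scf`);
#'   `embedding_kernel` selects the QM-MM kernel (`"coulomb"` default)
#' @return object of class `scf_state`: MO coefficients `C`, energies
#'   `mo_energies`, density `P`, fluctuations `dq`, FQ solution `fq`
#'   (or NULL), energy decomposition `energies` (band, gamma2, repulsive,
#'   fq, coupling, total), `history`, plus the inputs needed downstream
#'   (`basis`, `gamma`, `S`, `H0`, `G`, `fqm`, `geom`, `part`, `n_occ`)
#' @export
scf <- function(geom, tables, part = NULL, fq_params = NULL,
                settings = list()) {
  st <- utils::modifyList(default_settings()$scf, settings)
  emb_kernel <- if (is.null(st$embedding_kernel)) "coulomb" else st$embedding_kernel
  if (is.null(part)) part <- partition(seq_len(n_atoms(geom)),
                                       n_atoms = n_atoms(geom))
  basis <- basis_map(geom, tables, part$qm_atoms)
  hs <- build_h0_s(geom, tables, basis)
  H0 <- hs$H0; S <- hs$S
  gam <- gamma_matrix(geom, tables, basis)
  n_elec <- sum(basis$n0)
  if (abs(n_elec - round(n_elec)) > 1e-8 || round(n_elec) %% 2 != 0) {
    stop(sprintf("odd or fractional valence electron count (%g): only closed shells are supported",
                 n_elec))
  }
  n_occ <- as.integer(round(n_elec) / 2)
  e_rep <- repulsive_energy(geom, tables, part$qm_atoms)

  has_fq <- length(part$mm_fragments) > 0L
  fqm <- NULL; G <- NULL
  if (has_fq) {
    if (is.null(fq_params)) stop("fq_params required when the partition has MM fragments")
    fqm <- build_fq_matrix(geom, part, fq_params)
    G <- embedding_kernel(geom, part, fq_params, tables, kernel = emb_kernel)
  }

  n_at <- length(basis$atoms)
  dq <- numeric(n_at)
  e_old <- NA_real_
  history <- data.frame(iter = integer(0), energy = numeric(0),
                        max_dq_change = numeric(0))
  converged <- FALSE
  cycle_out <- NULL

  one_cycle <- function(dq) {
    fq_sol <- NULL; v_emb <- numeric(n_at)
    if (has_fq) {
      V <- potential_at_fq_sites(dq, G)
      fq_sol <- solve_fq(fqm, V = V)
      v_emb <- embedding_potential(fq_sol$q, G)
    }
    H <- build_hamiltonian(H0, S, gam, dq, v_emb, basis)
    ro <- solve_roothaan(H, S)
    Cocc <- ro$C[, seq_len(n_occ), drop = FALSE]
    P <- 2 * tcrossprod(Cocc)
    dq_out <- mulliken(P, S, basis)
    e_band <- sum(P * H0)
    e_gamma <- 0.5 * sum(dq_out * (gam %*% dq_out))
    e_fq <- if (has_fq) fq_energy(fqm, fq_sol, include_external = FALSE) else 0
    e_coup <- if (has_fq) coupling_energy(dq_out, fq_sol$q, G) else 0
    list(ro = ro, P = P, dq_out = dq_out, fq_sol = fq_sol, v_emb = v_emb,
         energies = c(band = e_band, gamma2 = e_gamma, repulsive = e_rep,
                      fq = e_fq, coupling = e_coup,
                      total = e_band + e_gamma + e_rep + e_fq + e_coup))
  }

  for (iter in seq_len(st$max_iter)) {
    cycle_out <- one_cycle(dq)
    e_new <- cycle_out$energies[["total"]]
    d_dq <- max(abs(cycle_out$dq_out - dq))
    history <- rbind(history,
                     data.frame(iter = iter, energy = e_new,
                                max_dq_change = d_dq))
    if (d_dq < st$tol_dq && !is.na(e_old) && abs(e_new - e_old) < st$tol_e) {
      converged <- TRUE
      dq <- cycle_out$dq_out
      break
    }
    dq <- dq + st$mixing * (cycle_out$dq_out - dq)
    e_old <- e_new
  }
  if (!converged) {
    err <- simpleError(sprintf("SCF did not converge in %d iterations (last max|ddq| = %.2e)",
                               st$max_iter, utils::tail(history$max_dq_change, 1)))
    err$history <- history
    stop(err)
  }
  # one clean evaluation at the converged fluctuations
  cycle_out <- one_cycle(dq)
  structure(
    list(C = cycle_out$ro$C, mo_energies = cycle_out$ro$energies,
         P = cycle_out$P, dq = cycle_out$dq_out, fq = cycle_out$fq_sol,
         v_emb = cycle_out$v_emb, energies = cycle_out$energies,
         history = history, converged = converged,
         basis = basis, gamma = gam, S = S, H0 = H0, G = G, fqm = fqm,
         geom = geom, part = part, n_occ = n_occ,
         settings = st),
    class = "scf_state"
  )
}

#' @export
print.scf_state <- function(x, ...) {
  cat(sprintf("<scf_state> %d QM atoms, %d orbitals, %d cycles; E = %.8f Ha\n",
              length(x$basis$atoms), x$basis$n_orb, nrow(x$history),
              x$energies[["total"]]))
  cat("  components (Ha): ",
      paste(sprintf("%s=%.8f", names(x$energies), x$energies), collapse = " "),
      "\n")
  invisible(x)
}

#' Energy decomposition of a converged state
#'
#' @param state an `scf_state`
#' @return named numeric vector: `band`, `gamma2`, `repulsive`, `fq`,
#'   `coupling`, `total` (hartree); components sum to `total`
#' @export
total_energy <- function(state) {
  state$energies
}

#' Total DFTB(/FQ) energy as a functional of a density matrix
#'
#' Evaluates `sum(P*H0) + dq'g dq/2 + E_rep + E_FQ + E_coupling` with the
#' Mulliken fluctuations, and (when an FQ layer is present) the re-solved FQ
#' charges, derived from the supplied `P`. Used by the finite-difference
#' variational checks: its derivative with respect to `P` is the
#' self-consistent Hamiltonian.
#'
#' @param state an `scf_state` (supplies geometry, tables and kernels)
#' @param P a symmetric density matrix
#' @return total energy in hartree
#' @export
energy_of_density <- function(state, P) {
  dq <- mulliken(P, state$S, state$basis)
  e <- sum(P * state$H0) + 0.5 * sum(dq * (state$gamma %*% dq)) +
    state$energies[["repulsive"]]
  if (!is.null(state$fqm)) {
    V <- potential_at_fq_sites(dq, state$G)
    sol <- solve_fq(state$fqm, V = V)
    e <- e + fq_energy(state$fqm, sol, include_external = TRUE)
  }
  e
}
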