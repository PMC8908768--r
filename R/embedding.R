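#' Interaction kernel between a QM Mulliken charge and an FQ site
#'
#' The density fluctuation on a QM atom is contracted to a point Mulliken
#' charge (its spatial profile shrunk to a delta at the nucleus), so the
#' default QM-MM kernel is the bare Coulomb `1/r`. An Ohno-damped variant
#' (mean of the QM atom's Hubbard parameter and the MM site's hardness) is
#' available behind the kernel selector for close-contact robustness.
#' Distances below 0.5 bohr are rejected: they indicate a partition that
#' places an MM atom inside the QM region.
#'
#' @param r distance(s) in bohr, `r > 0`
#' @param kernel `"coulomb"` (default) or `"ohno"`
#' @param u_qm QM-side Hubbard parameter (required for `"ohno"`)
#' @param eta_mm MM-side hardness (required for `"ohno"`)
#' @return kernel value(s), hartree/e^2
#' @export
gamma_fq <- function(r, kernel = c("coulomb", "ohno"), u_qm = NULL,
                     eta_mm = NULL) {
  kernel <- match.arg(kernel)
  if (any(r < 0.5)) {
    stop(sprintf("QM-MM distance %.3f bohr below the 0.5 bohr floor: the partition likely places an MM atom inside the QM region",
                 min(r)))
  }
  if (kernel == "coulomb") return(1 / r)
  if (is.null(u_qm) || is.null(eta_mm)) {
    stop("the ohno embedding kernel needs u_qm and eta_mm")
  }
  fq_kernel(r, u_qm, eta_mm, kernel = "ohno")
}

#' QM-MM embedding kernel matrix
#'
#' @param geom the full frame
#' @param part its [partition()]
#' @param params [fq_parameter_set()] (needed for the ohno variant)
#' @param tables [skf_set()] (needed for the ohno variant's Hubbard values)
#' @param kernel `"coulomb"` or `"ohno"`
#' @return `n_qm x n_mm` matrix of kernel values
#' @export
embedding_kernel <- function(geom, part, params = NULL, tables = NULL,
                             kernel = "coulomb") {
  qm <- part$qm_atoms
  mm <- mm_atoms(part)
  G <- matrix(0, length(qm), length(mm))
  if (length(mm) == 0L) return(G)
  for (a in seq_along(qm)) {
    d <- sqrt(colSums((t(geom$coords[mm, , drop = FALSE]) -
                         geom$coords[qm[a], ])^2))
    if (kernel == "ohno") {
      ty <- fq_types_of(part, geom)
      u <- skf_pair(tables, geom$elements[qm[a]], geom$elements[qm[a]])$hubbard[["s"]]
      G[a, ] <- gamma_fq(d, "ohno", u_qm = u, eta_mm = unname(params$eta[ty]))
    } else {
      G[a, ] <- gamma_fq(d, "coulomb")
    }
  }
  G
}

#' Electrostatic potential of the QM charge fluctuations at the FQ sites
#'
#' `V_i = sum_a (-dq_a) * G[a, i]`: the Mulliken fluctuation `dq` counts
#' excess electrons, so the electrostatic source charge is `-dq`. Linear in
#' `dq`.
#'
#' @param dq per-QM-atom Mulliken charge fluctuations (excess electrons)
#' @param G embedding kernel matrix from [embedding_kernel()]
#' @return potential per MM site (hartree/e)
#' @export
potential_at_fq_sites <- function(dq, G) {
  drop(crossprod(G, -dq))
}

#' Electrostatic potential of the FQ charges at the QM atoms
#'
#' `v_emb_a = sum_i G[a, i] * q_i`; fed to [build_hamiltonian()], where it
#' enters the electron Hamiltonian with a negative sign (dq counts excess
#' electrons while q are true charges).
#'
#' @param q_fq FQ charges (e)
#' @param G embedding kernel matrix
#' @return potential per QM atom (hartree/e)
#' @export
embedding_potential <- function(q_fq, G) {
  drop(G %*% q_fq)
}

#' QM-MM electrostatic coupling energy
#'
#' `E = sum_{a,i} (-dq_a) G[a,i] q_i`; equal to both contraction orders
#' `q . V(dq)` and `(-dq) . v_emb(q)`.
#'
#' @param dq Mulliken fluctuations per QM atom
#' @param q_fq FQ charges
#' @param G embedding kernel matrix
#' @return energy in hartree
#' @export
coupling_energy <- function(dq, q_fq, G) {
  sum(-dq * (G %*% q_fq))
}
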