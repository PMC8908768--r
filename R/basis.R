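#' Minimal-basis orbital map for the QM region
#'
#' Derives, from the homonuclear Slater-Koster tables, which shells (s, or
#' s+p) each QM atom carries, the global orbital index range per atom, and
#' the neutral-atom valence electron counts used as the Mulliken reference.
#' A shell is considered present when its on-site energy is finite in the
#' element's homonuclear table and its channel is tabulated. Orbital order
#' within an atom is `s, p_x, p_y, p_z`.
#'
#' @param geom a [geometry()] (or its QM sub-frame)
#' @param tables an [skf_set()] covering every QM element
#' @param qm_atoms indices of the QM atoms within `geom` (default: all)
#' @return object of class `basis_map`: `atoms` (frame indices), `shells`
#'   (list of character vectors), `orb_atom` (atom of each orbital, as a
#'   position in `atoms`), `orb_type` (orbital labels), `ranges` (list of
#'   per-atom orbital index vectors), `n0` (valence electrons per atom),
#'   `n_orb`
#' @export
basis_map <- function(geom, tables, qm_atoms = seq_len(n_atoms(geom))) {
  elements <- geom$elements[qm_atoms]
  shells <- list(); n0 <- numeric(length(qm_atoms))
  for (k in seq_along(qm_atoms)) {
    el <- elements[k]
    tb <- skf_pair(tables, el, el)
    if (is.null(tb$onsite)) {
      stop(sprintf("homonuclear table %s-%s lacks the on-site line", el, el))
    }
    sh <- c("s")
    if (is.finite(tb$onsite[["p"]]) && any(tb$H[, "pp_sigma"] != 0)) {
      sh <- c(sh, "p")
    }
    shells[[k]] <- sh
    n0[k] <- tb$valence_electrons
  }
  orb_atom <- integer(0); orb_type <- character(0)
  ranges <- vector("list", length(qm_atoms))
  for (k in seq_along(qm_atoms)) {
    labs <- if ("p" %in% shells[[k]]) c("s", "px", "py", "pz") else "s"
    ranges[[k]] <- length(orb_atom) + seq_along(labs)
    orb_atom <- c(orb_atom, rep(k, length(labs)))
    orb_type <- c(orb_type, labs)
  }
  structure(list(atoms = qm_atoms, elements = elements, shells = shells,
                 orb_atom = orb_atom, orb_type = orb_type, ranges = ranges,
                 n0 = n0, n_orb = length(orb_atom)),
            class = "basis_map")
}

#' @export
print.basis_map <- function(x, ...) {
  cat(sprintf("<basis_map> %d atoms, %d orbitals, %g valence electrons\n",
              length(x$atoms), x$n_orb, sum(x$n0)))
  invisible(x)
}
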