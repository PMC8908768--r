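#' QM/MM partition of a frame
#'
#' Assigns every atom of a frame either to the quantum (DFTB) region or to
#' exactly one classical fluctuating-charge fragment with a fixed total
#' charge Q. Atom indices are 1-based everywhere (both in partition files and
#' inside R), following the chemistry convention.
#'
#' @param qm_atoms integer vector of QM atom indices (1-based)
#' @param mm_fragments list of fragments, each a list with `atoms` (integer
#'   indices) and `Q` (total fragment charge, units of e)
#' @param fq_types named character vector mapping atom index (as name) to an
#'   FQ parameter type; when omitted, element symbols are used at validation
#' @param n_atoms total atom count of the frame the partition describes
#' @return object of class `partition`
#' @export
partition <- function(qm_atoms, mm_fragments = list(), fq_types = NULL,
                      n_atoms = NULL) {
  qm_atoms <- as.integer(qm_atoms)
  mm_atoms <- unlist(lapply(mm_fragments, `[[`, "atoms"))
  mm_atoms <- if (is.null(mm_atoms)) integer(0) else as.integer(mm_atoms)
  all_idx <- c(qm_atoms, mm_atoms)
  if (anyDuplicated(all_idx)) {
    dup <- all_idx[duplicated(all_idx)][1]
    stop(sprintf("atom %d assigned to more than one region/fragment", dup))
  }
  if (!is.null(n_atoms)) {
    if (any(all_idx < 1L) || any(all_idx > n_atoms)) {
      stop(sprintf("partition references atom indices outside 1..%d", n_atoms))
    }
    if (length(all_idx) != n_atoms) {
      miss <- setdiff(seq_len(n_atoms), all_idx)
      stop(sprintf("partition does not cover the frame; missing atoms: %s",
                   paste(utils::head(miss, 5), collapse = ", ")))
    }
  }
  for (f in mm_fragments) {
    if (is.null(f$Q) || !is.finite(f$Q)) {
      stop("every MM fragment needs a finite total charge Q")
    }
  }
  structure(
    list(qm_atoms = sort(qm_atoms),
         mm_fragments = mm_fragments,
         fq_types = fq_types,
         n_atoms = n_atoms),
    class = "partition"
  )
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d QM atoms, %d MM fragments (%d MM atoms)\n",
              length(x$qm_atoms), length(x$mm_fragments),
              length(mm_atoms(x))))
  invisible(x)
}

#' MM atom indices of a partition, fragment-ordered
#' @param part a [partition()]
#' @return integer vector (possibly empty)
#' @export
mm_atoms <- function(part) {
  out <- unlist(lapply(part$mm_fragments, `[[`, "atoms"))
  if (is.null(out)) integer(0) else as.integer(out)
}

#' Per-MM-atom FQ type symbols, aligned with [mm_atoms()]
#' @param part a [partition()]
#' @param geom the frame the partition describes (used when no explicit type
#'   map was given: element symbols become the FQ types)
#' @return character vector of FQ type names
#' @export
fq_types_of <- function(part, geom) {
  idx <- mm_atoms(part)
  if (!is.null(part$fq_types)) {
    ty <- part$fq_types[as.character(idx)]
    if (anyNA(ty)) {
      stop(sprintf("MM atom %s has no FQ type assigned",
                   idx[which(is.na(ty))[1]]))
    }
    return(unname(ty))
  }
  geom$elements[idx]
}

#' Read a partition file
#'
#' Declarative text, one statement per line, `#` comments allowed:
#' \preformatted{
#'   qm 1-3
#'   frag 4-6 Q=0
#'   frag 7-9 Q=0 types=O,H,H
#' }
#' Index ranges are 1-based and may be comma-separated lists of ranges or
#' single indices (`4-6,10`). `types=` optionally overrides the element-based
#' FQ type assignment for the fragment's atoms, in atom order.
#'
#' @param path path to a partition file
#' @param n_atoms atom count of the frame (for full validation); optional
#' @return a [partition()]
#' @export
read_partition <- function(path, n_atoms = NULL) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  stmts <- trimws(unlist(strsplit(lines, ";", fixed = TRUE)))
  stmts <- stmts[nzchar(stmts)]
  qm <- integer(0)
  frags <- list()
  types <- character(0)
  for (ln in stmts) {
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    kw <- tolower(toks[1])
    if (kw == "qm") {
      qm <- c(qm, parse_index_ranges(toks[2], ln))
    } else if (kw == "frag") {
      idx <- parse_index_ranges(toks[2], ln)
      qtok <- grep("^[Qq]=", toks, value = TRUE)
      if (length(qtok) != 1L) {
        stop(sprintf("fragment without total charge Q: '%s'", ln))
      }
      Q <- as.numeric(sub("^[Qq]=", "", qtok))
      ttok <- grep("^types=", toks, value = TRUE)
      if (length(ttok) == 1L) {
        ty <- strsplit(sub("^types=", "", ttok), ",")[[1]]
        if (length(ty) != length(idx)) {
          stop(sprintf("types= list length does not match fragment size: '%s'", ln))
        }
        tnew <- stats::setNames(ty, as.character(idx))
        types <- c(types, tnew)
      }
      frags[[length(frags) + 1L]] <- list(atoms = idx, Q = Q)
    } else {
      stop(sprintf("unknown partition statement: '%s'", ln))
    }
  }
  partition(qm, frags,
            fq_types = if (length(types)) types else NULL,
            n_atoms = n_atoms)
}

parse_index_ranges <- function(tok, line) {
  if (is.na(tok)) stop(sprintf("missing index list in '%s'", line))
  parts <- strsplit(tok, ",", fixed = TRUE)[[1]]
  out <- integer(0)
  for (p in parts) {
    m <- regmatches(p, regexec("^([0-9]+)(-([0-9]+))?$", p))[[1]]
    if (length(m) == 0L || !nzchar(m[1])) {
      stop(sprintf("cannot parse index range '%s' in '%s' (1-based indices expected)",
                   p, line))
    }
    a <- as.integer(m[2])
    b <- if (nzchar(m[4])) as.integer(m[4]) else a
    out <- c(out, seq.int(a, b))
  }
  out
}

#' Write a partition file
#' @param part a [partition()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_partition <- function(part, path) {
  fmt_ranges <- function(idx) {
    idx <- sort(idx)
    brk <- c(0L, which(diff(idx) != 1L), length(idx))
    paste(vapply(seq_len(length(brk) - 1L), function(k) {
      seg <- idx[(brk[k] + 1L):brk[k + 1L]]
      if (length(seg) == 1L) as.character(seg)
      else sprintf("%d-%d", seg[1], seg[length(seg)])
    }, ""), collapse = ",")
  }
  out <- sprintf("qm %s", fmt_ranges(part$qm_atoms))
  for (f in part$mm_fragments) {
    ln <- sprintf("frag %s Q=%g", fmt_ranges(f$atoms), f$Q)
    if (!is.null(part$fq_types)) {
      ty <- part$fq_types[as.character(sort(f$atoms))]
      if (!anyNA(ty)) ln <- paste0(ln, " types=", paste(ty, collapse = ","))
    }
    out <- c(out, ln)
  }
  writeLines(out, path)
  invisible(path)
}
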