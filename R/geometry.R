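#' Molecular geometry container
#'
#' A single molecular frame: element symbols plus Cartesian coordinates.
#' Coordinates are stored in bohr; the XYZ reader/writer converts from/to
#' angstrom at the file boundary.
#'
#' @param elements character vector of element symbols
#' @param coords N x 3 numeric matrix of coordinates in bohr
#' @param frame_id integer frame index (0-based, matching multi-frame files)
#' @return an object of class `geometry` with fields `elements`, `coords`
#'   (bohr) and `frame_id`
#' @export
geometry <- function(elements, coords, frame_id = 0L) {
  coords <- as.matrix(coords)
  if (length(elements) < 1L) stop("geometry must contain at least one atom")
  if (!is.numeric(coords) || ncol(coords) != 3L ||
      nrow(coords) != length(elements)) {
    stop("coords must be an N x 3 numeric matrix matching length(elements)")
  }
  if (!all(is.finite(coords))) stop("geometry coordinates must be finite")
  structure(
    list(elements = as.character(elements),
         coords = unname(coords),
         frame_id = as.integer(frame_id)),
    class = "geometry"
  )
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry> frame %d: %d atoms (%s)\n", x$frame_id,
              length(x$elements),
              paste(names(table(x$elements)), table(x$elements),
                    sep = "x", collapse = ", ")))
  invisible(x)
}

#' Number of atoms in a geometry
#' @param geom a [geometry()]
#' @return integer atom count
#' @export
n_atoms <- function(geom) length(geom$elements)

#' Interatomic distance matrix in bohr
#' @param geom a [geometry()]
#' @return N x N matrix of pair distances (bohr)
#' @export
distance_matrix <- function(geom) {
  as.matrix(stats::dist(geom$coords))
}

#' Read a (multi-frame) XYZ file
#'
#' Reads concatenated XYZ blocks (atom-count line, comment line, then one
#' `symbol x y z` line per atom, coordinates in angstrom). Every frame in the
#' file becomes one [geometry()] with coordinates converted to bohr and
#' `frame_id` numbered sequentially from 0.
#'
#' @param path path to an XYZ file
#' @return list of `geometry` objects (empty list, with a warning, for an
#'   empty file)
#' @export
read_xyz_frames <- function(path) {
  lines <- readLines(path)
  # trailing blank lines are tolerated
  while (length(lines) > 0L && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L) {
    warning(sprintf("empty XYZ file: %s", path))
    return(list())
  }
  frames <- list()
  i <- 1L
  frame_id <- 0L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L) {
      stop(sprintf("malformed atom-count line %d in %s: '%s'", i, path, lines[i]))
    }
    if (i + 1L + nat > length(lines)) {
      stop(sprintf("frame starting at line %d of %s declares %d atoms but the file ends early",
                   i, path, nat))
    }
    atom_lines <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(atom_lines), "\\s+")
    bad <- which(vapply(toks, length, 1L) < 4L)
    if (length(bad) > 0L) {
      stop(sprintf("malformed atom line %d in %s", i + 1L + bad[1L], path))
    }
    elements <- vapply(toks, `[[`, "", 1L)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) {
      stop(sprintf("non-numeric coordinates in frame starting at line %d of %s", i, path))
    }
    frames[[frame_id + 1L]] <- geometry(elements, ang_to_bohr(xyz), frame_id)
    frame_id <- frame_id + 1L
    i <- i + 2L + nat
  }
  frames
}

#' Write geometries as a multi-frame XYZ file
#'
#' @param frames a `geometry` or list of `geometry` objects (coordinates in
#'   bohr; written in angstrom)
#' @param path output path
#' @param comments optional character vector of per-frame comment lines
#' @return `path`, invisibly
#' @export
write_xyz_frames <- function(frames, path, comments = NULL) {
  if (inherits(frames, "geometry")) frames <- list(frames)
  out <- character(0)
  for (k in seq_along(frames)) {
    g <- frames[[k]]
    cmt <- if (is.null(comments)) sprintf("frame %d", g$frame_id) else comments[[k]]
    ang <- bohr_to_ang(g$coords)
    out <- c(out, as.character(n_atoms(g)), cmt,
             sprintf("%-3s %18.10f %18.10f %18.10f",
                     g$elements, ang[, 1], ang[, 2], ang[, 3]))
  }
  writeLines(out, path)
  invisible(path)
}

# rigid-body helpers used by tests and fixtures
translate_geometry <- function(geom, shift) {
  geom$coords <- sweep(geom$coords, 2L, shift, `+`)
  geom
}

rotate_geometry <- function(geom, rotmat) {
  geom$coords <- geom$coords %*% t(rotmat)
  geom
}
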