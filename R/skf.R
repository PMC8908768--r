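#' Read a Slater-Koster parameter file (.skf, simple dialect)
#'
#' Parses the "simple format" .skf dialect: a grid line (`gridDist nGrid`),
#' for homonuclear files a line of on-site energies / Hubbard parameters /
#' occupations (`Ed Ep Es SPE Ud Up Us fd fp fs`), a mass+polynomial line,
#' `nGrid` rows of 10 Hamiltonian and 10 overlap channels in the standard
#' order (`dd sigma, dd pi, dd delta, pd sigma, pd pi, pp sigma, pp pi,
#' sd sigma, sp sigma, ss sigma`), and an optional `Spline` repulsive block.
#' Only the s/p channels (`ss sigma`, `sp sigma`, `pp sigma`, `pp pi`) are
#' retained; the extended f-shell dialect is not supported. All values are in
#' atomic units. Grid row `k` corresponds to distance `k * grid_step` bohr.
#'
#' @param path path to an .skf file
#' @param pair length-2 character vector of element symbols `(A, B)`; the
#'   file is the A-B table (first-element orbitals in the bra)
#' @return an object of class `skf_table` with fields `element_pair`,
#'   `grid_step`, `n_grid`, `H` and `S` (n_grid x 4 matrices with columns
#'   `ss_sigma`, `sp_sigma`, `pp_sigma`, `pp_pi`), and for homonuclear files
#'   `onsite`, `hubbard`, `occupations`, `valence_electrons`; `spline` holds
#'   the repulsive block or `NULL`
#' @export
read_skf <- function(path, pair) {
  stopifnot(length(pair) == 2L)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  num <- function(line) {
    # the dialect allows both whitespace and comma separators
    as.numeric(strsplit(trimws(gsub(",", " ", line)), "\\s+")[[1]])
  }
  g <- num(lines[1])
  grid_step <- g[1]
  n_grid <- as.integer(g[2])
  if (!is.finite(grid_step) || grid_step <= 0) {
    stop(sprintf("non-positive grid step in %s", path))
  }
  homonuclear <- identical(pair[1], pair[2])
  i <- 2L
  onsite <- hubbard <- occupations <- NULL
  valence_electrons <- NA_real_
  if (homonuclear) {
    v <- num(lines[i]); i <- i + 1L
    if (length(v) < 10L) stop(sprintf("homonuclear %s: on-site line needs 10 fields", path))
    # order: Ed Ep Es SPE Ud Up Us fd fp fs
    onsite <- c(d = v[1], p = v[2], s = v[3])
    hubbard <- c(d = v[5], p = v[6], s = v[7])
    occupations <- c(d = v[8], p = v[9], s = v[10])
    valence_electrons <- sum(occupations)
    if (any(hubbard[c("s", "p")][is.finite(hubbard[c("s", "p")])] < 0)) {
      stop(sprintf("negative Hubbard parameter in %s", path))
    }
  }
  i <- i + 1L  # mass + polynomial-repulsion line (both dialect variants carry it)
  rows <- t(vapply(lines[i:(i + n_grid - 1L)], num, numeric(20), USE.NAMES = FALSE))
  i <- i + n_grid
  chan <- c(ss_sigma = 10L, sp_sigma = 9L, pp_sigma = 6L, pp_pi = 7L)
  H <- rows[, chan, drop = FALSE]
  S <- rows[, chan + 10L, drop = FALSE]
  colnames(H) <- colnames(S) <- names(chan)

  spline <- NULL
  spl_at <- which(trimws(lines) == "Spline")
  if (length(spl_at) == 1L) {
    j <- spl_at + 1L
    hd <- num(lines[j]); j <- j + 1L
    n_int <- as.integer(hd[1]); cutoff <- hd[2]
    expc <- num(lines[j]); j <- j + 1L
    knots <- t(vapply(lines[j:(j + n_int - 1L)], num_pad8, numeric(8),
                      USE.NAMES = FALSE))
    colnames(knots) <- c("start", "end", paste0("c", 0:5))
    if (cutoff < knots[1, "start"]) {
      stop(sprintf("repulsive cutoff below first knot in %s", path))
    }
    spline <- list(n_int = n_int, cutoff = cutoff, exp_coef = expc,
                   knots = knots)
  }

  structure(
    list(element_pair = as.character(pair), grid_step = grid_step,
         n_grid = n_grid, H = H, S = S,
         onsite = onsite, hubbard = hubbard, occupations = occupations,
         valence_electrons = valence_electrons, spline = spline),
    class = "skf_table"
  )
}

num_pad8 <- function(line) {
  v <- as.numeric(strsplit(trimws(line), "\\s+")[[1]])
  length(v) <- 8L
  v[is.na(v)] <- 0
  v
}

#' @export
print.skf_table <- function(x, ...) {
  cat(sprintf("<skf_table> %s-%s: %d grid points, step %.4f bohr%s%s\n",
              x$element_pair[1], x$element_pair[2], x$n_grid, x$grid_step,
              if (!is.null(x$onsite)) " (homonuclear)" else "",
              if (!is.null(x$spline)) ", repulsive spline" else ""))
  invisible(x)
}

#' Evaluate a tabulated Slater-Koster channel at arbitrary distance
#'
#' Local cubic interpolation through the 4 grid points nearest to `r`.
#' Distances beyond the last grid point evaluate to exactly 0 (the tables are
#' built to decay); distances below the first grid point use the first four
#' points.
#'
#' @param table an `skf_table`
#' @param channel one of `"ss_sigma"`, `"sp_sigma"`, `"pp_sigma"`, `"pp_pi"`
#' @param r distance in bohr (scalar or vector)
#' @param what `"H"` or `"S"`
#' @return interpolated value(s), atomic units
#' @export
skf_eval <- function(table, channel, r, what = c("H", "S")) {
  what <- match.arg(what)
  y <- table[[what]][, channel]
  h <- table$grid_step
  n <- table$n_grid
  vapply(r, function(ri) {
    if (ri > n * h) return(0)
    k <- floor(ri / h)          # grid row k sits at distance k*h
    i0 <- min(max(k - 1L, 1L), n - 3L)
    xs <- (i0:(i0 + 3L)) * h
    ys <- y[i0:(i0 + 3L)]
    lagrange4(xs, ys, ri)
  }, numeric(1))
}

lagrange4 <- function(xs, ys, x) {
  out <- 0
  for (j in 1:4) {
    lj <- 1
    for (m in 1:4) if (m != j) lj <- lj * (x - xs[m]) / (xs[j] - xs[m])
    out <- out + ys[j] * lj
  }
  out
}

#' Evaluate the repulsive pair potential of an .skf table
#'
#' Below the first knot the exponential head `exp(-a1*r + a2) + a3` is used;
#' inside each knot interval the tabulated polynomial in `(r - start)` is
#' evaluated (cubic, quintic for the final interval); beyond the cutoff the
#' repulsive energy is 0.
#'
#' @param table an `skf_table` with a spline block
#' @param r distance in bohr (scalar or vector)
#' @return repulsive energy in hartree
#' @export
skf_repulsive <- function(table, r) {
  sp <- table$spline
  if (is.null(sp)) {
    stop(sprintf("no Spline repulsive block in table %s-%s",
                 table$element_pair[1], table$element_pair[2]))
  }
  kn <- sp$knots
  vapply(r, function(ri) {
    if (ri >= sp$cutoff) return(0)
    if (ri < kn[1, "start"]) {
      a <- sp$exp_coef
      return(exp(-a[1] * ri + a[2]) + a[3])
    }
    idx <- max(which(kn[, "start"] <= ri))
    d <- ri - kn[idx, "start"]
    cf <- kn[idx, paste0("c", 0:5)]
    sum(cf * d^(0:5))
  }, numeric(1))
}

#' Bundle .skf tables for a set of elements
#'
#' @param tables named list of `skf_table` objects; names are "A-B" pairs
#' @return object of class `skf_set`
#' @export
skf_set <- function(tables) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  structure(list(tables = tables), class = "skf_set")
}

#' Look up the table for an ordered element pair
#' @param set an `skf_set`
#' @param a,b element symbols
#' @return the `skf_table` for the pair `a`-`b`
#' @export
skf_pair <- function(set, a, b) {
  key <- paste(a, b, sep = "-")
  tb <- set$tables[[key]]
  if (is.null(tb)) stop(sprintf("no Slater-Koster table for element pair %s", key))
  tb
}

#' Load an element-to-file .skf mapping
#'
#' @param files named character vector or list mapping "A-B" pair names to
#'   .skf paths
#' @return an `skf_set`
#' @export
read_skf_set <- function(files) {
  tables <- lapply(names(files), function(key) {
    pr <- strsplit(key, "-", fixed = TRUE)[[1]]
    read_skf(files[[key]], pr)
  })
  names(tables) <- names(files)
  skf_set(tables)
}
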