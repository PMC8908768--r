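#' Toy element specification for generated Slater-Koster tables
#'
#' Describes one element of the self-contained toy parameter world: shells,
#' on-site energies, Hubbard parameters, neutral occupations, smooth
#' exponential-decay generators for the Hamiltonian/overlap channels, and a
#' short-range repulsive spec. The generated integrals are analytic toy
#' forms chosen for smoothness, correct symmetry structure and physically
#' sane magnitudes; they are not fitted to any published parameter set.
#'
#' @param symbol element symbol
#' @param shells `"s"` or `c("s", "p")`
#' @param onsite named vector of shell energies (hartree); `p` entry
#'   required only when a p shell is present
#' @param hubbard atomic Hubbard parameter U (hartree/e^2)
#' @param occupations named vector of neutral shell occupations
#' @param decay exponential decay constant of the element's integrals
#'   (1/bohr)
#' @param h_strength,s_strength named prefactors for channels `ss`, `sp`,
#'   `pp_sigma`, `pp_pi` (Hamiltonian, overlap)
#' @param rep list with `k` (prefactor, hartree/bohr^3) and `rc` (cutoff,
#'   bohr) of the repulsive `k (rc - r)^3` pair potential
#' @return object of class `toy_element_spec`
#' @export
toy_element_spec <- function(symbol, shells, onsite, hubbard, occupations,
                             decay, h_strength, s_strength, rep) {
  stopifnot(hubbard > 0, decay > 0, rep$k >= 0, rep$rc > 0.5)
  structure(list(symbol = symbol, shells = shells, onsite = onsite,
                 hubbard = hubbard, occupations = occupations,
                 decay = decay, h_strength = h_strength,
                 s_strength = s_strength, rep = rep),
            class = "toy_element_spec")
}

#' Built-in toy elements (hydrogen-like "H", oxygen-like "O")
#'
#' @return named list of [toy_element_spec()] objects
#' @export
toy_elements <- function() {
  list(
    H = toy_element_spec(
      "H", shells = "s",
      onsite = c(s = -0.24), hubbard = 0.42, occupations = c(s = 1),
      decay = 1.4,
      h_strength = c(ss = -0.40, sp = 0.30, pp_sigma = 0, pp_pi = 0),
      s_strength = c(ss = 0.35, sp = 0.28, pp_sigma = 0, pp_pi = 0),
      rep = list(k = 0.008, rc = 3.5)),
    O = toy_element_spec(
      "O", shells = c("s", "p"),
      onsite = c(s = -0.88, p = -0.33), hubbard = 0.50,
      occupations = c(s = 2, p = 4),
      decay = 1.5,
      h_strength = c(ss = -0.50, sp = 0.36, pp_sigma = 0.30, pp_pi = -0.18),
      s_strength = c(ss = 0.33, sp = 0.26, pp_sigma = 0.24, pp_pi = -0.16),
      rep = list(k = 0.015, rc = 4.0))
  )
}

toy_grid <- function() list(step = 0.1, n = 190L)

# smooth decaying radial shape shared by all toy channels
toy_radial <- function(pref, decay, r) {
  pref * exp(-decay * r) * (1 + 0.5 * r)
}

toy_channels <- function(spec_a, spec_b, r) {
  decay <- (spec_a$decay + spec_b$decay) / 2
  has_p_b <- "p" %in% spec_b$shells
  has_p_both <- ("p" %in% spec_a$shells) && has_p_b
  comb <- function(field, name, active) {
    if (!active) return(rep(0, length(r)))
    pref <- (spec_a[[field]][[name]] + spec_b[[field]][[name]]) / 2
    toy_radial(pref, decay, r)
  }
  list(
    H = cbind(ss_sigma = comb("h_strength", "ss", TRUE),
              sp_sigma = comb("h_strength", "sp", has_p_b),
              pp_sigma = comb("h_strength", "pp_sigma", has_p_both),
              pp_pi    = comb("h_strength", "pp_pi", has_p_both)),
    S = cbind(ss_sigma = comb("s_strength", "ss", TRUE),
              sp_sigma = comb("s_strength", "sp", has_p_b),
              pp_sigma = comb("s_strength", "pp_sigma", has_p_both),
              pp_pi    = comb("s_strength", "pp_pi", has_p_both))
  )
}

#' Write a toy Slater-Koster file for an ordered element pair
#'
#' Emits the simple .skf dialect readable by [read_skf()]: grid header,
#' on-site/Hubbard/occupation line for homonuclear pairs, mass line, 20
#' gridded channels per row, and a Spline repulsive block representing the
#' exact cubic `k (rc - r)^3` pair potential. Deterministic: identical specs
#' yield byte-identical files.
#'
#' @param spec_a,spec_b [toy_element_spec()] of the bra and ket elements
#' @param path output path
#' @return `path`, invisibly
#' @export
write_toy_skf <- function(spec_a, spec_b, path) {
  g <- toy_grid()
  r <- g$step * seq_len(g$n)
  ch <- toy_channels(spec_a, spec_b, r)
  fmt <- function(v) paste(sprintf("%.14e", v), collapse = "  ")
  lines <- sprintf("%.6f %d", g$step, g$n)
  homonuclear <- identical(spec_a$symbol, spec_b$symbol)
  if (homonuclear) {
    on_p <- if ("p" %in% spec_a$shells) spec_a$onsite[["p"]] else 0
    f_p <- if ("p" %in% spec_a$shells) spec_a$occupations[["p"]] else 0
    # Ed Ep Es SPE Ud Up Us fd fp fs
    lines <- c(lines, fmt(c(0, on_p, spec_a$onsite[["s"]], 0,
                            spec_a$hubbard, spec_a$hubbard, spec_a$hubbard,
                            0, f_p, spec_a$occupations[["s"]])))
  }
  lines <- c(lines, fmt(c(1.0, rep(0, 9))))  # mass + unused polynomial slots
  zeros5 <- matrix(0, g$n, 5)
  zeros1 <- matrix(0, g$n, 1)
  rows <- cbind(zeros5, ch$H[, "pp_sigma"], ch$H[, "pp_pi"], zeros1,
                ch$H[, "sp_sigma"], ch$H[, "ss_sigma"],
                zeros5, ch$S[, "pp_sigma"], ch$S[, "pp_pi"], zeros1,
                ch$S[, "sp_sigma"], ch$S[, "ss_sigma"])
  lines <- c(lines, apply(rows, 1L, fmt))

  k <- sqrt(spec_a$rep$k * spec_b$rep$k)
  rc <- (spec_a$rep$rc + spec_b$rep$rc) / 2
  r0 <- 0.5
  n_int <- 8L
  starts <- seq(r0, rc, length.out = n_int + 1L)
  lines <- c(lines, "Spline", sprintf("%d %.14e", n_int, rc))
  # exponential head, value-continuous at the first knot
  a1 <- 1.5
  f0 <- k * (rc - r0)^3
  lines <- c(lines, fmt(c(a1, log(f0) + a1 * r0, 0)))
  for (i in seq_len(n_int)) {
    s <- starts[i]; e <- starts[i + 1L]
    w <- rc - s
    cf <- c(k * w^3, -3 * k * w^2, 3 * k * w, -k)
    if (i < n_int) {
      lines <- c(lines, fmt(c(s, e, cf)))
    } else {
      lines <- c(lines, fmt(c(s, e, cf, 0, 0)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the full toy .skf file set for a set of elements
#'
#' @param specs named list of [toy_element_spec()] (default [toy_elements()])
#' @param dir output directory
#' @return named character vector mapping "A-B" pair names to file paths
#' @export
write_toy_skf_set <- function(specs = toy_elements(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- character(0)
  for (a in names(specs)) {
    for (b in names(specs)) {
      key <- paste(a, b, sep = "-")
      p <- file.path(dir, paste0(key, ".skf"))
      write_toy_skf(specs[[a]], specs[[b]], p)
      out[key] <- p
    }
  }
  out
}

rigid_water <- function() {
  # OH 0.9572 angstrom, HOH 104.52 degrees, oxygen at the origin
  oh <- ang_to_bohr(0.9572)
  half <- 104.52 / 2 * pi / 180
  rbind(c(0, 0, 0),
        c(oh * sin(half), 0, oh * cos(half)),
        c(-oh * sin(half), 0, oh * cos(half)))
}

random_rotation <- function() {
  # QR-based uniform random rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a toy solvated cluster: one QM water in a shell of FQ waters
#'
#' A rigid 3-site water (the chromophore stand-in, treated at the DFTB
#' level) surrounded by `n_solvent` rigid waters placed with random position
#' and orientation by seeded rejection sampling; no two atoms of different
#' molecules come closer than 2.5 bohr. Each solvent water is one MM
#' fragment with total charge Q = 0.
#'
#' @param n_solvent number of FQ waters (>= 0)
#' @param seed RNG seed (placement is fully deterministic given the seed)
#' @param r_min minimum intermolecular atom-atom distance (bohr)
#' @return list with `geom` (a [geometry()]) and `part` (a [partition()])
#' @export
make_water_cluster <- function(n_solvent = 10L, seed = 1L, r_min = 2.5) {
  stopifnot(n_solvent >= 0L)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  w0 <- rigid_water()
  coords <- w0
  elements <- c("O", "H", "H")
  r_max <- 5 + 3.2 * max(n_solvent, 1)^(1 / 3)
  for (k in seq_len(n_solvent)) {
    placed <- FALSE
    for (try in seq_len(5000L)) {
      center <- stats::runif(3, -1, 1)
      if (sum(center^2) > 1) next
      center <- center * r_max
      if (sqrt(sum(center^2)) < 4.0) next   # keep a shell around the solute
      w <- t(random_rotation() %*% t(w0)) + rep(center, each = 3)
      dmin <- min(proxy_cross_dist(w, coords))
      if (dmin >= r_min) {
        coords <- rbind(coords, w)
        elements <- c(elements, "O", "H", "H")
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf("could not place solvent molecule %d without overlap; increase the box by lowering n_solvent or r_min",
                   k))
    }
  }
  geom <- geometry(elements, coords)
  frags <- lapply(seq_len(n_solvent), function(k) {
    list(atoms = 3L + (k - 1L) * 3L + 1:3, Q = 0)
  })
  part <- partition(1:3, frags, n_atoms = n_atoms(geom))
  list(geom = geom, part = part)
}

proxy_cross_dist <- function(A, B) {
  # all pair distances between rows of A and rows of B
  out <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    out[i, ] <- sqrt(colSums((t(B) - A[i, ])^2))
  }
  out
}

#' Jittered snapshot ensemble from a base geometry
#'
#' Emulates configurational sampling: frame 0 is the base geometry, each
#' further frame displaces every Cartesian coordinate by seeded Gaussian
#' noise of the given amplitude (standard deviation, bohr).
#'
#' @param base a [geometry()]
#' @param n_frames total number of frames including the base
#' @param amplitude Gaussian displacement standard deviation (bohr), >= 0
#' @param seed RNG seed
#' @return list of [geometry()] frames with sequential `frame_id`
#' @export
jitter_snapshots <- function(base, n_frames, amplitude = 0.05, seed = 1L) {
  stopifnot(amplitude >= 0, n_frames >= 1L)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  frames <- vector("list", n_frames)
  base$frame_id <- 0L
  frames[[1]] <- base
  for (k in seq_len(n_frames - 1L)) {
    g <- base
    g$coords <- g$coords + matrix(stats::rnorm(length(g$coords), 0, amplitude),
                                  ncol = 3)
    g$frame_id <- k
    frames[[k + 1L]] <- g
  }
  frames
}

#' Emit a complete self-test workspace
#'
#' Writes toy .skf tables, a multi-frame XYZ snapshot ensemble of a solvated
#' toy water cluster, the matching partition file, and a YAML run config
#' wiring them together with the documented toy FQ parameters.
#'
#' @param dir output directory (created if needed)
#' @param n_solvent number of FQ waters
#' @param n_frames number of snapshot frames
#' @param seed RNG seed controlling placement and jitter
#' @param amplitude jitter amplitude (bohr)
#' @return path of the written config file, invisibly; all artifact paths
#'   are recorded inside it
#' @export
make_fixture_workspace <- function(dir, n_solvent = 10L, n_frames = 20L,
                                   seed = 1L, amplitude = 0.05) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  skf_dir <- file.path(dir, "skf")
  skf_files <- write_toy_skf_set(dir = skf_dir)
  cl <- make_water_cluster(n_solvent, seed = seed)
  frames <- jitter_snapshots(cl$geom, n_frames, amplitude = amplitude,
                             seed = seed + 1L)
  geom_path <- file.path(dir, "snapshots.xyz")
  write_xyz_frames(frames, geom_path)
  part_path <- file.path(dir, "partition.txt")
  write_partition(cl$part, part_path)
  fqp <- toy_fq_water_params()
  cfg <- list(
    paths = list(geometry = "snapshots.xyz", partition = "partition.txt",
                 skf = as.list(file.path("skf", basename(skf_files))),
                 output = "out"),
    fq = list(chi = as.list(fqp$chi), eta = as.list(fqp$eta),
              kernel = fqp$kernel),
    scf = default_settings()$scf,
    response = default_settings()$response,
    # the toy chromophore's excitations span roughly 1.5-18 eV; the fixture
    # grid covers them all so no convolution area is truncated
    spectra = utils::modifyList(default_settings()$spectra,
                                list(grid_min_ev = 0.5, grid_max_ev = 20.0)),
    seed = seed
  )
  names(cfg$paths$skf) <- names(skf_files)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
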