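# Shared fixtures, built once per test session.

.fixture_env <- new.env(parent = emptyenv())

# toy Slater-Koster tables written to a session tempdir and read back
toy_tables <- function() {
  if (is.null(.fixture_env$tables)) {
    dir <- file.path(tempdir(), "dftbfq_toy_skf")
    files <- write_toy_skf_set(dir = dir)
    .fixture_env$skf_files <- files
    .fixture_env$tables <- read_skf_set(files)
  }
  .fixture_env$tables
}

toy_skf_files <- function() {
  toy_tables()
  .fixture_env$skf_files
}

# gas-phase toy water (all-QM)
gas_water_state <- function() {
  if (is.null(.fixture_env$gas_state)) {
    cl <- make_water_cluster(0L, seed = 11L)
    .fixture_env$gas_state <- scf(cl$geom, toy_tables())
  }
  .fixture_env$gas_state
}

# solvated toy water: 1 QM water + n FQ waters
solvated_state <- function(n_solvent = 4L, seed = 7L) {
  key <- sprintf("solv_%d_%d", n_solvent, seed)
  if (is.null(.fixture_env[[key]])) {
    cl <- make_water_cluster(n_solvent, seed = seed)
    .fixture_env[[key]] <- scf(cl$geom, toy_tables(), cl$part,
                               toy_fq_water_params())
  }
  .fixture_env[[key]]
}

# a custom s-only homonuclear table with zero overlap and exact hopping h at
# distance d (used for closed-form eigenvalue checks)
hopping_element <- function(onsite = -0.5, hopping = -0.2, d = 2.0,
                            decay = 1.4) {
  pref <- hopping / (exp(-decay * d) * (1 + 0.5 * d))
  toy_element_spec(
    "X", shells = "s", onsite = c(s = onsite), hubbard = 0.4,
    occupations = c(s = 1), decay = decay,
    h_strength = c(ss = pref, sp = 0, pp_sigma = 0, pp_pi = 0),
    s_strength = c(ss = 0, sp = 0, pp_sigma = 0, pp_pi = 0),
    rep = list(k = 0, rc = 3.0))
}

hopping_tables <- function(...) {
  spec <- hopping_element(...)
  dir <- tempfile("hoptab_")
  dir.create(dir)
  p <- file.path(dir, "X-X.skf")
  write_toy_skf(spec, spec, p)
  read_skf_set(c("X-X" = p))
}

# random small FQ problem: n_mm sites scattered in space, random fragment
# structure, random chi/eta; returns the pieces needed by solve_fq and the
# brute-force oracle
random_fq_problem <- function(n_mm, n_frag = NULL, kernel = "ohno") {
  if (is.null(n_frag)) n_frag <- sample(1:min(2L, n_mm), 1L)
  coords <- matrix(stats::runif(3 * n_mm, -4, 4), ncol = 3)
  # keep sites apart so the kernel matrix is well-conditioned
  while (n_mm > 1L && min(stats::dist(coords)) < 1.0) {
    coords <- matrix(stats::runif(3 * n_mm, -4, 4), ncol = 3)
  }
  eta <- stats::runif(n_mm, 0.4, 0.9)
  chi <- stats::runif(n_mm, -0.2, 0.3)
  Q <- stats::runif(n_frag, -0.5, 0.5)
  frag_of <- sort(sample(rep(seq_len(n_frag), length.out = n_mm)))
  n_tot <- n_mm + n_frag
  M <- matrix(0, n_tot, n_tot)
  for (i in seq_len(n_mm)) {
    for (j in seq_len(n_mm)) {
      if (i == j) {
        M[i, i] <- eta[i]
      } else {
        r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
        M[i, j] <- fq_kernel(r, eta[i], eta[j], kernel)
      }
    }
  }
  for (f in seq_len(n_frag)) {
    rows <- which(frag_of == f)
    M[n_mm + f, rows] <- 1
    M[rows, n_mm + f] <- 1
  }
  list(M = M, n_mm = n_mm, n_frag = n_frag, chi = chi, eta = eta, Q = Q,
       frag_of = frag_of, coords = coords,
       fqm = fq_matrix_from_dense(M, n_mm, n_frag, chi = chi, Q = Q))
}

# independent oracle: minimize the constrained FQ functional numerically by
# eliminating one charge per fragment (exact equality constraints), BFGS on
# the remaining free charges
fq_minimize_oracle <- function(prob, V = NULL) {
  n_mm <- prob$n_mm
  if (is.null(V)) V <- numeric(n_mm)
  J <- prob$M[seq_len(n_mm), seq_len(n_mm), drop = FALSE]
  last_of_frag <- vapply(seq_len(prob$n_frag),
                         function(f) max(which(prob$frag_of == f)), 1L)
  free <- setdiff(seq_len(n_mm), last_of_frag)
  expand <- function(x) {
    q <- numeric(n_mm)
    q[free] <- x
    for (f in seq_len(prob$n_frag)) {
      members <- which(prob$frag_of == f)
      fixed <- last_of_frag[f]
      q[fixed] <- prob$Q[f] - sum(q[setdiff(members, fixed)])
    }
    q
  }
  fn <- function(x) {
    q <- expand(x)
    sum(prob$chi * q) + 0.5 * sum(q * (J %*% q)) + sum(q * V)
  }
  gr <- function(x) {
    q <- expand(x)
    g <- prob$chi + drop(J %*% q) + V
    vapply(free, function(i) {
      e <- last_of_frag[prob$frag_of[i]]
      g[i] - g[e]
    }, numeric(1))
  }
  if (length(free) == 0L) return(expand(numeric(0)))
  opt <- stats::optim(numeric(length(free)), fn, gr, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 5000))
  expand(opt$par)
}

random_rotation_matrix <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
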