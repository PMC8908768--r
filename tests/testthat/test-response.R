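test_that("transition charges sum to zero over atoms for every pair", {
  st <- gas_water_state()
  tb <- transition_basis(st)
  expect_true(all(abs(rowSums(tb$tq)) < 1e-8))
  expect_true(all(tb$de > 0))
})

test_that("homonuclear sigma->sigma* transition charges are antisymmetric", {
  tabs <- hopping_tables(onsite = -0.5, hopping = -0.2, d = 2.0)
  g <- geometry(c("X", "X"), rbind(c(0, 0, 0), c(2, 0, 0)))
  st <- scf(g, tabs)
  q <- transition_charges(st$C, st$S, st$basis, 1L, 2L)
  expect_equal(q[1], -q[2], tolerance = 1e-12)
  expect_gt(abs(q[1]), 1e-3)
})

test_that("identity overlap reduces transition charges to coefficient products", {
  tabs <- hopping_tables()
  g <- geometry(c("X", "X"), rbind(c(0, 0, 0), c(2, 0, 0)))
  st <- scf(g, tabs)
  q <- transition_charges(st$C, diag(2), st$basis, 1L, 2L)
  direct <- vapply(st$basis$ranges, function(rg) {
    sum(st$C[rg, 1] * st$C[rg, 2])
  }, numeric(1))
  expect_equal(q, direct, tolerance = 1e-14)
})

test_that("gamma coupling matrix is symmetric with zero rows for dark pairs", {
  st <- gas_water_state()
  tb <- transition_basis(st)
  K <- build_coupling(tb, st$gamma)
  expect_lt(max(abs(K - t(K))), 1e-12)
  tb0 <- tb
  tb0$tq[3, ] <- 0
  K0 <- build_coupling(tb0, st$gamma)
  expect_true(all(abs(K0[3, ]) < 1e-15))
  # diagonal of a positive-definite quadratic form is non-negative
  expect_true(all(diag(K) >= 0))
})

test_that("FQ response coupling matches the brute-force quadratic oracle", {
  st <- solvated_state()
  tb <- transition_basis(st)
  Kfq <- build_kfq(tb, st$fqm, st$G)
  expect_lt(max(abs(Kfq - t(Kfq))), 1e-12)
  expect_true(all(diag(Kfq) <= 1e-14))
  # dense-inverse oracle on the full KKT matrix
  Minv <- solve(st$fqm$M)
  V <- tb$tq %*% st$G                       # n_pair x n_mm
  Vpad <- cbind(V, matrix(0, nrow(V), st$fqm$n_frag))
  K_oracle <- -(Vpad %*% Minv %*% t(Vpad))
  expect_lt(max(abs(Kfq - K_oracle)), 1e-10)
})

test_that("FQ response equals constrained minimization under the perturbing potential", {
  set.seed(99)
  prob <- random_fq_problem(5L, n_frag = 2L)
  # two artificial transition-potential columns on the FQ sites
  V1 <- stats::runif(5, -0.2, 0.2)
  V2 <- stats::runif(5, -0.2, 0.2)
  # package route: -V1' M^-1 V2 with zero-padded constraint rows
  tb_fake <- structure(list(de = c(0.3, 0.4), tq = diag(2)), class = "transition_basis")
  Gfake <- rbind(V1, V2)                    # so tq %*% G = rbind(V1, V2)
  Kfq <- build_kfq(tb_fake, prob$fqm, Gfake)
  # oracle: minimize the charge functional with chi = 0, Q = 0 under V1,
  # then contract the relaxed charges with V2
  prob0 <- prob; prob0$chi <- numeric(5); prob0$Q <- numeric(2)
  q1 <- fq_minimize_oracle(prob0, V = V1)
  q2 <- fq_minimize_oracle(prob0, V = V2)
  expect_lt(abs(Kfq[1, 2] - sum(V2 * q1)), 1e-8)
  expect_lt(abs(Kfq[2, 1] - sum(V1 * q2)), 1e-8)
  expect_lt(abs(Kfq[1, 1] - sum(V1 * q1)), 1e-8)
  expect_true(all(diag(Kfq) <= 0))
})

test_that("single-pair response has the closed-form Casida root", {
  tb <- structure(list(de = 0.3, tq = matrix(0, 1, 1),
                       dip = matrix(0, 1, 3), f_single = 0,
                       R = matrix(0, 1, 3)),
                  class = "transition_basis")
  ex <- solve_casida(tb, K = matrix(0.05, 1, 1), Kfq = NULL, n_states = 1L)
  expect_equal(ex$omega, sqrt(0.3^2 + 4 * 0.3 * 0.05), tolerance = 1e-12)
})

test_that("zero coupling returns bare orbital-energy differences", {
  st <- gas_water_state()
  tb <- transition_basis(st)
  n <- length(tb$de)
  ex <- solve_casida(tb, K = matrix(0, n, n), n_states = n)
  expect_equal(ex$omega, sort(tb$de), tolerance = 1e-12)
})

test_that("reduced Hermitian and full two-block solvers agree", {
  for (seed in c(3L, 17L)) {
    cl <- make_water_cluster(2L, seed = seed)
    st <- scf(cl$geom, toy_tables(), cl$part, toy_fq_water_params())
    ex_r <- tddftb_excitations(st, solver = "reduced")
    ex_f <- tddftb_excitations(st, solver = "full")
    expect_lt(max(abs(ex_r$omega - ex_f$omega)), 1e-9)
  }
})

test_that("requesting more states than the basis holds is an error", {
  st <- gas_water_state()
  tb <- transition_basis(st)
  K <- build_coupling(tb, st$gamma)
  expect_error(solve_casida(tb, K, n_states = length(tb$de) + 1L), "exceeds")
})

test_that("oscillator strengths are non-negative and reduce to the single-pair value", {
  ex <- tddftb_excitations(gas_water_state())
  expect_true(all(ex$f >= 0))
  # independent-particle limit on a 1-pair basis
  tabs <- hopping_tables(onsite = -0.5, hopping = -0.2, d = 2.0)
  g <- geometry(c("X", "X"), rbind(c(0, 0, 0), c(2, 0, 0)))
  st <- scf(g, tabs)
  tb <- transition_basis(st)
  ex1 <- oscillator_strengths(
    solve_casida(tb, K = matrix(0, 1, 1), n_states = 1L))
  expect_equal(ex1$f, tb$f_single, tolerance = 1e-12)
})

test_that("parity-forbidden states of a centrosymmetric chain are dark", {
  # linear, equally spaced, centered homonuclear chain: g/u alternation makes
  # half of the single-orbital transitions dipole-forbidden
  tabs <- hopping_tables(onsite = -0.4, hopping = -0.15, d = 2.0)
  g <- geometry(rep("X", 4),
                cbind(c(-3, -1, 1, 3), 0, 0))
  st <- scf(g, tabs)
  ex <- tddftb_excitations(st, n_states = 4L)
  expect_lt(min(ex$f), 1e-10)   # at least one forbidden state
  expect_gt(max(ex$f), 1e-4)    # and at least one allowed one
})

test_that("excitation energies are rigid-motion invariant", {
  cl <- make_water_cluster(2L, seed = 23L)
  st1 <- scf(cl$geom, toy_tables(), cl$part, toy_fq_water_params())
  ex1 <- tddftb_excitations(st1)
  g2 <- cl$geom
  g2$coords <- g2$coords %*% t(random_rotation_matrix())
  g2$coords <- sweep(g2$coords, 2L, c(3, 4, -5), `+`)
  st2 <- scf(g2, toy_tables(), cl$part, toy_fq_water_params())
  ex2 <- tddftb_excitations(st2)
  expect_lt(max(abs(ex1$omega - ex2$omega)), 1e-9)
  expect_equal(ex1$f, ex2$f, tolerance = 1e-6)
})

test_that("removing the FQ layer removes its coupling exactly", {
  cl <- make_water_cluster(3L, seed = 29L)
  st <- scf(cl$geom, toy_tables(), cl$part, toy_fq_water_params())
  g_solute <- geometry(cl$geom$elements[1:3], cl$geom$coords[1:3, ])
  st_gas <- scf(g_solute, toy_tables())
  tb <- transition_basis(st)
  K <- build_coupling(tb, st$gamma)
  Kfq <- build_kfq(tb, st$fqm, st$G)
  ex_nofq_coupling <- solve_casida(tb, K, Kfq = NULL,
                                   n_states = length(tb$de))
  # the gas-phase run on the same geometry differs only through the SCF
  # ground state; with the FQ layer far away both routes must coincide
  mm <- mm_atoms(cl$part)
  gfar <- cl$geom
  gfar$coords[mm, ] <- sweep(gfar$coords[mm, , drop = FALSE], 2L,
                             c(5e3, 0, 0), `+`)
  st_far <- scf(gfar, toy_tables(), cl$part, toy_fq_water_params())
  ex_far <- tddftb_excitations(st_far)
  ex_gas <- tddftb_excitations(st_gas)
  expect_lt(max(abs(ex_far$omega_ev - ex_gas$omega_ev)), 1e-8)
})

test_that("an FQ layer with diagonal-dominant coupling never blue-shifts the lowest root", {
  # 1-pair basis: omega^2 = de^2 + 4 de (K + Kfq); Kfq <= 0 lowers it
  tb <- structure(list(de = 0.25, tq = matrix(1, 1, 1),
                       dip = matrix(0, 1, 3), f_single = 0,
                       R = matrix(0, 1, 3)),
                  class = "transition_basis")
  K <- matrix(0.04, 1, 1)
  w_bare <- solve_casida(tb, K, n_states = 1L)$omega
  Kfq <- matrix(-0.01, 1, 1)
  w_fq <- solve_casida(tb, K, Kfq, n_states = 1L)$omega
  expect_lt(w_fq, w_bare)
})

test_that("intensity selection is monotone and the no-filter limit is exact", {
  # >= 20-pair fixture: two all-QM waters
  cl1 <- make_water_cluster(0L, seed = 41L)
  g2 <- geometry(c(cl1$geom$elements, cl1$geom$elements),
                 rbind(cl1$geom$coords,
                       sweep(cl1$geom$coords, 2L, c(6, 0.3, 0.2), `+`)))
  st <- scf(g2, toy_tables())
  tb <- transition_basis(st)
  expect_gte(length(tb$de), 20L)
  expect_identical(intensity_select(tb, 0), tb)   # bitwise no-filter limit
  expect_error(intensity_select(tb, max(tb$f_single) * 1.01), "lower the threshold")
  fm <- max(tb$f_single)
  f_min_pos <- min(tb$f_single[tb$f_single > 0])
  thresholds <- c(fm * 0.5, fm * 0.05, fm * 1e-3, fm * 1e-8, f_min_pos / 2, 0)
  sizes <- integer(0); lowest <- numeric(0)
  for (th in thresholds) {
    tbs <- intensity_select(tb, th)
    sizes <- c(sizes, length(tbs$de))
    K <- build_coupling(tbs, st$gamma)
    lowest <- c(lowest, solve_casida(tbs, K, n_states = 1L)$omega)
  }
  expect_true(all(diff(sizes) >= 0))          # basis grows as threshold drops
  expect_true(all(diff(lowest) <= 1e-14))     # variational: omega non-increasing
  expect_equal(lowest[length(lowest)], lowest[length(lowest) - 1L],
               tolerance = 1e-9)              # converged to the unfiltered value
})
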