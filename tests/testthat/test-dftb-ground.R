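test_that("two s-shell atoms pick the tabulated ss sigma value at grid distances", {
  tabs <- toy_tables()
  hh <- skf_pair(tabs, "H", "H")
  d <- 20L * hh$grid_step
  g <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(d, 0, 0)))
  b <- basis_map(g, tabs)
  hs <- build_h0_s(g, tabs, b)
  expect_equal(hs$H0[1, 2], unname(hh$H[20L, "ss_sigma"]), tolerance = 1e-14)
  expect_equal(hs$S[1, 2], unname(hh$S[20L, "ss_sigma"]), tolerance = 1e-14)
  expect_identical(hs$H0, t(hs$H0))
  expect_identical(hs$S, t(hs$S))
})

test_that("a single atom gives on-site energies and identity overlap", {
  tabs <- toy_tables()
  g <- geometry("O", matrix(c(1, 2, 3), 1))
  b <- basis_map(g, tabs)
  hs <- build_h0_s(g, tabs, b)
  on <- toy_elements()$O$onsite
  expect_equal(diag(hs$H0), c(on[["s"]], rep(on[["p"]], 3)))
  expect_equal(hs$S, diag(4))
  expect_true(all(hs$H0[upper.tri(hs$H0)] == 0))
})

test_that("s-p blocks transform as vectors under rotation of the geometry", {
  tabs <- toy_tables()
  cl <- make_water_cluster(0L, seed = 3L)
  b <- basis_map(cl$geom, tabs)
  hs <- build_h0_s(cl$geom, tabs, b)
  for (R in list(matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3),  # 90 deg about z
                 random_rotation_matrix())) {
    g2 <- cl$geom
    g2$coords <- g2$coords %*% t(R)
    hs2 <- build_h0_s(g2, tabs, b)
    # block-diagonal orbital transformation: scalar for s, R for (px,py,pz)
    Tm <- diag(b$n_orb)
    for (k in seq_along(b$atoms)) {
      rg <- b$ranges[[k]]
      if (length(rg) == 4L) Tm[rg[2:4], rg[2:4]] <- R
    }
    expect_lt(max(abs(hs2$H0 - Tm %*% hs$H0 %*% t(Tm))), 1e-10)
    expect_lt(max(abs(hs2$S - Tm %*% hs$S %*% t(Tm))), 1e-10)
  }
})

test_that("missing pair tables are reported by name", {
  tabs <- skf_set(toy_tables()$tables["H-H"])
  g <- geometry(c("H", "O"), rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_error(basis_map(g, tabs), "O-O")
})

test_that("gamma kernel hits the Hubbard contact limit and Coulomb far field", {
  expect_equal(gamma_pair(0.4, 0.4, 0), 0.4)
  expect_lt(abs(gamma_pair(0.4, 0.4, 60) - 1 / 60) / (1 / 60), 0.005)
  # unequal-U branch: still 1/R at long range
  expect_lt(abs(gamma_pair(0.42, 0.50, 60) - 1 / 60) / (1 / 60), 0.005)
  # monotone decreasing in R for fixed U
  rs <- seq(0, 30, by = 0.05)
  v <- gamma_pair(0.5, 0.5, rs)
  expect_true(all(diff(v) < 0))
  v2 <- gamma_pair(0.42, 0.5, rs)
  expect_true(all(diff(v2) < 0))
})

test_that("Mulliken analysis reduces to net populations for identity overlap", {
  tabs <- hopping_tables()   # zero-overlap table
  g <- geometry(c("X", "X"), rbind(c(0, 0, 0), c(2, 0, 0)))
  b <- basis_map(g, tabs)
  P <- matrix(c(1.2, 0.3, 0.3, 0.8), 2)
  dq <- mulliken(P, diag(2), b)
  expect_equal(dq, c(1.2, 0.8) - b$n0)
})

test_that("converged Mulliken fluctuations conserve total charge and symmetry", {
  st <- gas_water_state()
  expect_lt(abs(sum(st$dq)), 1e-8)
  # the two hydrogens of the symmetric water frame carry identical dq
  expect_equal(st$dq[2], st$dq[3], tolerance = 1e-8)
  # electron-count contract: Tr(P S) = valence electron count
  expect_equal(sum(st$P * st$S), sum(st$basis$n0), tolerance = 1e-8)
})

test_that("the Hamiltonian reduces to H0 at zero fluctuations and shifts with -cS", {
  tabs <- toy_tables()
  cl <- make_water_cluster(0L, seed = 3L)
  b <- basis_map(cl$geom, tabs)
  hs <- build_h0_s(cl$geom, tabs, b)
  gam <- gamma_matrix(cl$geom, tabs, b)
  n_at <- length(b$atoms)
  H <- build_hamiltonian(hs$H0, hs$S, gam, numeric(n_at), numeric(n_at), b)
  expect_identical(H, hs$H0)
  # a uniform embedding potential c acts as a gauge shift -c S on the electrons
  cshift <- 0.37
  Hc <- build_hamiltonian(hs$H0, hs$S, gam, numeric(n_at),
                          rep(cshift, n_at), b)
  expect_equal(Hc, hs$H0 - cshift * hs$S, tolerance = 1e-14)
})

test_that("toy homonuclear diatomic reproduces the closed-form orbital energies", {
  tabs <- hopping_tables(onsite = -0.5, hopping = -0.2, d = 2.0)
  g <- geometry(c("X", "X"), rbind(c(0, 0, 0), c(2, 0, 0)))
  st <- scf(g, tabs)
  expect_equal(st$mo_energies, c(-0.7, -0.3), tolerance = 1e-10)
  expect_equal(st$n_occ, 1L)
})

test_that("odd valence electron counts are rejected", {
  tabs <- toy_tables()
  g <- geometry(c("O", "H"), rbind(c(0, 0, 0), c(1.8, 0, 0)))
  expect_error(scf(g, tabs), "closed shell")
})

test_that("non-convergence raises an error carrying the iteration history", {
  cl <- make_water_cluster(0L, seed = 3L)
  err <- tryCatch(scf(cl$geom, toy_tables(),
                      settings = list(max_iter = 2L, mixing = 0.05)),
                  error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "converge")
  expect_s3_class(err$history, "data.frame")
  expect_equal(nrow(err$history), 2L)
})

test_that("an empty MM region reproduces the pure gas-phase path exactly", {
  cl <- make_water_cluster(0L, seed = 11L)
  st_plain <- gas_water_state()
  st_part <- scf(cl$geom, toy_tables(), part = cl$part,
                 fq_params = toy_fq_water_params())
  expect_lt(abs(st_plain$energies[["total"]] - st_part$energies[["total"]]),
            1e-12)
  expect_equal(st_part$energies[["fq"]], 0)
  expect_equal(st_part$energies[["coupling"]], 0)
})

test_that("energy components are bookkept exactly and vanish appropriately", {
  st <- solvated_state()
  e <- total_energy(st)
  expect_equal(sum(e[c("band", "gamma2", "repulsive", "fq", "coupling")]),
               e[["total"]], tolerance = 1e-12)
  gas <- total_energy(gas_water_state())
  expect_identical(gas[["fq"]], 0)
  expect_identical(gas[["coupling"]], 0)
})

test_that("total energy is invariant under rigid translation of the full system", {
  cl <- make_water_cluster(2L, seed = 17L)
  st1 <- scf(cl$geom, toy_tables(), cl$part, toy_fq_water_params())
  g2 <- cl$geom
  g2$coords <- sweep(g2$coords, 2L, c(12.3, -4.5, 6.7), `+`)
  st2 <- scf(g2, toy_tables(), cl$part, toy_fq_water_params())
  expect_lt(abs(st1$energies[["total"]] - st2$energies[["total"]]), 1e-10)
})

test_that("repulsive energy is pair-symmetric and zero beyond all cutoffs", {
  tabs <- toy_tables()
  cl <- make_water_cluster(0L, seed = 3L)
  e1 <- repulsive_energy(cl$geom, tabs)
  g2 <- geometry(cl$geom$elements[c(2, 3, 1)], cl$geom$coords[c(2, 3, 1), ])
  expect_equal(repulsive_energy(g2, tabs), e1, tolerance = 1e-14)
  far <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_identical(repulsive_energy(far, tabs), 0)
})

test_that("the Hamiltonian is the derivative of the coupled energy functional", {
  # variational consistency including the Mulliken and FQ chains
  cl <- make_water_cluster(2L, seed = 19L)
  # QM region: the solute water; H2-like diatomic variant also covered in the
  # acceptance suite
  st <- scf(cl$geom, toy_tables(), cl$part, toy_fq_water_params())
  v_emb <- st$v_emb
  H <- build_hamiltonian(st$H0, st$S, st$gamma, st$dq, v_emb, st$basis)
  P <- st$P
  h <- 1e-5
  idx <- rbind(c(1, 1), c(1, 3), c(2, 5), c(4, 4), c(3, 6))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    Pp <- P; Pm <- P
    if (i == j) {
      Pp[i, j] <- Pp[i, j] + h; Pm[i, j] <- Pm[i, j] - h
      d <- (energy_of_density(st, Pp) - energy_of_density(st, Pm)) / (2 * h)
    } else {
      Pp[i, j] <- Pp[i, j] + h; Pp[j, i] <- Pp[j, i] + h
      Pm[i, j] <- Pm[i, j] - h; Pm[j, i] <- Pm[j, i] - h
      d <- (energy_of_density(st, Pp) - energy_of_density(st, Pm)) / (4 * h)
    }
    expect_equal(d, H[i, j], tolerance = 1e-6)
  }
})

test_that("SCF is self-consistent both ways at convergence", {
  st <- solvated_state()
  tol <- st$settings$tol_dq
  # re-solving FQ at the converged dq moves no charge
  V <- potential_at_fq_sites(st$dq, st$G)
  sol <- solve_fq(st$fqm, V = V)
  expect_lt(max(abs(sol$q - st$fq$q)), tol * 10)
  # rebuilding H at the converged FQ charges moves no MO energy
  v_emb <- embedding_potential(st$fq$q, st$G)
  H <- build_hamiltonian(st$H0, st$S, st$gamma, st$dq, v_emb, st$basis)
  ro <- dftbfq:::solve_roothaan(H, st$S)
  expect_lt(max(abs(ro$energies - st$mo_energies)), tol * 10)
})
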