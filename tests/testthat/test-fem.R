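# assembly, eigensolver, scaling laws, MAC tracking, strain energy

# independent dense T4 element oracle: engineering B-matrix formulation,
# K = V B' D B with the Voigt 6x6 isotropic D; consistent mass by the
# closed-form rho V / 20 * (1 + delta_ab) corner pattern.
t4_oracle <- function(corners, E, nu, rho) {
  A <- rbind(1, t(corners))
  Ainv <- solve(A)
  V <- abs(det(A)) / 6
  g <- Ainv[, 2:4]                       # dN_a/dx_r for N_a = lambda_a
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- g[a, 1]
    B[2, c0 + 2] <- g[a, 2]
    B[3, c0 + 3] <- g[a, 3]
    B[4, c0 + 1] <- g[a, 2]; B[4, c0 + 2] <- g[a, 1]
    B[5, c0 + 2] <- g[a, 3]; B[5, c0 + 3] <- g[a, 2]
    B[6, c0 + 1] <- g[a, 3]; B[6, c0 + 3] <- g[a, 1]
  }
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(lam + 2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3][lower.tri(matrix(0, 3, 3))] <- lam
  D[1:3, 1:3][upper.tri(matrix(0, 3, 3))] <- lam
  K <- V * t(B) %*% D %*% B
  M <- matrix(0, 12, 12)
  for (a in 1:4) for (b in 1:4)
    for (p in 1:3)
      M[3 * (a - 1) + p, 3 * (b - 1) + p] <-
        rho * V / 20 * (1 + (a == b))
  list(K = K, M = M)
}

test_that("single-T4 stiffness and mass match the independent dense oracle", {
  m <- fx_single_tet()
  E <- 3.7e9; nu <- 0.27; rho <- 1840
  sys <- assemble_system(m, list(stiff_bone = material_card(rho, E, nu)))
  orc <- t4_oracle(m$nodes, E, nu, rho)
  expect_lt(max(abs(as.matrix(sys$K) - orc$K)) / max(abs(orc$K)), 1e-10)
  expect_lt(max(abs(as.matrix(sys$M) - orc$M)) / max(abs(orc$M)), 1e-10)
})

test_that("unconstrained stiffness annihilates rigid translations", {
  for (mesh in list(fx_single_tet(), promote_to_t10(fx_single_tet()))) {
    sys <- assemble_system(mesh, fx_unit_material())
    K <- as.matrix(sys$K)
    n <- nrow(mesh$nodes)
    for (ax in 1:3) {
      u <- rep(0, 3 * n); u[seq(ax, 3 * n, 3)] <- 1
      expect_lt(max(abs(K %*% u)), 1e-9 * max(abs(K)))
    }
  }
})

test_that("consistent mass sums to rho V along each axis", {
  toy <- fx_toy_t4()
  mats <- tpc_reference_materials()
  sys <- assemble_system(toy$mesh, mats, integer(0))
  M <- sys$M
  rhoV <- sum(vapply(seq_len(nrow(toy$mesh$elements)), function(e)
    mats[[toy$mesh$region[e]]]$density, numeric(1)) *
      element_volumes(toy$mesh))
  n <- nrow(toy$mesh$nodes)
  for (ax in 1:3) {
    u <- rep(0, 3 * n); u[seq(ax, 3 * n, 3)] <- 1
    expect_rel(as.numeric(t(u) %*% M %*% u), rhoV, 1e-9)
  }
})

test_that("free-free solve shows exactly six rigid modes", {
  beam <- make_beam_mesh(0.3, 0.06, 0.04, divisions = c(6, 2, 2), order = 10)
  sys <- assemble_system(beam, fx_unit_material(), integer(0))
  sol <- solve_modes(sys, k = 8, free_free = TRUE)
  ratios <- sol$omega2 / max(sol$omega2)
  expect_true(all(ratios[1:6] < 1e-8))
  expect_true(all(ratios[7:8] > 1e-4))
})

test_that("cantilever frequencies match the Euler-Bernoulli closed form", {
  bs <- fx_beam_solve()
  E <- 25e9; rho <- 2400; W <- 0.05; L <- 1
  I <- W^4 / 12; A <- W^2
  f_eb <- function(bl) bl^2 / (2 * pi * L^2) * sqrt(E * I / (rho * A))
  f <- bs$sol$frequencies_hz
  # square section: bending modes come in near-degenerate pairs (y, z)
  expect_lt(abs(f[1] / f_eb(1.8751) - 1), 0.03)
  expect_lt(abs(f[2] / f_eb(1.8751) - 1), 0.03)
  expect_lt(abs(f[3] / f_eb(4.6941) - 1), 0.03)
  expect_lt(abs(f[4] / f_eb(4.6941) - 1), 0.03)
})

test_that("solve is deterministic and meets its quality invariants", {
  bs <- fx_beam_solve()
  again <- solve_modes(bs$sys, k = 8)
  expect_identical(bs$sol$frequencies_hz, again$frequencies_hz)
  expect_identical(bs$sol$shapes, again$shapes)
  expect_lt(bs$sol$ortho_error, 1e-8)
  expect_lt(max(bs$sol$residuals), 1e-6)
  expect_true(all(diff(bs$sol$frequencies_hz) >= 0))
  expect_error(solve_modes(bs$sys, k = 0), "k must satisfy")
})

test_that("uniform scaling divides every frequency by the factor", {
  bs <- fx_beam_solve()
  beam <- fx_beam()
  scaled <- scale_mesh(beam, 1.2)
  base_s <- which(abs(scaled$nodes[, 1]) < 1e-12)
  sys_s <- assemble_system(scaled, bs$mats, base_s)
  sol_s <- solve_modes(sys_s, k = 8)
  expect_rel(sol_s$frequencies_hz, bs$sol$frequencies_hz / 1.2, 1e-9)
  # mode shapes unchanged: MAC >= 0.999 mode by mode
  mac <- mac_matrix(bs$sol$shapes[bs$sol$free_dofs, ],
                    sol_s$shapes[sol_s$free_dofs, ])
  expect_true(all(diag(mac) >= 0.999))
})

test_that("stiffness and density scalings move frequencies as sqrt laws", {
  beam <- make_beam_mesh(0.5, 0.05, 0.05, divisions = c(10, 1, 1), order = 10)
  base <- beam$base_nodes
  mats0 <- list(stiff_bone = material_card(2000, 10e9, 0.3))
  f0 <- solve_modes(assemble_system(beam, mats0, base), k = 5)$frequencies_hz
  for (c_ in c(2.5, 0.4)) {
    fE <- solve_modes(assemble_system(
      beam, list(stiff_bone = material_card(2000, c_ * 10e9, 0.3)), base),
      k = 5)$frequencies_hz
    expect_rel(fE, sqrt(c_) * f0, 1e-9)
    fR <- solve_modes(assemble_system(
      beam, list(stiff_bone = material_card(2000 * c_, 10e9, 0.3)), base),
      k = 5)$frequencies_hz
    expect_rel(fR, f0 / sqrt(c_), 1e-9)
  }
})

test_that("normal displacement: closed forms and brute-force oracle", {
  cube <- make_beam_mesh(1, 1, 1, divisions = c(2, 2, 2), order = 4)
  surf <- surface_extract(cube)
  n <- nrow(cube$nodes)
  sys <- assemble_system(cube, fx_unit_material(), integer(0))
  fake <- structure(list(
    frequencies_hz = 1, omega2 = 1,
    shapes = matrix(rep(c(1, 0, 0), n), ncol = 1),
    residuals = 0, ortho_error = 0,
    free_dofs = seq_len(3 * n), n_nodes = n,
    provenance = list(mesh_hash = cube$hash)), class = "modal_solution")
  nd <- normal_displacement(fake, surf)
  on_x <- abs(abs(surf$vertex_normals[, 1]) - 1) < 1e-12
  expect_true(all(abs(nd[on_x, 1] - 1) < 1e-12))
  on_yz <- abs(surf$vertex_normals[, 1]) < 1e-12
  expect_true(all(nd[on_yz, 1] < 1e-12))

  # toy mode vs brute-force per-vertex dot products
  ts <- fx_toy_ablated()
  sol <- ts$sol; surf2 <- ts$surface
  nd2 <- normal_displacement(sol, surf2)
  k <- 3
  brute <- vapply(seq_along(surf2$to_volume), function(v) {
    nid <- surf2$to_volume[v]
    u <- sol$shapes[(3 * nid - 2):(3 * nid), k]
    abs(sum(u * surf2$vertex_normals[v, ]))
  }, numeric(1))
  expect_lt(max(abs(nd2[, k] - brute)), 1e-12)

  # hash mismatch is an error
  expect_error(normal_displacement(fake, surf2), "hash")
})

test_that("MAC self-match is the identity", {
  bs <- fx_beam_solve()
  tr <- track_modes(bs$sol, bs$sol, mass = bs$sys$M)
  expect_equal(tr$pairs$mode_a, tr$pairs$mode_b)
  expect_true(all(abs(tr$pairs$mac - 1) < 1e-10))
})

test_that("mode tracking follows shapes through a 2-dof eigenvalue crossing", {
  # two weakly coupled oscillators, closed form by direct 2x2 eigen
  two_dof <- function(k1, k2, kc) {
    K <- matrix(c(k1 + kc, -kc, -kc, k2 + kc), 2)
    e <- eigen(K, symmetric = TRUE)
    ord <- order(e$values)
    structure(list(
      frequencies_hz = sqrt(e$values[ord]) / (2 * pi),
      omega2 = e$values[ord], shapes = e$vectors[, ord],
      residuals = c(0, 0), ortho_error = 0,
      free_dofs = 1:2, n_nodes = NA, provenance = list()),
      class = "modal_solution")
  }
  lo <- two_dof(1, 0.5, 0.01)   # mode 1 localized on dof 2
  hi <- two_dof(1, 2.0, 0.01)   # after the crossing: mode 1 on dof 1
  tr <- track_modes(lo, hi, dofs = 1:2, threshold = 0.7)
  swap <- tr$pairs[order(tr$pairs$mode_a), ]
  expect_equal(swap$mode_b, c(2L, 1L))
  expect_true(all(swap$mac >= 0.9))
})

test_that("strain energy fractions sum to one and find appendage modes", {
  ts <- fx_toy_solve()
  en <- strain_energy_fractions(ts$toy$mesh, ts$mats, ts$sol)
  expect_true(all(abs(colSums(en) - 1) < 1e-9))
  app <- colSums(en[c("incus", "stapes", "ligament_malleoincudal",
                      "ligament_incudostapedial", "ligament_annular"), ])
  # the toy has both whole-structure and chain-localized modes
  expect_true(any(app > 0.9))
  expect_true(any(app < 0.1))
})

test_that("sweep of one combination equals a direct solve", {
  beam <- make_beam_mesh(0.5, 0.05, 0.05, divisions = c(8, 1, 1), order = 4)
  cards <- list(stiff_bone = list(material_card(2000, 10e9, 0.3)))
  sw <- sweep_materials(beam, cards, beam$base_nodes, k = 4)
  expect_length(sw, 1L)
  direct <- solve_modes(
    assemble_system(beam, list(stiff_bone = cards$stiff_bone[[1]]),
                    beam$base_nodes), k = 4)
  expect_equal(sw[[1]]$frequencies_hz, direct$frequencies_hz)
})

test_that("missing material card and bad fixed sets are rejected", {
  toy <- fx_toy_t4()
  expect_error(assemble_system(toy$mesh, fx_unit_material(), toy$base_nodes),
               "missing material card")
  expect_error(assemble_system(toy$mesh, tpc_reference_materials(),
                               fixed = 10^7), "out of range")
})

test_that("modal solutions round-trip through HDF5", {
  bs <- fx_beam_solve()
  path <- tempfile(fileext = ".h5")
  sol <- bs$sol
  sol$provenance$scale <- 1.2
  write_modal_h5(sol, path)
  back <- read_modal_h5(path)
  expect_equal(back$frequencies_hz, sol$frequencies_hz)
  expect_equal(back$shapes, sol$shapes, ignore_attr = TRUE)
  expect_equal(back$provenance$mesh_hash, sol$provenance$mesh_hash)
  expect_equal(back$provenance$scale, 1.2)
  unlink(path)
  # frequencies CSV
  csv <- tempfile(fileext = ".csv")
  write_frequencies_csv(sol, csv)
  tab <- utils::read.csv(csv)
  expect_equal(tab$frequency_hz, sol$frequencies_hz)
  expect_equal(unique(tab$scale), 1.2)
  unlink(csv)
})
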