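## Linear-elasticity modal FEM ----------------------------------------------
##
## Small-strain isotropic elasticity on labeled tet meshes. Element matrices
## are integrated exactly using the barycentric monomial formula
##   int_T lambda^alpha dV = 6V * a1! a2! a3! a4! / (|alpha| + 3)!
## which is valid for straight-sided (affine) T4 and T10 elements; no
## quadrature tables are needed and the consistent mass matrix is exact.
## The generalized symmetric eigenproblem K phi = omega^2 M phi is reduced to
## standard form with a sparse Cholesky factor of M and solved by
## shift-invert Lanczos (RSpectra) through a CHOLMOD factorization of K.

# polynomial-in-barycentric representation: list of (coef, alpha[4]) terms
.shape_polys <- function(npe) {
  e <- diag(4)
  if (npe == 4L) {
    N <- lapply(1:4, function(a) list(list(c = 1, a = e[a, ])))
    dN <- lapply(1:4, function(a) lapply(1:4, function(i)
      if (i == a) list(list(c = 1, a = c(0, 0, 0, 0))) else list()))
  } else {
    N <- vector("list", 10L)
    dN <- lapply(1:10, function(a) lapply(1:4, function(i) list()))
    for (a in 1:4) {
      N[[a]] <- list(list(c = 2, a = 2 * e[a, ]), list(c = -1, a = e[a, ]))
      dN[[a]][[a]] <- list(list(c = 4, a = e[a, ]), list(c = -1, a = c(0, 0, 0, 0)))
    }
    for (k in 1:6) {
      i <- TET10_EDGES[k, 1]; j <- TET10_EDGES[k, 2]
      N[[4 + k]] <- list(list(c = 4, a = e[i, ] + e[j, ]))
      dN[[4 + k]][[i]] <- list(list(c = 4, a = e[j, ]))
      dN[[4 + k]][[j]] <- list(list(c = 4, a = e[i, ]))
    }
  }
  list(N = N, dN = dN)
}

# exact integral of lambda^alpha over the reference measure: physical
# integral = 6V * .bary_int(alpha)
.bary_int <- function(alpha)
  prod(factorial(alpha)) / factorial(sum(alpha) + 3)

.poly_pair_int <- function(p, q) {
  s <- 0
  for (t in p) for (u in q) s <- s + t$c * u$c * .bary_int(t$a + u$a)
  s
}

# reference tensors, computed once per element order and cached:
#   Mref[a,b]      = int N_a N_b            (in 6V units)
#   Gref[(a,b), (i,j)] = int dN_a/dl_i dN_b/dl_j  (in 6V units), flattened
#   with ab = a + npe*(b-1) rows and ij = i + 4*(j-1) columns
.ref_cache <- new.env(parent = emptyenv())
reference_tensors <- function(npe) {
  key <- as.character(npe)
  if (!is.null(.ref_cache[[key]])) return(.ref_cache[[key]])
  sp <- .shape_polys(npe)
  Mref <- matrix(0, npe, npe)
  for (a in 1:npe) for (b in 1:npe)
    Mref[a, b] <- .poly_pair_int(sp$N[[a]], sp$N[[b]])
  Gref <- matrix(0, npe * npe, 16L)
  for (a in 1:npe) for (b in 1:npe) for (i in 1:4) for (j in 1:4) {
    p <- sp$dN[[a]][[i]]; q <- sp$dN[[b]][[j]]
    if (length(p) && length(q))
      Gref[a + npe * (b - 1L), i + 4L * (j - 1L)] <- .poly_pair_int(p, q)
  }
  out <- list(Mref = Mref, Gref = Gref)
  .ref_cache[[key]] <- out
  out
}

# per-element geometry: inverse affine map and volume
.element_geometry <- function(corners) {
  A <- rbind(1, t(corners))              # 4x4: lambda = A^{-1} [1; x]
  Ainv <- solve(A)
  g <- Ainv[, 2:4, drop = FALSE]         # dlambda_i / dx_r
  V <- abs(det(A)) / 6
  list(g = g, V = V)
}

# stiffness and mass of one element (dof order: x,y,z of node 1, then node 2, ...)
element_matrices <- function(corners, npe, lam, mu, rho, ref) {
  geo <- .element_geometry(corners)
  g <- geo$g; sixV <- 6 * geo$V
  # W: 16 x 9 with column (r,s) = vec(g[,r] outer g[,s])
  W <- matrix(0, 16L, 9L)
  for (s in 1:3) for (r in 1:3)
    W[, r + 3L * (s - 1L)] <- as.vector(outer(g[, r], g[, s]))
  H <- sixV * (ref$Gref %*% W)                   # (npe^2) x 9
  Harr <- array(H, c(npe, npe, 3L, 3L))          # [a,b,r,s]
  trH <- Harr[, , 1, 1] + Harr[, , 2, 2] + Harr[, , 3, 3]
  K1 <- aperm(Harr, c(3L, 1L, 4L, 2L))           # [p,a,q,b] = H[a,b,p,q]
  K2 <- aperm(Harr, c(4L, 1L, 3L, 2L))           # [p,a,q,b] = H[a,b,q,p]
  Ktr <- array(0, c(3L, npe, 3L, npe))
  for (p in 1:3) Ktr[p, , p, ] <- trH
  Ke <- matrix(lam * K1 + mu * (Ktr + K2), 3L * npe, 3L * npe)
  Marr <- array(0, c(3L, npe, 3L, npe))
  Mab <- rho * sixV * ref$Mref
  for (p in 1:3) Marr[p, , p, ] <- Mab
  list(K = Ke, M = matrix(Marr, 3L * npe, 3L * npe), V = geo$V)
}

#' Assemble stiffness and mass matrices over the free DOFs
#'
#' Standard small-strain isotropic linear elasticity with a consistent mass
#' matrix. Fixed-base constraints are imposed by DOF elimination, which
#' preserves symmetry and definiteness.
#'
#' @param mesh a [tet_mesh()].
#' @param materials named list: region -> [material_card()].
#' @param fixed integer vector of fixed node ids (all three DOFs of each are
#'   constrained). May be empty for a free-free diagnostic model.
#' @return an object of class `fem_system`: sparse `K` (N/m) and `M` (kg)
#'   over free DOFs, `free_dofs` (global dof ids, dof = 3*(node-1)+axis),
#'   `n_nodes`, `fixed_nodes`, `mesh_hash`.
#' @export
assemble_system <- function(mesh, materials, fixed = integer(0)) {
  check_materials(mesh, materials)
  npe <- mesh$order
  ref <- reference_tensors(npe)
  ne <- nrow(mesh$elements)
  block <- (3L * npe)^2
  ii <- integer(ne * block); jj <- integer(ne * block)
  kx <- numeric(ne * block); mx <- numeric(ne * block)
  lam <- vapply(mesh$region, function(r) lame_lambda(materials[[r]]), numeric(1))
  mu <- vapply(mesh$region, function(r) lame_mu(materials[[r]]), numeric(1))
  rho <- vapply(mesh$region, function(r) materials[[r]]$density, numeric(1))
  for (e in seq_len(ne)) {
    nd <- mesh$elements[e, ]
    corners <- mesh$nodes[nd[1:4], , drop = FALSE]
    em <- element_matrices(corners, npe, lam[e], mu[e], rho[e], ref)
    dofs <- as.vector(rbind(3L * nd - 2L, 3L * nd - 1L, 3L * nd))
    idx <- seq_len(block) + (e - 1L) * block
    ii[idx] <- rep(dofs, times = 3L * npe)
    jj[idx] <- rep(dofs, each = 3L * npe)
    kx[idx] <- as.vector(em$K)
    mx[idx] <- as.vector(em$M)
  }
  ndof <- 3L * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = kx, dims = c(ndof, ndof))
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = mx, dims = c(ndof, ndof))
  K <- (K + Matrix::t(K)) / 2
  M <- (M + Matrix::t(M)) / 2
  fixed <- sort(unique(as.integer(fixed)))
  if (length(fixed) && (any(fixed < 1L) || any(fixed > nrow(mesh$nodes))))
    stop2("fixed node id out of range")
  fixed_dofs <- if (length(fixed))
    as.vector(rbind(3L * fixed - 2L, 3L * fixed - 1L, 3L * fixed)) else integer(0)
  free <- setdiff(seq_len(ndof), fixed_dofs)
  structure(
    list(K = K[free, free, drop = FALSE], M = M[free, free, drop = FALSE],
         free_dofs = free, n_nodes = nrow(mesh$nodes), fixed_nodes = fixed,
         mesh_hash = mesh$hash),
    class = "fem_system")
}

#' Solve for the lowest natural modes
#'
#' Smallest `k` eigenpairs of K phi = omega^2 M phi by shift-invert Lanczos:
#' M = Lt Lt' (sparse Cholesky), C = Lt^-1 K Lt^-T, and the largest
#' eigenvalues of C^-1 (through a CHOLMOD factorization of K, or K + sigma M
#' in free-free mode) are computed with a fixed deterministic start vector,
#' so repeated runs are bit-stable.
#'
#' @param system a [assemble_system()] result.
#' @param k number of modes (default 20).
#' @param free_free allow rigid-body modes (uses a small positive spectral
#'   shift so the singular K can be factorized).
#' @param tol Lanczos tolerance (default 1e-10).
#' @param provenance optional named list stored in the solution (mesh hash is
#'   added automatically).
#' @return an object of class `modal_solution`: `frequencies_hz` (ascending),
#'   `shapes` (full 3*N x k, zeros at fixed DOFs, mass-normalized),
#'   `omega2`, `residuals` (per-mode relative eigen-residuals),
#'   `ortho_error` (max |Phi' M Phi - I|), `free_dofs`, `provenance`.
#' @export
solve_modes <- function(system, k = 20L, free_free = FALSE, tol = 1e-10,
                        provenance = list()) {
  K <- system$K; M <- system$M
  n <- nrow(K)
  if (k < 1L || k >= n) stop2("k must satisfy 1 <= k < %d free dofs", n)
  chM <- Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE, perm = TRUE)
  ex <- Matrix::expand2(chM)
  Lt <- ex$P1. %*% ex$L1 %*% Matrix::Diagonal(n, sqrt(Matrix::diag(ex$D)))
  sigma <- 0
  Kshift <- K
  if (free_free) {
    sigma <- 1e-6 * sum(Matrix::diag(K)) / sum(Matrix::diag(M))
    Kshift <- K + sigma * M
  }
  chK <- tryCatch(
    Matrix::Cholesky(Matrix::forceSymmetric(Kshift), LDL = FALSE, perm = TRUE),
    error = function(e) stop2(paste0(
      "stiffness factorization failed (%s); ",
      "is the fixed-base constraint rank-sufficient?"), conditionMessage(e)))
  op <- function(x, args) {
    y <- args$Lt %*% x
    z <- Matrix::solve(args$chK, y, system = "A")
    as.numeric(Matrix::t(args$Lt) %*% z)
  }
  v0 <- sin(seq_len(n) * 0.7292) + 1.1     # fixed, deterministic start vector
  res <- RSpectra::eigs_sym(op, k = k, which = "LM", n = n,
                            args = list(Lt = Lt, chK = chK),
                            opts = list(tol = tol, maxitr = 5000,
                                        initvec = v0))
  if (length(res$values) < k)
    stop2("eigensolver converged only %d of %d modes", length(res$values), k)
  lambda <- 1 / res$values - sigma          # ascending after reversal below
  ord <- order(lambda)
  lambda <- lambda[ord]
  Y <- res$vectors[, ord, drop = FALSE]
  # back-transform: phi = Lt^-T y  (triangular solve through the permutation)
  Phi <- as.matrix(Matrix::solve(Matrix::t(Lt), Y))
  # exact mass normalization + deterministic sign (largest |entry| positive)
  mnorm <- sqrt(colSums(Phi * as.matrix(M %*% Phi)))
  Phi <- sweep(Phi, 2, mnorm, "/")
  sgn <- apply(Phi, 2, function(v) sign(v[which.max(abs(v))]))
  Phi <- sweep(Phi, 2, sgn, "*")
  # quality metrics
  KP <- as.matrix(K %*% Phi)
  MP <- as.matrix(M %*% Phi)
  resid <- vapply(seq_len(k), function(j) {
    num <- sqrt(sum((KP[, j] - lambda[j] * MP[, j])^2))
    num / max(sqrt(sum(KP[, j]^2)), .Machine$double.xmin)
  }, numeric(1))
  G <- crossprod(Phi, MP)
  ortho <- max(abs(G - diag(k)))
  lambda[lambda < 0 & lambda > -tol * max(abs(lambda))] <- 0
  full <- matrix(0, 3L * system$n_nodes, k)
  full[system$free_dofs, ] <- Phi
  structure(
    list(frequencies_hz = sqrt(pmax(lambda, 0)) / (2 * pi),
         omega2 = lambda, shapes = full,
         residuals = resid, ortho_error = ortho,
         free_dofs = system$free_dofs, n_nodes = system$n_nodes,
         provenance = c(list(mesh_hash = system$mesh_hash,
                             free_free = free_free, k = k), provenance)),
    class = "modal_solution")
}

#' @exportS3Method base::print
print.modal_solution <- function(x, ...) {
  cat(sprintf("modal_solution: %d modes, ortho error %.2e\n",
              length(x$frequencies_hz), x$ortho_error))
  print(data.frame(mode = seq_along(x$frequencies_hz),
                   frequency_hz = round(x$frequencies_hz, 2),
                   residual = signif(x$residuals, 3)))
  invisible(x)
}

#' Surface-normal displacement of each mode
#'
#' |u . n| at every surface vertex, with vertex normals the area-weighted
#' average of incident triangle normals. Values are zero at constrained
#' nodes. The surface must come from the same mesh as the solution
#' (hash-checked).
#'
#' @param solution a [solve_modes()] result.
#' @param surface a [surface_extract()] result.
#' @return matrix, surface vertices x modes, of |u . n|.
#' @export
normal_displacement <- function(solution, surface) {
  if (!identical(surface$mesh_hash, solution$provenance$mesh_hash))
    stop2("surface and solution come from different meshes (hash mismatch)")
  vol <- surface$to_volume
  k <- length(solution$frequencies_hz)
  out <- matrix(0, length(vol), k)
  for (ax in 1:3) {
    comp <- solution$shapes[3L * (vol - 1L) + ax, , drop = FALSE]
    out <- out + comp * surface$vertex_normals[, ax]
  }
  abs(out)
}

#' Modal assurance criterion matrix
#'
#' MAC(i, j) = (phi_i' W phi_j)^2 / ((phi_i' W phi_i)(phi_j' W phi_j)).
#' With `W = NULL` the plain (identity-weighted) MAC is used, which also
#' permits comparing solutions restricted to a shared node subset.
#'
#' @param A,B shape matrices (dofs x modes) on the same dof set.
#' @param W optional symmetric weighting matrix (typically the mass matrix).
#' @return MAC matrix, modes of A x modes of B, entries in [0, 1].
#' @export
mac_matrix <- function(A, B, W = NULL) {
  WB <- if (is.null(W)) B else as.matrix(W %*% B)
  WA <- if (is.null(W)) A else as.matrix(W %*% A)
  num <- crossprod(A, WB)^2
  den <- outer(colSums(A * WA), colSums(B * WB))
  num / pmax(den, .Machine$double.xmin)
}

#' Track modes between two solutions by greedy maximum-MAC assignment
#'
#' Pairs are assigned in descending MAC order, each index used once; ties are
#' broken by the smaller frequency gap; pairs below `threshold` are left
#' unmatched. Both solutions must share a dof map unless `dofs` restricts
#' the comparison to a common subset.
#'
#' @param a,b [solve_modes()] results.
#' @param mass optional mass matrix over free DOFs for the M-weighted MAC
#'   (e.g. `system$M`); requires identical free-dof maps.
#' @param threshold minimum MAC to accept a pair (default 0.7).
#' @param dofs optional integer vector of full-model dof ids on which to
#'   compare (defaults to the free dofs of `a`).
#' @return an object of class `mode_track`: data.frame `pairs` (mode_a,
#'   mode_b, mac, df_hz), `unmatched_a`, `unmatched_b`, and the full `mac`
#'   matrix.
#' @export
track_modes <- function(a, b, mass = NULL, threshold = 0.7, dofs = NULL) {
  if (is.null(dofs)) {
    if (!identical(a$free_dofs, b$free_dofs))
      stop2("solutions have different dof maps; pass `dofs` to compare on a subset")
    A <- a$shapes[a$free_dofs, , drop = FALSE]
    B <- b$shapes[b$free_dofs, , drop = FALSE]
  } else {
    if (!is.null(mass)) stop2("mass weighting requires the full shared dof map")
    A <- a$shapes[dofs, , drop = FALSE]
    B <- b$shapes[dofs, , drop = FALSE]
  }
  mac <- mac_matrix(A, B, W = mass)
  ka <- ncol(A); kb <- ncol(B)
  fa <- a$frequencies_hz; fb <- b$frequencies_hz
  cand <- which(mac >= threshold, arr.ind = TRUE)
  if (nrow(cand)) {
    gap <- abs(fa[cand[, 1]] - fb[cand[, 2]])
    ordc <- order(-mac[cand], gap)
    cand <- cand[ordc, , drop = FALSE]
  }
  used_a <- logical(ka); used_b <- logical(kb)
  pairs <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    pairs[[length(pairs) + 1L]] <-
      data.frame(mode_a = i, mode_b = j, mac = mac[i, j],
                 df_hz = fb[j] - fa[i])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(mode_a = integer(0), mode_b = integer(0),
               mac = numeric(0), df_hz = numeric(0))
  pairs <- pairs[order(pairs$mode_a), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, unmatched_a = which(!used_a),
                 unmatched_b = which(!used_b), mac = mac,
                 threshold = threshold),
            class = "mode_track")
}

#' @exportS3Method base::print
print.mode_track <- function(x, ...) {
  cat(sprintf("mode_track: %d pair(s), threshold %.2f\n",
              nrow(x$pairs), x$threshold))
  print(x$pairs)
  if (length(x$unmatched_a))
    cat("unmatched in a:", paste(x$unmatched_a, collapse = ", "), "\n")
  if (length(x$unmatched_b))
    cat("unmatched in b:", paste(x$unmatched_b, collapse = ", "), "\n")
  invisible(x)
}

#' Run a factorial material sweep
#'
#' One modal solve per combination of the per-region card lists; each
#' solution is tagged with its material cards in the provenance.
#'
#' @param mesh a [tet_mesh()].
#' @param cards named list: region -> list of [material_card()]s.
#' @param fixed fixed node ids (see [fixed_node_set()]).
#' @param k modes per solve.
#' @param max_combinations combination guard (default 200).
#' @param ... passed to [solve_modes()].
#' @return list of `modal_solution`s, one per combination.
#' @export
sweep_materials <- function(mesh, cards, fixed, k = 20L,
                            max_combinations = 200L, ...) {
  combos <- expand_material_sweep(cards, max_combinations)
  lapply(seq_along(combos), function(i) {
    mats <- combos[[i]]
    sys <- assemble_system(mesh, mats, fixed)
    solve_modes(sys, k = k,
                provenance = list(materials = mats, combination = i), ...)
  })
}

#' Per-component modal strain energy fractions
#'
#' For each mode, the fraction of total strain energy phi' K phi carried by
#' the elements of each component. Used to classify modes as "appendage"
#' (ossicle-chain) modes versus whole-structure modes for ablation studies.
#'
#' @param mesh the mesh the solution was computed on.
#' @param materials region -> [material_card()] used for the solve.
#' @param solution a [solve_modes()] result.
#' @return matrix, components x modes, columns summing to 1.
#' @export
strain_energy_fractions <- function(mesh, materials, solution) {
  if (!identical(mesh$hash, solution$provenance$mesh_hash))
    stop2("mesh and solution hashes differ")
  npe <- mesh$order
  ref <- reference_tensors(npe)
  comps <- unique(mesh$component)
  k <- length(solution$frequencies_hz)
  energy <- matrix(0, length(comps), k,
                   dimnames = list(comps, NULL))
  for (e in seq_len(nrow(mesh$elements))) {
    nd <- mesh$elements[e, ]
    card <- materials[[mesh$region[e]]]
    em <- element_matrices(mesh$nodes[nd[1:4], , drop = FALSE], npe,
                           lame_lambda(card), lame_mu(card), card$density, ref)
    dofs <- as.vector(rbind(3L * nd - 2L, 3L * nd - 1L, 3L * nd))
    Pe <- solution$shapes[dofs, , drop = FALSE]
    energy[mesh$component[e], ] <- energy[mesh$component[e], ] +
      colSums(Pe * (em$K %*% Pe))
  }
  sweep(energy, 2, colSums(energy), "/")
}

#' Compare an intact and an ablated model mode by mode
#'
#' MAC tracking restricted to the shared surviving nodes (identity-weighted
#' MAC, since the two models have different mass matrices). For every mode of
#' the intact solution the best ablated match, its MAC and the relative
#' frequency shift are reported.
#'
#' @param intact,ablated [solve_modes()] results of the full and reduced
#'   models.
#' @param node_map the renumbering map returned by [remove_components()].
#' @param threshold MAC acceptance threshold (default 0.7).
#' @return data.frame: mode (intact index), matched (ablated index or NA),
#'   mac, f_intact_hz, f_ablated_hz, rel_shift.
#' @export
ablation_compare <- function(intact, ablated, node_map, threshold = 0.7) {
  shared_old <- which(!is.na(node_map))
  shared_new <- node_map[shared_old]
  dofs_old <- as.vector(rbind(3L * shared_old - 2L, 3L * shared_old - 1L,
                              3L * shared_old))
  dofs_new <- as.vector(rbind(3L * shared_new - 2L, 3L * shared_new - 1L,
                              3L * shared_new))
  A <- intact$shapes[dofs_old, , drop = FALSE]
  B <- ablated$shapes[dofs_new, , drop = FALSE]
  mac <- mac_matrix(A, B)
  ka <- ncol(A)
  out <- data.frame(mode = seq_len(ka), matched = NA_integer_,
                    mac = NA_real_, f_intact_hz = intact$frequencies_hz,
                    f_ablated_hz = NA_real_, rel_shift = NA_real_)
  used_b <- logical(ncol(B))
  cand <- which(mac >= threshold, arr.ind = TRUE)
  if (nrow(cand)) {
    gap <- abs(intact$frequencies_hz[cand[, 1]] -
               ablated$frequencies_hz[cand[, 2]])
    cand <- cand[order(-mac[cand], gap), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (!is.na(out$matched[i]) || used_b[j]) next
      out$matched[i] <- j; used_b[j] <- TRUE
      out$mac[i] <- mac[i, j]
      out$f_ablated_hz[i] <- ablated$frequencies_hz[j]
      out$rel_shift[i] <- (ablated$frequencies_hz[j] -
                           intact$frequencies_hz[i]) / intact$frequencies_hz[i]
    }
  }
  out
}
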