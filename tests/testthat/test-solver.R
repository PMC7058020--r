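# Independent brute-force path: enumerate the discrete quadratic form of
# the scalar energy functional by polarization of total_energy() over
# neighbouring unknowns (the functional is local, so only same-node and
# adjacent-node pairs couple), then minimize with a dense constrained
# solve.  This never touches the sparse assembly code.
brute_force_solve <- function(layout, grid) {
  prob <- assemble(layout, grid)      # constraint definition only
  m <- grid$m; N <- grid$N
  vec2field <- function(u) {
    deformation_field(grid$x,
                      n_u = u[seq_len(N)], n_l = u[N + seq_len(N)],
                      H_u = u[2 * N + seq_len(N)],
                      H_l = u[3 * N + seq_len(N)],
                      M = u[4 * N + seq_len(N)], layout = layout,
                      excl_cells_u = prob$excl_cells_u,
                      excl_cells_l = prob$excl_cells_l)
  }
  fe <- function(u) suppressWarnings(total_energy(vec2field(u)))
  z <- numeric(m)
  f0 <- fe(z)
  ei <- function(i) { v <- z; v[i] <- 1; v }
  fp <- vapply(seq_len(m), function(i) fe(ei(i)), numeric(1))
  fm <- vapply(seq_len(m), function(i) fe(-ei(i)), numeric(1))
  g <- (fp - fm) / 2                       # linear part
  q <- (fp + fm) / 2 - f0                  # diagonal quadratic part
  H <- matrix(0, m, m)
  diag(H) <- 2 * q
  # couple unknowns at the same node or adjacent nodes only
  node_of <- rep(seq_len(N), 5)
  for (i in seq_len(m)) {
    js <- which(abs(node_of - node_of[i]) <= 1)
    js <- js[js > i]
    for (j in js) {
      v <- z; v[i] <- 1; v[j] <- 1
      qij <- (fe(v) + fe(-v)) / 2 - f0 - q[i] - q[j]
      H[i, j] <- H[j, i] <- qij
    }
  }
  C <- as.matrix(prob$C); d <- prob$d; k <- nrow(C)
  KKT <- rbind(cbind(H, t(C)), cbind(C, matrix(0, k, k)))
  sol <- solve(KKT, c(-g, d))
  u <- sol[seq_len(m)]
  list(W = fe(u) + 0, u = u)
}

test_that("uniform membranes relax to the zero-energy ground state", {
  mem <- test_membrane()
  for (ph in c("r", "s")) {
    lay <- region_layout(uniform_membrane(mem[[ph]]), L = 0)
    sol <- solve_layout(lay, fast_settings())
    expect_lt(abs(sol$W), 1e-10)
    expect_lt(max(abs(sol$field$n_u)), 1e-8)
    up <- mem[[ph]]
    expect_equal(max(abs(sol$field$H_u - sol$field$M -
                           up$h * (1 - up$alpha0))), 0, tolerance = 1e-8)
  }
  # a uniform phase with spontaneous curvature is still stress-free
  pj <- monolayer_parameters(B = 10, Kt = 10, Ka = 30, J0 = 0.25, h = 1.3)
  solj <- solve_layout(region_layout(uniform_membrane(pj), L = 0),
                       fast_settings())
  expect_lt(abs(solj$W), 1e-10)
})

test_that("constrained minimization agrees with brute-force enumeration", {
  mem <- test_membrane()
  layouts <- list(
    bare = region_layout(mem, L = 2),
    stripe = region_layout(mem, L = 2,
                           inclusion = lipid_stripe(1.5, 0.2, 12, X0 = 1)),
    tm = region_layout(mem, L = 2,
                       inclusion = transmembrane_protein(3.1, dnx_u = 0.2,
                                                         X0 = 1)))
  for (nm in names(layouts)) {
    lay <- layouts[[nm]]
    grid <- raftline:::build_grid(lay, dx = 0.4, half_width = 10)
    ours <- solve_equilibrium(assemble(lay, grid))
    oracle <- brute_force_solve(lay, grid)
    expect_equal(ours$W, oracle$W, tolerance = 5e-3, info = nm)
  }
})

test_that("quadratic-form energy equals the functional on the minimizer", {
  mem <- test_membrane()
  for (lay in list(region_layout(mem, L = 3),
                   region_layout(mem, L = -3,
                                 inclusion = lipid_stripe(1.55, 0.25, 10,
                                                          X0 = -1)))) {
    sol <- solve_layout(lay, fast_settings())
    expect_lt(abs(sol$W - sol$W_quad), 1e-6)
    expect_lt(sol$residual, 1e-8)
  }
})

test_that("enlarging the box never raises the energy beyond tolerance", {
  mem <- test_membrane()
  lay <- region_layout(mem, L = 3)
  W12 <- solve_layout(lay, solver_settings(0.05, 12))$W
  W20 <- solve_layout(lay, solver_settings(0.05, 20))$W
  W30 <- solve_layout(lay, solver_settings(0.05, 30))$W
  expect_lt(W20 - W12, 1e-3 * abs(W12))
  expect_lt(W30 - W20, 1e-3 * abs(W20))
})

test_that("minimizer deformations decay towards the box edges", {
  # the thickness/tilt modes decay over 1-2 nm; a weak tension-bending
  # tail (decay scale sqrt(sum(B)/2 sigma0), tens of nm) keeps the edge
  # deviation at the per-mille level rather than strictly zero
  mem <- test_membrane()
  ratios <- function(hw) {
    f <- solve_layout(region_layout(mem, L = 3),
                      solver_settings(0.05, hw))$field
    x <- f$x
    outer <- x < min(x) + 0.1 * (max(x) - min(x)) |
      x > max(x) - 0.1 * (max(x) - min(x))
    up <- raftline:::layout_cell_params(f$layout, x, "upper")
    td <- abs(f$H_u - f$M - up$h * (1 - up$alpha0))
    c(n = max(abs(f$n_u[outer])) / max(abs(f$n_u)),
      thick = max(td[outer]) / max(td))
  }
  r15 <- ratios(15)
  expect_lt(r15["n"], 1e-2)
  expect_lt(r15["thick"], 5e-2)
  r20 <- ratios(20)
  expect_lt(r20["n"], r15["n"] + 1e-9)
  expect_lt(r20["thick"], r15["thick"] + 1e-9)
})

test_that("refinement ladder converges and reports diagnostics", {
  mem <- test_membrane()
  res <- refine_until_converged(region_layout(mem, L = 3),
                                solver_settings(0.05, 12,
                                                rel_tol = 1e-2,
                                                max_refinements = 4))
  expect_true(nrow(res$diagnostics) >= 2)
  Ws <- res$diagnostics$W
  expect_lt(abs(Ws[length(Ws)] - Ws[length(Ws) - 1]),
            1e-2 * abs(Ws[length(Ws)]))
  # trivial uniform case converges immediately
  res0 <- refine_until_converged(region_layout(uniform_membrane(mem$s)),
                                 solver_settings(0.05, 12, rel_tol = 1e-3,
                                                 max_refinements = 3))
  expect_equal(nrow(res0$diagnostics), 2)
  expect_lt(abs(res0$W), 1e-10)
  expect_error(refine_until_converged(region_layout(mem, L = 3),
                                      solver_settings(0.05, 12,
                                                      rel_tol = 0)),
               "rel_tol")
})

test_that("dropping the gauge constraint exposes the rigid mode", {
  mem <- test_membrane()
  lay <- region_layout(mem, L = 3)
  grid <- raftline:::build_grid(lay, 0.1, 10)
  prob <- assemble(lay, grid)
  keep <- !grepl("gauge", prob$tags)
  prob$C <- prob$C[keep, , drop = FALSE]
  prob$d <- prob$d[keep]
  prob$tags <- prob$tags[keep]
  expect_error(suppressWarnings(solve_equilibrium(prob)),
               "vertical\\s+translation")
})

test_that("constraint bookkeeping matches the configuration", {
  mem <- test_membrane()
  # bare boundary: 2 x (2 directors + 2 thickness anchors) + 1 gauge pin
  prob <- assemble(region_layout(mem, L = 3),
                   raftline:::build_grid(region_layout(mem, L = 3),
                                         0.05, 12))
  expect_length(prob$tags, 9)
  # transmembrane adds 7 physical conditions plus excluded-node pins
  lay <- region_layout(mem, L = 3,
                       inclusion = transmembrane_protein(3.1, dnx_u = 0.4,
                                                         X0 = 1))
  grid <- raftline:::build_grid(lay, 0.05, 12)
  prob2 <- assemble(lay, grid)
  n_inner <- sum(grid$x > 1 - 0.65 + 1e-9 & grid$x < 1 + 0.65 - 1e-9)
  expect_length(prob2$tags, 9 + 7 + 5 * n_inner)
})
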