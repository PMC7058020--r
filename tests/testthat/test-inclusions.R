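test_that("geometric director jump magnitudes", {
  # direct arithmetic of |dn| = dL / sqrt((dL/2)^2 + (h/2)^2)
  expect_equal(director_jump_bulk(1.3, 1.3), 1.3 / sqrt(0.65^2 + 0.65^2),
               tolerance = 1e-9)
  expect_equal(director_jump_bulk(1.3, 1.3), sqrt(2), tolerance = 1e-9)
  expect_equal(director_jump_bulk(1.3, 1.8), 1.3 / sqrt(0.65^2 + 0.9^2),
               tolerance = 1e-9)
  expect_equal(director_jump_bulk(1.3, 1.8), 1.1709822, tolerance = 1e-6)
  # narrow-peptide limit
  expect_lt(director_jump_bulk(1e-6, 1.3), 1e-5)
  expect_error(director_jump_bulk(0, 1.3), "positive")
  expect_error(director_jump_bulk(1.3, -1), "positive")
})

test_that("boundary-straddling jump interpolates between the phases", {
  expect_equal(director_jump_boundary(1.3, 1.8, 1.3, delta = 1),
               director_jump_bulk(1.3, 1.8))
  expect_equal(director_jump_boundary(1.3, 1.8, 1.3, delta = 0),
               director_jump_bulk(1.3, 1.3))
  expect_equal(director_jump_boundary(1.3, 1.8, 1.3, delta = 0.5),
               (director_jump_bulk(1.3, 1.8) +
                  director_jump_bulk(1.3, 1.3)) / 2)
  expect_equal(director_jump_boundary(1.3, 1.8, 1.3, delta = 0.5),
               1.2925977, tolerance = 1e-6)
  expect_error(director_jump_boundary(1.3, 1.8, 1.3, delta = 1.2),
               "\\[0, 1\\]")
})

test_that("constraint sets carry the family contract and provenance tags", {
  mem <- test_membrane()
  grid <- raftline:::build_grid(region_layout(mem, L = 3), 0.05, 12)
  tags_of <- function(spec) {
    lay <- region_layout(mem, L = 3, inclusion = spec)
    bc <- raftline:::build_constraints(spec, lay, grid)
    vapply(bc$constraints, `[[`, character(1), "tag")
  }

  tg <- tags_of(amphipathic_peptide(X0 = -5))
  expect_length(tg, 2)
  expect_true(any(grepl("director jump", tg)))
  expect_true(any(grepl("rotation", tg)))

  tg <- tags_of(hydrophobic_peptide(0.4, X0 = -5, where = "upper"))
  expect_length(tg, 2)
  expect_true(any(grepl("director jump, upper", tg)))
  expect_true(any(grepl("continuous neutral surface, upper", tg)))

  tg <- tags_of(hydrophobic_peptide(0.4, X0 = -5, where = "midplane"))
  expect_length(tg, 4)
  expect_true(any(grepl("director jump, lower", tg)))
  expect_true(any(grepl("continuous neutral surface, lower", tg)))

  tg <- tags_of(transmembrane_protein(3.1, dnx_u = 0.4, X0 = -5))
  expect_length(tg, 7)
  expect_equal(sum(grepl("thickness", tg)), 2)
  expect_equal(sum(grepl("boundary director", tg)), 4)
  expect_equal(sum(grepl("rigid body", tg)), 1)

  lay <- region_layout(mem, L = 3,
                       inclusion = lipid_stripe(1.55, 0, 10, X0 = -5))
  bc <- raftline:::build_constraints(lay$inclusion, lay, grid)
  expect_length(bc$constraints, 0)
  expect_false(any(bc$excl_cells_u))
})

test_that("peptide jump applied in bulk equals the geometric estimate", {
  mem <- test_membrane()
  spec <- amphipathic_peptide(X0 = -6)   # deep in the Ld phase
  lay <- region_layout(mem, L = 3, inclusion = spec)
  grid <- raftline:::build_grid(lay, 0.05, 12)
  bc <- raftline:::build_constraints(spec, lay, grid)
  jump <- Filter(function(cr) grepl("director jump", cr$tag),
                 bc$constraints)[[1]]
  # negative x-projection (heads pushed apart) of bulk magnitude
  expect_equal(jump$rhs, -director_jump_bulk(1.3, mem$s$h),
               tolerance = 1e-9)
  # in the ordered bulk the magnitude uses h_r instead
  spec2 <- amphipathic_peptide(X0 = 8)
  bc2 <- raftline:::build_constraints(spec2,
                                      region_layout(mem, L = 3,
                                                    inclusion = spec2),
                                      grid)
  jump2 <- Filter(function(cr) grepl("director jump", cr$tag),
                  bc2$constraints)[[1]]
  expect_equal(jump2$rhs, -director_jump_bulk(1.3, mem$r$h),
               tolerance = 1e-9)
})

test_that("identity inclusions leave the membrane energy unchanged", {
  mem <- test_membrane()
  st <- fast_settings()
  Wbare <- cached("bare_L3_fast", function()
    solve_layout(region_layout(mem, L = 3), st))$W
  # stripe with host-phase parameters deep in the ordered bulk
  ident <- lipid_stripe(h0 = mem$r$h, J0 = mem$r$J0, B0 = mem$r$B, X0 = 8)
  Wid <- solve_layout(region_layout(mem, L = 3, inclusion = ident), st)$W
  # the simulation box is laid out around the inclusion, so agreement is
  # limited by the residual box-truncation error, not by the physics
  expect_equal(Wid, Wbare, tolerance = 1e-4)
  # hydrophobic-length-matched cylinder in a uniform disordered membrane
  cyl <- transmembrane_protein(h0 = 2 * mem$s$h * (1 - mem$s$alpha0),
                               dnx_u = 0, X0 = 3)
  W0 <- solve_layout(region_layout(uniform_membrane(mem$s), L = 0,
                                   inclusion = cyl), st)$W
  expect_lt(abs(W0), 1e-6)
})

test_that("mirror symmetry through the bilayer midplane", {
  # reflecting the whole stack swaps the leaflets; re-anchoring the
  # lower-leaflet boundary at x = 0 then maps (X0, L) to (X0 - L, -L)
  mem <- test_membrane()
  st <- fast_settings()
  for (spec in list(hydrophobic_peptide(0.4, where = "midplane"),
                    transmembrane_protein(3.1, dnx_u = 0.4,
                                          dnx_l = 0.4))) {
    Wp <- solve_layout(region_layout(
      mem, L = 3, inclusion = raftline:::set_position(spec, 1)), st)$W
    Wm <- solve_layout(region_layout(
      mem, L = -3, inclusion = raftline:::set_position(spec, -2)), st)$W
    expect_equal(Wp, Wm, tolerance = 1e-9, info = spec$family)
  }
  # asymmetric transmembrane: the reflection also swaps the per-leaflet
  # director jumps
  a <- transmembrane_protein(3.1, dnx_u = 0.4, dnx_l = -0.1, X0 = 1)
  b <- transmembrane_protein(3.1, dnx_u = -0.1, dnx_l = 0.4, X0 = -2)
  Wa <- solve_layout(region_layout(mem, L = 3, inclusion = a), st)$W
  Wb <- solve_layout(region_layout(mem, L = -3, inclusion = b), st)$W
  expect_equal(Wa, Wb, tolerance = 1e-9)
  # the bare boundary inherits the same symmetry: W(L) = W(-L)
  Wp <- solve_layout(region_layout(mem, L = 2), st)$W
  Wm <- solve_layout(region_layout(mem, L = -2), st)$W
  expect_equal(Wp, Wm, tolerance = 1e-9)
})

test_that("inclusion geometry is validated", {
  mem <- test_membrane()
  expect_error(lipid_stripe(h0 = -1), "positive")
  expect_error(transmembrane_protein(h0 = 0), "positive")
  expect_error(hydrophobic_peptide(2.5), "exceed")
  lay <- region_layout(mem, L = 3,
                       inclusion = transmembrane_protein(3.1, X0 = 0,
                                                         deltaL = 0.06))
  grid <- raftline:::build_grid(lay, 0.05, 12)
  expect_error(raftline:::build_constraints(lay$inclusion, lay, grid),
               "2\\*dx")
  # unset position
  lay2 <- region_layout(mem, L = 3, inclusion = amphipathic_peptide())
  expect_error(raftline:::build_constraints(lay2$inclusion, lay2, grid),
               "not set")
})
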