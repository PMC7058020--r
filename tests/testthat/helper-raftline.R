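# Shared fixtures for the suite.  Scans use a coarse but converged grid
# (dx = 0.05 nm, 12 nm box margin) to keep the default run quick; the
# refinement-ladder tests check that this resolution is inside the 1%
# convergence band.

fast_settings <- function() solver_settings(dx = 0.05, half_width = 12)
test_membrane <- function() default_membrane()

# single-phase membrane built from one monolayer parameter set
uniform_membrane <- function(p) list(r = p, s = p)

# cache for expensive profiles reused across test blocks
.raftline_cache <- new.env(parent = emptyenv())
cached <- function(key, fun) {
  if (!exists(key, envir = .raftline_cache))
    assign(key, fun(), envir = .raftline_cache)
  get(key, envir = .raftline_cache)
}

# random smooth decaying perturbation of the flat state (admissible for
# total_energy: deformations vanish near the box edges)
random_field <- function(layout, grid, seed, amp = 0.05) {
  set.seed(seed)
  x <- grid$x
  bump <- function() {
    ctr <- stats::runif(1, min(x) + 8, max(x) - 8)
    wid <- stats::runif(1, 0.8, 2.5)
    stats::runif(1, -amp, amp) * exp(-(x - ctr)^2 / (2 * wid^2))
  }
  many <- function(k) Reduce(`+`, replicate(k, bump(), simplify = FALSE))
  f <- raftline:::flat_field(layout, grid)
  f$n_u <- f$n_u + many(3)
  f$n_l <- f$n_l + many(3)
  f$H_u <- f$H_u + many(3)
  f$H_l <- f$H_l + many(3)
  f$M <- f$M + many(3)
  f
}
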