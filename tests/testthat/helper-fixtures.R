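# Shared fixtures. The "mini" head is a shrunk phantom (46 mm scalp radius,
# 3 mm voxels, ~16k unknowns) with proportionally shrunk arrays, solved by
# the direct solver in well under a second - used by unit tests. The
# full-scale acceptance runs (2 mm) are computed once and memoized.

mini_phantom_config <- function(spacing = 3, tumor_center = c(24, 0, 0),
                                defect_diameter = 26) {
  phantom_config(
    radii = c(scalp = 46, skull = 42, csf = 39, gm = 37, wm = 30),
    spacing = spacing,
    tumor = list(center = tumor_center, r_core = 5, t_shell = 4),
    defect = list(diameter = defect_diameter),
    montage = "LR",
    array = list(pitch = 18, transducer_radius = 7, gel_radius = 8.5)
  )
}

## tight-tolerance iterative solve: deterministic, and much faster than a
## 3-D direct factorization at the mini phantom size
mini_solver <- function() solver_config(mode = "iterative", rel_tol = 1e-10)

mini_study_config <- function(..., cases = c("intact", "defect", "insulated")) {
  study_config(phantom = mini_phantom_config(...),
               solver = mini_solver(),
               cases = cases)
}

## one solved mini intact case, shared across test files
mini_solution <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pl <- ttfieldsim:::build_case_phantom(mini_study_config(), "intact")
      sys <- assemble_system(pl$phantom, cfg = mini_solver())
      sol <- electric_field(solve_potential(sys, mini_solver()))
      cache <<- list(phantom = pl$phantom, sys = sys, sol = sol)
    }
    cache
  }
})

## full-scale 2 mm acceptance runs: per fixture, all three cases, with the
## power-balance error recorded before the heavy solution object is dropped
acceptance_cases <- local({
  cache <- new.env(parent = emptyenv())
  function(fixture = c("superficial", "deep")) {
    fixture <- match.arg(fixture)
    if (!is.null(cache[[fixture]])) return(cache[[fixture]])
    cfg <- study_config(
      phantom = switch(fixture,
                       superficial = superficial_fixture_config(spacing = 2),
                       deep = deep_fixture_config(spacing = 2)),
      solver = solver_config(mode = "iterative")
    )
    out <- lapply(c("intact", "defect", "insulated"), function(cs) {
      s <- run_case(cfg, cs)
      sol <- attr(s, "solution")
      attr(s, "solution") <- NULL
      attr(s, "phantom") <- NULL
      s$power_balance <- power_balance_error(sol)
      s
    })
    names(out) <- c("intact", "defect", "insulated")
    cache[[fixture]] <- out
    out
  }
})

shell_mean <- function(s) s$mean_shell_vcm
brain_mean <- function(s) s$tissue_stats$mean_vcm[s$tissue_stats$tissue == "brain"]
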