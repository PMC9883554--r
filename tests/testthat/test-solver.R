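# Solver unit tests on small fixtures.

test_that("assembled system is conservative and complex symmetric", {
  ms <- mini_solution()
  sys <- ms$sys
  # interior rows (no Dirichlet face) sum to zero: diag == sum of offd
  rowsum_off <- rowSums(sys$offd)
  interior <- setdiff(seq_len(sys$n), sys$dirichlet$row)
  expect_lt(max(Mod(sys$diag[interior] - rowsum_off[interior])),
            1e-12 * max(Mod(sys$diag)))
  # symmetry: the conductance stored for (i -> j) equals (j -> i)
  for (c_plus in c(2L, 4L, 6L)) {
    sel <- which(sys$nbr[, c_plus] > 0L)
    j <- sys$nbr[sel, c_plus]
    expect_identical(sys$nbr[cbind(j, c_plus - 1L)], sel)
    expect_equal(sys$offd[cbind(j, c_plus - 1L)], sys$offd[sel, c_plus])
  }
})

test_that("homogeneous slab gives a linear potential and uniform field", {
  v <- validate_slab("scalp", 100, spacing = 10, frequency = 2e5)
  expect_lt(v$max_rel_err_E, 1e-9)
  expect_equal(unique(round(v$sol$emag, 6)), 800)
  # phi drops linearly along x
  phi <- Re(v$sol$phi[v$sol$sys$idx[, 2, 2]])
  expect_equal(diff(phi), rep(8, 9), tolerance = 1e-9)
})

test_that("DC two-layer slab satisfies the discrete maximum principle and the
           series field ratio", {
  v <- validate_slab(c("scalp", "skull"), c(50, 50), spacing = 5,
                     frequency = 0)
  phi <- Re(v$sol$phi)
  expect_gte(min(phi), 0)
  expect_lte(max(phi), 80)
  # |E_skull| / |E_scalp| = sigma_scalp / sigma_skull away from the interface
  sys <- v$sol$sys
  xs <- ttfieldsim:::phantom_coords(slab_phantom(c("scalp", "skull"),
                                                 c(50, 50), 5))$x
  x_dom <- xs[arrayInd(sys$dom_lin, sys$dims)[, 1]]
  e_scalp <- v$sol$emag[x_dom > 10 & x_dom < 40]
  e_skull <- v$sol$emag[x_dom > 60 & x_dom < 90]
  expect_equal(mean(e_skull) / mean(e_scalp), 0.25 / 0.0211,
               tolerance = 1e-9)
  # central differences agree with the closed form away from the interface
  sol_c <- electric_field(v$sol, method = "central")
  e_skull_c <- sol_c$emag[x_dom > 60 & x_dom < 90]
  expect_equal(mean(e_skull_c) / mean(e_scalp), 0.25 / 0.0211,
               tolerance = 1e-9)
})

test_that("mirror-symmetric phantom yields a mirror-symmetric potential", {
  ms <- mini_solution()
  vol <- as_volume(ms$sol, "phi")
  d <- dim(vol)
  flipped <- vol[, d[2]:1, , drop = FALSE]
  keep <- !is.na(vol)
  expect_lt(max(abs(vol[keep] - flipped[keep])), 1e-6 * 80)
})

test_that("swapping active and ground negates the potential about V/2", {
  ms <- mini_solution()
  cfg2 <- mini_phantom_config()
  cfg2$array$active_side <- -1L
  ph2 <- build_head_phantom(cfg2)
  ph2 <- embed_tumor(ph2, cfg2$tumor$center, cfg2$tumor$r_core,
                     cfg2$tumor$t_shell)
  pl2 <- place_arrays(ph2)
  sys2 <- assemble_system(pl2$phantom, cfg = mini_solver())
  sol2 <- electric_field(solve_potential(sys2, mini_solver()))
  # phi_swapped = 80 - phi by linearity; |E| unchanged
  expect_equal(sort(Re(sol2$phi)), sort(80 - Re(ms$sol$phi)),
               tolerance = 1e-6)
  expect_equal(sort(sol2$emag), sort(ms$sol$emag), tolerance = 1e-6)
})

test_that("insulating film with vanishing thickness recovers the bare contact", {
  cfgs <- mini_study_config()
  pl <- ttfieldsim:::build_case_phantom(cfgs, "insulated")
  scfg <- mini_solver()
  sys_thin <- assemble_system(pl$phantom, cfg = scfg,
                              film = contact_film(thickness = 1e-13))
  sol_thin <- solve_potential(sys_thin, scfg)
  pl0 <- ttfieldsim:::build_case_phantom(cfgs, "defect")  # same geometry, no film
  sys0 <- assemble_system(pl0$phantom, cfg = scfg)
  sol0 <- solve_potential(sys0, scfg)
  expect_equal(sol_thin$phi, sol0$phi, tolerance = 1e-4)
  # and the default 1 um film visibly decouples the array
  sys_f <- assemble_system(pl$phantom, cfg = scfg)
  sol_f <- solve_potential(sys_f, scfg)
  expect_gt(max(Mod(sol_f$phi - sol0$phi)), 1)
})

test_that("DC limit of the complex solver equals a real Laplace solve", {
  radii <- c(30, 27, 24)
  labs <- c("scalp", "skull", "gray_matter")
  ph <- build_layered_sphere_phantom(radii, labs, spacing = 3)
  cfg0 <- solver_config(freq = frequency_spec(0), mode = "iterative",
                        rel_tol = 1e-10)
  exc <- list(type = "caps", axis = 3L, half_angle_deg = 25, current_A = 1e-3)
  sys <- assemble_system(ph, cfg = cfg0, excitation = exc)
  sol_c <- solve_potential(sys, cfg0)
  expect_lt(max(abs(Im(sol_c$phi))), 1e-10 * max(abs(Re(sol_c$phi))))
  # independent real solve of the same (real) system via sparse LU
  n <- sys$n
  ii <- seq_len(n); jj <- ii; vv <- Re(sys$diag)
  for (cc in 1:6) {
    sel <- which(sys$nbr[, cc] > 0L)
    ii <- c(ii, sel); jj <- c(jj, sys$nbr[sel, cc])
    vv <- c(vv, -Re(sys$offd[sel, cc]))
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  # pin the (singular) pure-Neumann system by dropping the constant mode
  x <- as.numeric(Matrix::solve(M + Matrix::Diagonal(n, 1e-12 * max(vv)),
                                Re(sys$rhs)))
  x <- x - mean(x)
  expect_equal(Re(sol_c$phi), x, tolerance = 1e-4)
})

test_that("iterative solver reports non-convergence explicitly", {
  ms <- mini_solution()
  cfg_bad <- solver_config(mode = "iterative", max_iter = 2L)
  expect_error(solve_potential(ms$sys, cfg_bad), "did not converge")
})

test_that("assembly errors on missing excitation path", {
  ph <- build_head_phantom(mini_phantom_config())   # no arrays placed
  expect_error(assemble_system(ph), "place_arrays")
  # DC with sigma = 0 on the electrode: no conductive or capacitive path
  pl <- ttfieldsim:::build_case_phantom(mini_study_config(), "intact")
  cfg0 <- solver_config(freq = frequency_spec(0))
  expect_error(assemble_system(pl$phantom, cfg = cfg0), "path|disconnected")
})
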