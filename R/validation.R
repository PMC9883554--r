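## Built-in validation fixtures: voxel solver versus the closed forms.

#' Build a rectangular slab phantom
#'
#' A box of stacked tissue layers along the x axis, used with the
#' `"plate"` excitation (full-face electrodes on the two x boundaries) to
#' validate the solver against the series closed form.
#'
#' @param layer_labels Tissue label per layer (x order).
#' @param layer_thickness_mm Layer thicknesses, mm.
#' @param spacing Voxel edge, mm (must divide every thickness).
#' @param width_vox Cross-section width in voxels.
#' @return A `voxel_phantom`.
#' @export
slab_phantom <- function(layer_labels, layer_thickness_mm, spacing = 5,
                         width_vox = 4L) {
  stopifnot(length(layer_labels) == length(layer_thickness_mm))
  nlay <- round(layer_thickness_mm / spacing)
  if (max(abs(nlay * spacing - layer_thickness_mm)) > 1e-9) {
    stop("spacing must divide every layer thickness")
  }
  nx <- sum(nlay)
  lab <- array(0L, dim = c(nx, width_vox, width_vox))
  at <- 1L
  for (k in seq_along(layer_labels)) {
    lab[at:(at + nlay[k] - 1L), , ] <- label_code(layer_labels[k])
    at <- at + nlay[k]
  }
  structure(
    list(labels = lab, spacing = spacing,
         origin = c(spacing / 2, spacing / 2, spacing / 2),
         defect_mask = NULL, tid = NULL, arrays = NULL,
         insulation = rep(FALSE, 18L), cfg = NULL),
    class = "voxel_phantom"
  )
}

#' Relative power-balance error of a solution
#'
#' `|P_in - integral(Q)| / P_in`, where `P_in` is the real power through
#' the excitation boundary and the integral is `sum(Q) * voxel volume`.
#'
#' @param sol A solved `field_solution`.
#' @return Nonnegative relative error.
#' @export
power_balance_error <- function(sol) {
  if (is.null(sol$E)) sol <- electric_field(sol)
  P_in <- input_power(sol)
  P_q <- dissipated_power(joule_heating(sol))
  abs(P_in - P_q) / abs(P_in)
}

#' Solve a slab fixture and compare with the closed form
#'
#' @param layer_labels Tissue labels, x order.
#' @param layer_thickness_mm Thicknesses, mm.
#' @param spacing Voxel edge, mm.
#' @param voltage Applied voltage, V.
#' @param frequency Hz (0 = DC).
#' @return List: `sol` (solved `field_solution`), `oracle`
#'   (`slab_solution()` result), `max_rel_err_E` (worst per-voxel relative
#'   error of |E| against the per-layer closed form), `power_balance`.
#' @export
validate_slab <- function(layer_labels, layer_thickness_mm, spacing = 5,
                          voltage = 80, frequency = 0) {
  props <- tissue_table()
  freq <- frequency_spec(frequency)
  ph <- slab_phantom(layer_labels, layer_thickness_mm, spacing = spacing)
  cfg <- solver_config(applied_voltage = voltage, freq = freq,
                       mode = "direct")
  sys <- assemble_system(ph, props, cfg,
                         excitation = list(type = "plate", axis = 1L,
                                           v = voltage))
  sol <- electric_field(solve_potential(sys, cfg))
  kap <- admittivity(props, layer_labels, freq)
  stack <- slab_stack(layer_thickness_mm * 1e-3, kap, voltage = voltage)
  orc <- slab_solution(stack)
  ## per-voxel expected |E| from the layer the voxel sits in
  co <- phantom_coords(ph)
  xs <- co$x[arrayInd(sys$dom_lin, sys$dims)[, 1]]
  edges <- cumsum(layer_thickness_mm)
  layer <- findInterval(xs, edges, left.open = TRUE) + 1L
  expect_e <- Mod(orc$layers$E)[layer]
  err <- abs(sol$emag - expect_e) / max(expect_e)
  list(sol = sol, oracle = orc, max_rel_err_E = max(err),
       power_balance = power_balance_error(sol))
}

## packaged defaults for the two slab acceptance gates
validate_slab_fixture <- function() {
  hom <- validate_slab("scalp", 100, spacing = 5, frequency = 2e5)
  two <- validate_slab(c("scalp", "skull"), c(50, 50), spacing = 5,
                       frequency = 0)
  list(max_rel_err = hom$max_rel_err_E,
       twolayer_rel_err = two$max_rel_err_E,
       power_balance = max(hom$power_balance, two$power_balance))
}

#' Default 3-layer sphere validation fixture
#'
#' Scalp/skull/brain conductivities from the property table at DC, with the
#' head phantom's outer layer radii (scalp 92, skull 85, brain 78 mm) so the
#' gate exercises the same thin resistive shell the production phantom has;
#' opposed 20 degree polar caps inject 1 mA. The staircase-boundary error is
#' first order in the spacing, so the relative L2 error over the inner
#' sphere decreases when the spacing is halved.
#'
#' @param spacing Voxel edge, mm.
#' @param L Legendre truncation order.
#' @param radii Interface radii, mm (outer first).
#' @param subvoxel Split face links at the exact interface radii (series
#'   conductance of the two segments) instead of whole-voxel harmonic
#'   means. Removes the oscillating shell-quantization bias of
#'   nearest-center labeling so refinement converges monotonically;
#'   default on (the geometry is known analytically for this fixture).
#' @return List: `rel_l2` (relative L2 potential error over the inner
#'   sphere, numerical vs series), `n` (number of unknowns), `sol`,
#'   `truncation`.
#' @export
validate_sphere_fixture <- function(spacing = 2, L = 60L,
                                    radii = c(92, 85, 78),
                                    subvoxel = TRUE) {
  labels <- c("scalp", "skull", "gray_matter")
  alpha_deg <- 20
  I_tot <- 1e-3
  props <- tissue_table()
  freq <- frequency_spec(0)
  kap <- admittivity(props, labels, freq)
  ph <- build_layered_sphere_phantom(radii, labels, spacing = spacing)
  if (subvoxel) {
    ph$link_model <- list(radii_mm = radii, kappa = kap)
  }
  cfg <- solver_config(freq = freq, mode = "iterative", rel_tol = 1e-8)
  sys <- assemble_system(ph, props, cfg,
                         excitation = list(type = "caps", axis = 3L,
                                           half_angle_deg = alpha_deg,
                                           current_A = I_tot))
  sol <- solve_potential(sys, cfg)
  sph <- layered_sphere(radii, kap, cap_half_angle_deg = alpha_deg,
                        current_A = I_tot, L = L, axis = 3L)
  co <- phantom_coords(ph)
  sub <- arrayInd(sys$dom_lin, sys$dims)
  pts <- cbind(co$x[sub[, 1]], co$y[sub[, 2]], co$z[sub[, 3]])
  inner <- sqrt(rowSums(pts^2)) < radii[3]
  ser <- layered_sphere_solution(sph, pts[inner, , drop = FALSE])
  num <- Re(sol$phi[inner]); ana <- Re(ser$phi)
  num <- num - mean(num); ana <- ana - mean(ana)
  rel_l2 <- sqrt(sum((num - ana)^2)) / sqrt(sum(ana^2))
  list(rel_l2 = rel_l2, n = sys$n, sol = sol, truncation = ser$truncation)
}
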