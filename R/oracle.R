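## Closed-form reference solutions used as ground truth for the numerical
## solver: a 1-D layered slab (series impedance) and an N-layer concentric
## sphere driven by opposed polar-cap current injection (Legendre series).

#' Layered slab description
#'
#' @param thickness_m Layer thicknesses in meters (stack order).
#' @param kappa Complex admittivities, S/m (same length).
#' @param voltage Voltage across the stack, V.
#' @param area Cross-section area, m^2.
#' @return A list with class `slab_stack`.
#' @export
slab_stack <- function(thickness_m, kappa, voltage = 80, area = 1) {
  stopifnot(length(thickness_m) >= 1, length(kappa) == length(thickness_m),
            all(thickness_m > 0), area > 0)
  structure(list(thickness_m = thickness_m, kappa = as.complex(kappa),
                 voltage = voltage, area = area),
            class = "slab_stack")
}

#' Series closed form for the layered slab
#'
#' Current density is uniform: `J = V / sum(d_i / kappa_i)`; per-layer
#' field `E_i = J / kappa_i` and heating `Q_i = 1/2 Re(J conj(E_i))`.
#' A zero-admittivity layer blocks the stack: fields are zero and the
#' impedance is reported as infinite.
#'
#' @param stack A `slab_stack`.
#' @return A list: per-layer data.frame (`E_V_m`, `Q_W_m3` + complex
#'   columns `E`, `J`), `J` (A/m^2), `z_specific` (Ohm m^2), complex
#'   `power_W` across the stack.
#' @export
slab_solution <- function(stack) {
  stopifnot(inherits(stack, "slab_stack"))
  if (any(Mod(stack$kappa) == 0)) {
    layers <- data.frame(thickness_m = stack$thickness_m,
                         E_V_m = 0, Q_W_m3 = 0)
    layers$E <- 0 + 0i; layers$J <- 0 + 0i
    return(list(layers = layers, J = 0 + 0i, z_specific = Inf,
                power_W = 0 + 0i))
  }
  z <- sum(stack$thickness_m / stack$kappa)   # specific impedance, Ohm m^2
  J <- stack$voltage / z
  E <- J / stack$kappa
  Q <- 0.5 * Re(J * Conj(E))
  layers <- data.frame(thickness_m = stack$thickness_m,
                       E_V_m = Mod(E), Q_W_m3 = Q)
  layers$E <- E; layers$J <- rep(J, length(E))
  list(layers = layers, J = J, z_specific = z,
       power_W = 0.5 * stack$voltage * Conj(J) * stack$area)
}

#' Concentric layered sphere description
#'
#' @param radii_mm Interface radii in mm, strictly decreasing (outer
#'   surface first); one entry per layer.
#' @param kappa Complex admittivities per layer, outermost first.
#' @param cap_half_angle_deg Half-angle of the polar source caps, degrees.
#' @param current_A Total current injected at the north cap and withdrawn
#'   at the south cap, amperes.
#' @param L Legendre truncation order.
#' @param axis Cap axis (1, 2 or 3).
#' @return A list with class `layered_sphere`.
#' @export
layered_sphere <- function(radii_mm, kappa, cap_half_angle_deg = 10,
                           current_A = 1e-3, L = 60L, axis = 3L) {
  stopifnot(length(radii_mm) == length(kappa), length(radii_mm) >= 1,
            all(diff(radii_mm) < 0), L >= 1, cap_half_angle_deg > 0,
            cap_half_angle_deg < 90)
  structure(list(radii_mm = radii_mm, kappa = as.complex(kappa),
                 alpha = cap_half_angle_deg * pi / 180,
                 current_A = current_A, L = as.integer(L),
                 axis = as.integer(axis)),
            class = "layered_sphere")
}

## Legendre polynomials P_0..P_L at x: matrix length(x) x (L+1)
legendre_table <- function(L, x) {
  P <- matrix(0, length(x), L + 1L)
  P[, 1] <- 1
  if (L >= 1) P[, 2] <- x
  if (L >= 2) for (l in 1:(L - 1)) {
    P[, l + 2] <- ((2 * l + 1) * x * P[, l + 1] - l * P[, l]) / (l + 1)
  }
  P
}

## radial coefficients (a_k, b_k) per layer and degree l, scaled to the
## cap boundary condition; returns list(a, b) matrices (layers x L) plus f_l
sphere_coefficients <- function(sph) {
  R_out <- max(sph$radii_mm) * 1e-3
  rho_if <- rev(sph$radii_mm) * 1e-3 / R_out   # increasing, last = 1
  kap <- rev(sph$kappa)                        # innermost first
  nlay <- length(kap)
  L <- sph$L
  c0 <- cos(sph$alpha)
  j0 <- sph$current_A / (2 * pi * R_out^2 * (1 - c0))
  Pc <- legendre_table(L + 1L, c0)[1, ]
  a <- matrix(0 + 0i, nlay, L); b <- matrix(0 + 0i, nlay, L)
  f <- complex(L)
  for (l in seq_len(L)) {
    if (l %% 2 == 0) next                      # even modes vanish by symmetry
    f[l] <- j0 * (Pc[l] - Pc[l + 2])           # P_{l-1}(c) - P_{l+1}(c)
    ak <- 1 + 0i; bk <- 0 + 0i
    av <- complex(nlay); bv <- complex(nlay)
    av[1] <- ak
    if (nlay > 1) for (k in 1:(nlay - 1)) {
      rho <- rho_if[k]
      u <- ak * rho^l + bk * rho^(-l - 1)
      w <- kap[k] * (l * ak * rho^l - (l + 1) * bk * rho^(-l - 1))
      X <- ((l + 1) * u + w / kap[k + 1]) / (2 * l + 1)
      Yv <- u - X
      ak <- X * rho^(-l); bk <- Yv * rho^(l + 1)
      av[k + 1] <- ak; bv[k + 1] <- bk
    }
    dphi <- (l * ak - (l + 1) * bk) / R_out    # d/dr at rho = 1
    denom <- kap[nlay] * dphi
    if (Mod(denom) == 0) stop("degenerate sphere mode l = ", l)
    scale <- f[l] / denom
    a[, l] <- av * scale; b[, l] <- bv * scale
  }
  list(a = a, b = b, f = f, rho_if = rho_if, R_out = R_out, kap = kap)
}

#' Series solution of the layered sphere
#'
#' Potential of the concentric-sphere volume conductor driven by uniform
#' current density over two opposed polar caps (current `+I` at the north
#' cap, `-I` at the south). Per-degree radial coefficients are matched by
#' continuity of potential and normal current at every interface; by the
#' odd symmetry of the source only odd Legendre degrees contribute and the
#' potential has zero mean.
#'
#' @param sph A `layered_sphere`.
#' @param eval_points Matrix (n x 3) of physical coordinates in mm,
#'   relative to the sphere center; must lie inside the outer radius.
#' @return A list: `phi` (complex potential, V), `truncation`
#'   (max over points of the magnitude of the last retained term).
#' @export
layered_sphere_solution <- function(sph, eval_points) {
  stopifnot(inherits(sph, "layered_sphere"))
  pts <- as.matrix(eval_points)
  stopifnot(ncol(pts) == 3)
  co <- sphere_coefficients(sph)
  R_out <- co$R_out
  r <- sqrt(rowSums(pts^2)) * 1e-3
  if (any(r > R_out * (1 + 1e-9))) {
    stop("evaluation point(s) outside the outer radius")
  }
  rho <- pmin(r / R_out, 1)
  ct <- ifelse(r > 0, pts[, sph$axis] * 1e-3 / pmax(r, .Machine$double.eps), 0)
  ct <- pmin(pmax(ct, -1), 1)
  layer <- findInterval(rho, co$rho_if, left.open = TRUE) + 1L
  layer <- pmin(layer, length(co$kap))
  L <- sph$L
  P <- legendre_table(L, ct)
  phi <- complex(length(r))
  last <- numeric(length(r))
  for (l in seq_len(L)) {
    if (l %% 2 == 0) next
    rad <- co$a[cbind(layer, l)] * rho^l
    bl <- co$b[cbind(layer, l)]
    nz <- which(rho > 0 & Mod(bl) > 0)
    rad[nz] <- rad[nz] + bl[nz] * rho[nz]^(-l - 1)
    term <- rad * P[, l + 1]
    phi <- phi + term
    last <- Mod(term)
  }
  list(phi = phi, truncation = max(last))
}

#' Build a bare layered-sphere voxel phantom
#'
#' Voxelizes a concentric sphere (no tumor, no arrays) for cross-validation
#' of the numerical solver against [layered_sphere_solution()]. Layers are
#' labeled with arbitrary tissue names so their admittivities come from the
#' property table.
#'
#' @param radii_mm Decreasing interface radii, mm (outer first).
#' @param labels Tissue label per layer (outermost first).
#' @param spacing Voxel edge, mm.
#' @return A `voxel_phantom`.
#' @export
build_layered_sphere_phantom <- function(radii_mm, labels, spacing = 2) {
  stopifnot(length(radii_mm) == length(labels), all(diff(radii_mm) < 0))
  h <- spacing
  n <- as.integer(2L * ceiling((max(radii_mm) + h) / h) + 1L)
  x <- grid_coords(n, h)
  r2 <- outer(outer(x^2, x^2, `+`), x^2, `+`)
  lab <- array(0L, dim = c(n, n, n))
  for (k in seq_along(radii_mm)) {
    lab[r2 <= radii_mm[k]^2] <- label_code(labels[k])
  }
  structure(
    list(labels = lab, spacing = h, origin = rep(x[1], 3),
         defect_mask = NULL, tid = NULL, arrays = NULL,
         insulation = rep(FALSE, 18L), cfg = NULL),
    class = "voxel_phantom"
  )
}
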