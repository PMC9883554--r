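## Linear solve and field reconstruction.

#' Solve the assembled system for the complex potential
#'
#' Direct mode factorizes the real-split form of the complex-symmetric
#' system with a sparse LU (exact up to round-off); iterative mode runs
#' preconditioned conjugate-orthogonal CG to the configured relative
#' residual. Pure-Neumann systems (cap current injection) are defined up to
#' an additive constant, which is removed by subtracting the mean.
#'
#' @param sys An `fv_system` from [assemble_system()].
#' @param cfg A `solver_config`.
#' @return A `field_solution` with the potential only; pass to
#'   [electric_field()] to add E, J and the Joule heating inputs.
#' @export
solve_potential <- function(sys, cfg = solver_config()) {
  stopifnot(inherits(sys, "fv_system"))
  mode <- cfg$mode
  if (mode == "auto") {
    mode <- if (sys$n <= cfg$direct_max) "direct" else "iterative"
  }
  if (mode == "direct") {
    phi <- solve_direct(sys)
    res <- relative_residual(sys, phi)
    iters <- NA_integer_
    if (!is.finite(res) || res > 1e-6) {
      stop(sprintf("direct solve failed: relative residual %.3g", res))
    }
  } else {
    out <- .fv_cocg(sys$nbr, sys$offd, sys$diag, sys$rhs,
                    cfg$rel_tol, cfg$max_iter,
                    as.integer(cfg$precond == "ssor"))
    if (!out$converged && out$residual > cfg$rel_tol) {
      stop(sprintf(
        "iterative solver did not converge: residual %.3g after %d iterations",
        out$residual, out$iterations))
    }
    phi <- out$x
    res <- out$residual
    iters <- out$iterations
  }
  if (sys$pure_neumann) phi <- phi - mean(phi)
  structure(
    list(phi = phi, residual = res, iterations = iters, sys = sys,
         E = NULL, J = NULL, emag = NULL),
    class = "field_solution"
  )
}

## sparse LU on the 2n x 2n real-split system [Re -Im; Im Re]
solve_direct <- function(sys) {
  n <- sys$n
  ii <- seq_len(n); jj <- ii; vv <- sys$diag
  for (c in 1:6) {
    sel <- which(sys$nbr[, c] > 0L)
    ii <- c(ii, sel)
    jj <- c(jj, sys$nbr[sel, c])
    vv <- c(vv, -sys$offd[sel, c])
  }
  Ar <- Re(vv); Ai <- Im(vv)
  I2 <- c(ii, ii, ii + n, ii + n)
  J2 <- c(jj, jj + n, jj, jj + n)
  V2 <- c(Ar, -Ai, Ai, Ar)
  keep <- V2 != 0
  M <- Matrix::sparseMatrix(i = I2[keep], j = J2[keep], x = V2[keep],
                            dims = c(2L * n, 2L * n))
  b <- c(Re(sys$rhs), Im(sys$rhs))
  x <- as.numeric(Matrix::solve(M, b))
  complex(real = x[seq_len(n)], imaginary = x[n + seq_len(n)])
}

#' Relative residual of a potential vector
#'
#' @param sys An `fv_system`.
#' @param phi Complex potential vector (length `sys$n`).
#' @return `||b - A phi|| / ||b||`.
#' @export
relative_residual <- function(sys, phi) {
  r <- sys$rhs - .fv_matvec(sys$nbr, sys$offd, sys$diag, phi)
  sqrt(sum(Mod(r)^2)) / sqrt(sum(Mod(sys$rhs)^2))
}

#' Reconstruct E, J and |E| from the solved potential
#'
#' The current density is built from the face fluxes of the finite-volume
#' solution (the per-cell value is the mean of the two face current
#' densities along each axis) and the electric field follows as
#' `E = J / kappa` per voxel. This flux-consistent reconstruction is exact
#' for layered 1-D profiles and keeps the discrete power balance: naive
#' central differencing of `phi` across a conductivity jump overshoots the
#' field on the low-conductivity side by up to the conductivity ratio,
#' which would break both. A `central` method is available for comparison.
#'
#' @param sol A `field_solution` from [solve_potential()].
#' @param method `"flux"` (default) or `"central"`.
#' @return The solution with `E` (n x 3 complex matrix, V/m), `J` (n x 3,
#'   A/m^2) and `emag` (phasor amplitude `sqrt(sum |E_c|^2)`, V/m) filled.
#' @export
electric_field <- function(sol, method = c("flux", "central")) {
  method <- match.arg(method)
  sys <- sol$sys
  phi <- sol$phi
  n <- sys$n
  h <- sys$h
  A <- h * h
  J <- matrix(0 + 0i, n, 3L)
  if (method == "flux") {
    for (ax in 1:3) {
      fminus <- complex(n); fplus <- complex(n)
      fc <- sys$faces[[ax]]
      jdens <- fc$G * (phi[fc$r1] - phi[fc$r2]) / A   # + direction
      fplus[fc$r1] <- jdens
      fminus[fc$r2] <- jdens
      bc <- rbind_boundary(sys, ax)
      if (!is.null(bc)) {
        jb <- bc$jdens_plus(phi, A)
        fplus[bc$rows_plus] <- jb$plus
        fminus[bc$rows_minus] <- jb$minus
      }
      J[, ax] <- (fminus + fplus) / 2
    }
    E <- J / sys$kappa
    zero <- Mod(sys$kappa) == 0
    if (any(zero)) E[zero, ] <- 0 + 0i
  } else {
    E <- central_gradient(sys, phi)
    J <- E * sys$kappa
  }
  sol$E <- E
  sol$J <- J
  sol$emag <- sqrt(rowSums(Mod(E)^2))
  sol
}

## boundary-face current densities along one axis (Dirichlet and Neumann)
rbind_boundary <- function(sys, ax) {
  rp <- integer(0); rm <- integer(0)
  dir_p <- NULL; dir_m <- NULL; neu_p <- NULL; neu_m <- NULL
  if (!is.null(sys$dirichlet)) {
    dd <- sys$dirichlet[sys$dirichlet$axis == ax, ]
    dir_p <- dd[dd$dir > 0, ]; dir_m <- dd[dd$dir < 0, ]
    rp <- c(rp, dir_p$row); rm <- c(rm, dir_m$row)
  }
  if (!is.null(sys$neumann)) {
    nn <- sys$neumann[sys$neumann$axis == ax, ]
    neu_p <- nn[nn$dir > 0, ]; neu_m <- nn[nn$dir < 0, ]
    rp <- c(rp, neu_p$row); rm <- c(rm, neu_m$row)
  }
  if (!length(rp) && !length(rm)) return(NULL)
  list(
    rows_plus = rp, rows_minus = rm,
    jdens_plus = function(phi, A) {
      plus <- complex(0); minus <- complex(0)
      if (!is.null(dir_p) && nrow(dir_p)) {
        plus <- c(plus, dir_p$G * (phi[dir_p$row] - dir_p$V) / A)
      }
      if (!is.null(neu_p) && nrow(neu_p)) {
        plus <- c(plus, -neu_p$I / A)   # current into cell through + face
      }
      if (!is.null(dir_m) && nrow(dir_m)) {
        minus <- c(minus, dir_m$G * (dir_m$V - phi[dir_m$row]) / A)
      }
      if (!is.null(neu_m) && nrow(neu_m)) {
        minus <- c(minus, neu_m$I / A)
      }
      list(plus = plus, minus = minus)
    }
  )
}

## central-difference gradient (one-sided at domain boundaries)
central_gradient <- function(sys, phi) {
  n <- sys$n
  h <- sys$h
  E <- matrix(0 + 0i, n, 3L)
  for (ax in 1:3) {
    up <- sys$nbr[, 2L * ax]; dn <- sys$nbr[, 2L * ax - 1L]
    phi_up <- phi; su <- up > 0L; phi_up[su] <- phi[up[su]]
    phi_dn <- phi; sd <- dn > 0L; phi_dn[sd] <- phi[dn[sd]]
    span <- (as.numeric(su) + as.numeric(sd)) * h
    grad <- (phi_up - phi_dn) / pmax(span, h)
    grad[span == 0] <- 0 + 0i
    E[, ax] <- -grad
  }
  E
}

#' Real power delivered through the excitation boundary
#'
#' For Dirichlet (electrode) faces the complex input power is
#' `S = 1/2 * sum V * conj(I_in)` with `I_in = G (V - phi)`; for
#' current-injection caps the face potential is reconstructed from the
#' half-cell impedance. Used by the power-balance validation against the
#' domain integral of the Joule heating.
#'
#' @param sol A `field_solution`.
#' @return Real input power in watts.
#' @export
input_power <- function(sol) {
  sys <- sol$sys
  phi <- sol$phi
  P <- 0
  if (!is.null(sys$dirichlet)) {
    dd <- sys$dirichlet
    Iin <- dd$G * (dd$V - phi[dd$row])
    P <- P + 0.5 * sum(Re(dd$V * Conj(Iin)))
  }
  if (!is.null(sys$neumann)) {
    nn <- sys$neumann
    ghalf <- 2 * sys$h * sys$kappa[nn$row]      # A * kappa / (h/2)
    phi_face <- phi[nn$row] + nn$I / ghalf
    P <- P + 0.5 * sum(Re(phi_face * Conj(nn$I)))
  }
  P
}

#' Expand a per-voxel quantity to a full grid volume
#'
#' @param sol A `field_solution`.
#' @param what `"phi"` (Re), `"emag"` (V/m), `"emag_vcm"` (V/cm) or `"Q"`
#'   (W/m^3; requires [electric_field()] first, Q computed on the fly).
#' @param fill Value outside the domain.
#' @return A 3-D array aligned with the phantom grid.
#' @export
as_volume <- function(sol, what = c("emag_vcm", "emag", "phi", "Q"),
                      fill = NA_real_) {
  what <- match.arg(what)
  sys <- sol$sys
  v <- switch(what,
    phi = Re(sol$phi),
    emag = sol$emag,
    emag_vcm = sol$emag / 100,
    Q = joule_heating(sol)$Q
  )
  if (is.null(v)) stop("run electric_field() first")
  out <- array(fill, sys$dims)
  out[sys$dom_lin] <- v
  out
}
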