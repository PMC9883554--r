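## Finite-volume assembly of the electro-quasistatic equation
##     div( kappa * grad(phi) ) = 0,   kappa = sigma + i*omega*eps0*eps_r
## on the voxel grid. Cell-centered 7-point stencil; the conductance of the
## face between two cells is the harmonic mean of their admittivities times
## face area over center distance (exact for layered 1-D interfaces).
## Boundary conditions: Dirichlet on the outermost electrode faces (applied
## voltage on the active array, 0 on the ground array), zero normal current
## on every other outer face, and optionally a contact-impedance thin film
## on flagged transducer-gel interfaces, whose surface admittance per area
## is Y = (sigma_f + i*omega*eps0*eps_r_f) / d_f.

#' Solver configuration
#'
#' @param applied_voltage Voltage on the active array, V (default 80).
#' @param freq A `frequency_spec` (default 200 kHz).
#' @param rel_tol Relative residual tolerance of the linear solve.
#' @param max_iter Iteration cap for the iterative solver.
#' @param mode `"auto"` (direct below `direct_max` unknowns, iterative
#'   above), `"direct"` (sparse LU on the real-split system) or
#'   `"iterative"` (preconditioned conjugate-orthogonal CG).
#' @param direct_max Unknown-count threshold for `"auto"`.
#' @param precond `"ssor"` or `"jacobi"` preconditioner for the iterative
#'   solver.
#' @return A list with class `solver_config`.
#' @export
solver_config <- function(applied_voltage = 80,
                          freq = frequency_spec(),
                          rel_tol = 1e-8,
                          max_iter = 50000L,
                          mode = c("auto", "direct", "iterative"),
                          direct_max = 30000L,
                          precond = c("ssor", "jacobi")) {
  mode <- match.arg(mode)
  precond <- match.arg(precond)
  stopifnot(applied_voltage > 0, rel_tol > 0, rel_tol < 1,
            inherits(freq, "frequency_spec"))
  structure(list(applied_voltage = applied_voltage, freq = freq,
                 rel_tol = rel_tol, max_iter = as.integer(max_iter),
                 mode = mode, direct_max = as.integer(direct_max),
                 precond = precond),
            class = "solver_config")
}

#' Contact-impedance thin film
#'
#' Describes the insulating layer deposited between a transducer and its
#' gel pad. Rather than meshing a film orders of magnitude thinner than a
#' voxel, the transducer-gel face conductance gets the film's surface
#' admittance `Y = (sigma + i*omega*eps0*eps_r)/thickness` in series.
#' Defaults: 1 um thick polyethylene-like dielectric, `eps_r = 2.2`,
#' negligible conductivity.
#'
#' @param thickness Film thickness in meters (> 0).
#' @param eps_r Relative permittivity.
#' @param sigma Film conductivity, S/m.
#' @return A list with class `contact_film`.
#' @export
contact_film <- function(thickness = 1e-6, eps_r = 2.2, sigma = 0) {
  stopifnot(thickness > 0, eps_r >= 1, sigma >= 0)
  structure(list(thickness = thickness, eps_r = eps_r, sigma = sigma),
            class = "contact_film")
}

## surface admittance per area (S/m^2) of a film at angular frequency omega
film_admittance <- function(film, freq) {
  (film$sigma + 1i * freq$omega * freq$eps0 * film$eps_r) / film$thickness
}

## neighbor label along axis `ax` in direction `dir` (+1/-1); 0 beyond edge
neighbor_value <- function(v, ax, dir, fill = 0L) {
  d <- dim(v)
  out <- array(fill, d)
  src <- lapply(d, seq_len); dst <- src
  if (dir > 0) { dst[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
  else         { dst[[ax]] <- 2:d[ax];       src[[ax]] <- 1:(d[ax] - 1) }
  do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(v), src)))))
}

## Series conductance of face links that cross a known spherical interface.
## ph$link_model = list(radii_mm = decreasing interface radii, kappa =
## admittivities outer-first). Links whose endpoints lie in adjacent radial
## bands are split at the exact interface radius; each segment contributes
## its own material in series. Removes the first-order oscillating
## shell-quantization bias of nearest-center labeling on analytic fixtures.
link_model_conductance <- function(ph, ax, f1, f2, k1, k2, G, h) {
  lm <- ph$link_model
  rinc <- rev(lm$radii_mm)                # increasing interface radii, mm
  kinc <- rev(as.complex(lm$kappa))       # kappa per band, innermost first
  d <- dim(ph$labels)
  co <- phantom_coords(ph)
  cv <- list(co$x, co$y, co$z)
  s1 <- arrayInd(f1, d); s2 <- arrayInd(f2, d)
  p1 <- cbind(cv[[1]][s1[, 1]], cv[[2]][s1[, 2]], cv[[3]][s1[, 3]])
  p2 <- cbind(cv[[1]][s2[, 1]], cv[[2]][s2[, 2]], cv[[3]][s2[, 3]])
  r1 <- sqrt(rowSums(p1^2)); r2 <- sqrt(rowSums(p2^2))
  b1 <- findInterval(r1, rinc, left.open = TRUE)
  b2 <- findInterval(r2, rinc, left.open = TRUE)
  fix <- which(abs(b1 - b2) == 1L & pmax(b1, b2) <= length(rinc))
  if (!length(fix)) return(G)
  hs <- ph$spacing                        # link length, mm
  Rstar <- rinc[pmax(b1, b2)[fix]]
  x1a <- p1[fix, ax]
  disc <- x1a^2 - r1[fix]^2 + Rstar^2
  disc[disc < 0] <- 0
  tp <- (-x1a + sqrt(disc)) / hs
  tm <- (-x1a - sqrt(disc)) / hs
  t <- ifelse(tp >= 0 & tp <= 1, tp, tm)
  ok <- t >= 0 & t <= 1 & is.finite(t)
  t <- pmin(pmax(t, 0.01), 0.99)
  kA <- kinc[b1[fix] + 1L]
  kB <- kinc[b2[fix] + 1L]
  A <- h * h                               # face area, m^2
  Gnew <- A / (t * h / kA + (1 - t) * h / kB)
  re_inv <- function(k) ifelse(Mod(k) > 0, Re(1 / k), 0)
  list(G = replace(G, fix[ok], Gnew[ok]),
       fixed = fix[ok],
       Rz1 = (t[ok] * h / A) * re_inv(kA[ok]),
       Rz2 = ((1 - t[ok]) * h / A) * re_inv(kB[ok]))
}

#' Assemble the finite-volume linear system
#'
#' @param ph A `voxel_phantom` (with arrays placed for the default
#'   excitation).
#' @param props A `tissue_table`.
#' @param cfg A `solver_config`.
#' @param film A `contact_film`, used on transducer-gel faces of
#'   transducers flagged in `ph$insulation`.
#' @param excitation Either `list(type = "arrays")` (Dirichlet on the
#'   outermost electrode faces: applied voltage on the active array, ground
#'   on the other), `list(type = "plate", axis =, v =)` (full-face plate
#'   electrodes on the two grid boundaries along `axis` - used by the slab
#'   validation fixtures), or `list(type = "caps", axis =, half_angle_deg =,
#'   current_A =)` (opposed polar-cap current injection on the outer
#'   surface - used by the layered-sphere validation fixtures; the system
#'   is then pure-Neumann and solved up to an additive constant).
#' @return An `fv_system`: stencil neighbor/conductance arrays, diagonal,
#'   right-hand side, index maps and boundary-face bookkeeping.
#' @export
assemble_system <- function(ph, props = tissue_table(),
                            cfg = solver_config(),
                            film = contact_film(),
                            excitation = list(type = "arrays")) {
  stopifnot(inherits(ph, "voxel_phantom"), inherits(cfg, "solver_config"))
  lab <- ph$labels
  d <- dim(lab)
  h <- ph$spacing * 1e-3          # voxel edge, meters
  A <- h * h                      # face area, m^2
  dom <- lab != 0L
  N <- sum(dom)
  if (N == 0L) stop("empty computational domain")
  idx <- array(0L, d)
  idx[dom] <- seq_len(N)
  kap_code <- kappa_by_code(props, cfg$freq)
  kapv <- kap_code[lab + 1L]      # complex vector over the full grid
  dim(kapv) <- NULL

  labv <- as.integer(lab); dim(labv) <- NULL
  idxv <- as.integer(idx); dim(idxv) <- NULL
  domv <- as.logical(dom); dim(domv) <- NULL
  tidv <- if (is.null(ph$tid)) integer(length(labv)) else as.integer(ph$tid)

  LI <- array(seq_len(prod(d)), d)
  nbr <- matrix(0L, N, 6L)     # columns: -x,+x,-y,+y,-z,+z
  offd <- matrix(0 + 0i, N, 6L)
  diag_ <- complex(N)
  rhs <- complex(N)
  faces <- vector("list", 3L)

  el_code <- label_code("electrode")
  gel_code <- label_code("hydrogel")
  Y <- film_admittance(film, cfg$freq)

  for (ax in 1:3) {
    lo <- lapply(d, seq_len); hi <- lo
    lo[[ax]] <- 1:(d[ax] - 1); hi[[ax]] <- 2:d[ax]
    l1 <- as.vector(do.call(`[`, c(list(LI), lo)))
    l2 <- as.vector(do.call(`[`, c(list(LI), hi)))
    m <- domv[l1] & domv[l2]
    f1 <- l1[m]; f2 <- l2[m]
    k1 <- kapv[f1]; k2 <- kapv[f2]
    G <- h * 2 * k1 * k2 / (k1 + k2)     # A/h * harmonic mean
    G[!is.finite(G)] <- 0 + 0i
    ## real part of each half-link impedance (Ohm), for the conservative
    ## Joule-heating attribution: Re(z) = (h/2A) * Re(1/kappa)
    re_inv <- function(k) ifelse(Mod(k) > 0, Re(1 / k), 0)
    Rz1 <- (h / (2 * A)) * re_inv(k1)
    Rz2 <- (h / (2 * A)) * re_inv(k2)
    Rf <- numeric(length(G))             # lossy-film share, usually 0
    if (!is.null(ph$link_model)) {
      ## sub-voxel interface placement for analytically known spherical
      ## geometry: split the cell-center link at the exact interface
      ## radius and use the series conductance of the two segments.
      lk <- link_model_conductance(ph, ax, f1, f2, k1, k2, G, h)
      G <- lk$G
      Rz1[lk$fixed] <- lk$Rz1
      Rz2[lk$fixed] <- lk$Rz2
    }
    ## contact-impedance film on flagged transducer-gel faces
    ins <- ((labv[f1] == el_code & labv[f2] == gel_code) |
            (labv[f1] == gel_code & labv[f2] == el_code)) &
           tidv[f1] == tidv[f2] & tidv[f1] > 0L
    if (any(ins)) {
      ins[ins] <- ph$insulation[tidv[f1[ins]]]
      if (any(ins)) {
        G[ins] <- A / (h / (2 * k1[ins]) + h / (2 * k2[ins]) + 1 / Y)
        Rf[ins] <- Re(1 / Y) / A
      }
    }
    r1 <- idxv[f1]; r2 <- idxv[f2]
    nbr[cbind(r1, 2L * ax)] <- r2
    nbr[cbind(r2, 2L * ax - 1L)] <- r1
    offd[cbind(r1, 2L * ax)] <- G
    offd[cbind(r2, 2L * ax - 1L)] <- G
    diag_[r1] <- diag_[r1] + G
    diag_[r2] <- diag_[r2] + G
    faces[[ax]] <- list(r1 = r1, r2 = r2, G = G, Rz1 = Rz1, Rz2 = Rz2,
                        Rf = Rf)
  }

  dirichlet <- NULL
  neumann <- NULL

  if (excitation$type == "arrays") {
    if (is.null(ph$arrays)) {
      stop("phantom has no arrays; run place_arrays() first")
    }
    ax <- ph$arrays$axis
    s_active <- ph$arrays$active_side
    rows <- integer(0); Gd <- complex(0); Vd <- numeric(0); dird <- integer(0)
    for (a_i in 1:2) {
      s <- if (a_i == 1L) s_active else -s_active
      V <- if (a_i == 1L) cfg$applied_voltage else 0
      tid_ok <- if (a_i == 1L) tidv >= 1L & tidv <= 9L else tidv >= 10L
      nb <- as.integer(neighbor_value(lab, ax, s, fill = 0L)); dim(nb) <- NULL
      sel <- which(labv == el_code & tid_ok & nb == 0L & domv)
      if (!length(sel)) stop("array ", a_i, " has no outer electrode face")
      g <- 2 * h * kapv[sel]                 # A * kappa / (h/2)
      rows <- c(rows, idxv[sel]); Gd <- c(Gd, g)
      Vd <- c(Vd, rep(V, length(sel))); dird <- c(dird, rep(s, length(sel)))
      diag_[idxv[sel]] <- diag_[idxv[sel]] + g
      rhs[idxv[sel]] <- rhs[idxv[sel]] + g * V
    }
    if (max(Mod(Gd)) == 0) {
      stop("no conductive or capacitive path at the electrodes ",
           "(kappa = 0 on electrode faces; DC with sigma = 0?)")
    }
    dirichlet <- data.frame(row = rows, axis = ax, dir = dird, V = Vd)
    dirichlet$G <- Gd
  } else if (excitation$type == "plate") {
    ax <- excitation$axis %||% 1L
    V <- excitation$v %||% cfg$applied_voltage
    lo <- lapply(d, seq_len); hi <- lo
    lo[[ax]] <- 1L; hi[[ax]] <- d[ax]
    sel0 <- as.vector(do.call(`[`, c(list(LI), lo)))
    sel1 <- as.vector(do.call(`[`, c(list(LI), hi)))
    sel0 <- sel0[domv[sel0]]; sel1 <- sel1[domv[sel1]]
    rows <- c(idxv[sel0], idxv[sel1])
    Gd <- 2 * h * c(kapv[sel0], kapv[sel1])
    Vd <- c(rep(0, length(sel0)), rep(V, length(sel1)))
    dird <- c(rep(-1L, length(sel0)), rep(1L, length(sel1)))
    diag_[rows] <- diag_[rows] + Gd
    rhs[rows] <- rhs[rows] + Gd * Vd
    dirichlet <- data.frame(row = rows, axis = ax, dir = dird, V = Vd)
    dirichlet$G <- Gd
  } else if (excitation$type == "caps") {
    ax <- excitation$axis %||% 3L
    alpha <- (excitation$half_angle_deg %||% 10) * pi / 180
    I_tot <- excitation$current_A %||% 1e-3
    co <- phantom_coords(ph)
    cvec <- list(co$x, co$y, co$z)
    rows <- integer(0); Iraw <- numeric(0); dird <- integer(0)
    axd <- integer(0)
    for (fx in 1:3) for (s in c(-1L, 1L)) {
      nb <- as.integer(neighbor_value(lab, fx, s, fill = 0L)); dim(nb) <- NULL
      sel <- which(domv & nb == 0L)
      if (!length(sel)) next
      sub <- arrayInd(sel, d)
      pos <- cbind(cvec[[1]][sub[, 1]], cvec[[2]][sub[, 2]],
                   cvec[[3]][sub[, 3]])
      pos[, fx] <- pos[, fx] + s * ph$spacing / 2   # face center, mm
      r <- sqrt(rowSums(pos^2))
      ct <- pos[, ax] / pmax(r, .Machine$double.eps)
      w <- abs(pos[, fx] / pmax(r, .Machine$double.eps))  # |n . rhat|
      ## antialiased cap edge: faces within one face-angle of the rim get
      ## a fractional share instead of all-or-nothing inclusion
      dtheta <- ph$spacing / pmax(r, ph$spacing)
      theta <- acos(pmin(pmax(ct, -1), 1))
      f_n <- pmin(pmax((alpha - theta) / dtheta + 0.5, 0), 1)
      f_s <- pmin(pmax((theta - (pi - alpha)) / dtheta + 0.5, 0), 1)
      frac <- f_n - f_s                      # signed: north +, south -
      keep <- frac != 0
      if (!any(keep)) next
      rows <- c(rows, idxv[sel[keep]])
      Iraw <- c(Iraw, frac[keep] * w[keep] * A)
      dird <- c(dird, rep(s, sum(keep)))
      axd <- c(axd, rep(fx, sum(keep)))
    }
    if (!length(rows)) stop("no boundary faces found inside the source caps")
    Ipos <- sum(Iraw[Iraw > 0]); Ineg <- -sum(Iraw[Iraw < 0])
    if (Ipos == 0 || Ineg == 0) stop("one-sided cap excitation")
    Ifc <- ifelse(Iraw > 0, Iraw * I_tot / Ipos, Iraw * I_tot / Ineg)
    ## a voxel may own several boundary faces (staircase corners):
    ## aggregate before adding, or duplicated indices drop current
    agg <- rowsum(Ifc, rows)
    rhs[as.integer(rownames(agg))] <-
      rhs[as.integer(rownames(agg))] + agg[, 1]
    neumann <- data.frame(row = rows, axis = axd, dir = dird, I = Ifc)
  } else {
    stop("unknown excitation type: ", excitation$type)
  }

  if (any(Mod(diag_) == 0)) {
    stop("electrically disconnected voxel(s): zero admittivity row ",
         "(sigma = 0 tissue at DC?)")
  }

  structure(
    list(nbr = nbr, offd = offd, diag = diag_, rhs = rhs,
         faces = faces, dirichlet = dirichlet, neumann = neumann,
         idx = idx, dims = d, spacing = ph$spacing, h = h,
         kappa = kapv[domv], labels_dom = labv[domv],
         tid_dom = tidv[domv],
         dom_lin = which(domv),
         n = N, excitation = excitation, freq = cfg$freq,
         pure_neumann = is.null(dirichlet)),
    class = "fv_system"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @method print fv_system
#' @export
print.fv_system <- function(x, ...) {
  cat(sprintf("<fv_system> %d unknowns on %s grid, %s excitation\n",
              x$n, paste(x$dims, collapse = "x"), x$excitation$type))
  invisible(x)
}
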