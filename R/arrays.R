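## Transducer array placement.
##
## Two opposed 3x3 arrays are voxelized onto the scalp: for every grid
## column (along the montage axis) falling inside a gel disc, hydrogel
## voxels are stacked on the outermost scalp voxel, and electrode voxels on
## top of the gel wherever the column also falls inside the (smaller)
## transducer disc. The discs therefore conform to the curved scalp
## surface. All transducers of an array are electrically one equipotential
## electrode (current is controlled at the array level).

#' Place the two opposed 3x3 transducer arrays
#'
#' @param ph A `voxel_phantom` (layered head already built).
#' @param montage `"LR"` or `"AP"`; defaults to the phantom config.
#' @param insulate Logical vector of length 18 (or 9, recycled to the
#'   active-side array only): transducers whose transducer-gel interface
#'   carries the insulating film. Used later by the solver through the
#'   contact-impedance boundary condition.
#' @return A list `list(phantom, arrays)`: the phantom with gel/electrode
#'   voxels and per-voxel transducer ids (`tid`, 1-9 active side, 10-18
#'   ground side) and an `array_spec` describing the geometry and roles.
#' @export
place_arrays <- function(ph, montage = ph$cfg$montage, insulate = NULL) {
  stopifnot(inherits(ph, "voxel_phantom"))
  arr <- ph$cfg$array
  h <- ph$spacing
  ngel <- max(1L, as.integer(round(arr$gel_thickness / h)))
  nel  <- max(1L, as.integer(round(arr$transducer_height / h)))
  if (is.null(insulate)) insulate <- rep(FALSE, 18L)
  if (length(insulate) == 9L) insulate <- c(insulate, rep(FALSE, 9L))
  stopifnot(length(insulate) == 18L, is.logical(insulate))

  ax <- montage_axis(montage)
  tang <- setdiff(1:3, ax)
  off <- expand.grid(t1 = c(-1, 0, 1) * arr$pitch,
                     t2 = c(-1, 0, 1) * arr$pitch)
  if (!is.null(arr$seed) && arr$jitter_sd > 0) {
    set.seed(arr$seed)
    off$t1 <- off$t1 + stats::rnorm(9, sd = arr$jitter_sd)
    off$t2 <- off$t2 + stats::rnorm(9, sd = arr$jitter_sd)
  }
  dmin <- min(stats::dist(off))
  if (dmin < 2 * arr$gel_radius) {
    stop(sprintf(
      "transducer gel discs overlap: min center distance %.1f mm < %.1f mm",
      dmin, 2 * arr$gel_radius))
  }

  co <- phantom_coords(ph)
  cvec <- list(co$x, co$y, co$z)
  d <- dim(ph$labels)
  lab <- ph$labels
  tid <- array(0L, dim = d)
  scalp_code <- label_code("scalp")
  gel_code <- label_code("hydrogel")
  el_code <- label_code("electrode")

  sides <- c(arr$active_side, -arr$active_side)
  centers <- vector("list", 18L)
  for (a_i in 1:2) {
    s <- sides[a_i]
    for (t_i in 1:9) {
      id <- (a_i - 1L) * 9L + t_i
      c1 <- off$t1[t_i]; c2 <- off$t2[t_i]
      ## grid columns within the gel disc (tangential plane)
      i1 <- which(abs(cvec[[tang[1]]] - c1) <= arr$gel_radius)
      i2 <- which(abs(cvec[[tang[2]]] - c2) <= arr$gel_radius)
      n_gel_vox <- 0L; n_el_vox <- 0L; ax_sum <- 0
      for (p in i1) for (q in i2) {
        dt2 <- (cvec[[tang[1]]][p] - c1)^2 + (cvec[[tang[2]]][q] - c2)^2
        if (dt2 > arr$gel_radius^2) next
        ## extract the column along the montage axis
        idx <- vector("list", 3L)
        idx[[tang[1]]] <- p; idx[[tang[2]]] <- q; idx[[ax]] <- seq_len(d[ax])
        col <- do.call(`[`, c(list(lab), idx))
        js <- which(col == scalp_code)
        if (!length(js)) next
        j0 <- if (s > 0) max(js) else min(js)
        put <- function(j, code) {
          if (j < 1L || j > d[ax]) stop("grid too small for array stack")
          if (col[j] != 0L) stop("array placement collides with tissue")
          idx[[ax]] <- j
          lab <<- do.call(`[<-`, c(list(lab), idx, list(code)))
          tid <<- do.call(`[<-`, c(list(tid), idx, list(id)))
        }
        for (k in seq_len(ngel)) put(j0 + s * k, gel_code)
        n_gel_vox <- n_gel_vox + ngel
        if (dt2 <= arr$transducer_radius^2) {
          for (k in seq_len(nel)) put(j0 + s * (ngel + k), el_code)
          n_el_vox <- n_el_vox + nel
          ax_sum <- ax_sum + cvec[[ax]][j0 + s * ngel]
        }
        col <- do.call(`[`, c(list(lab),
                              { idx[[ax]] <- seq_len(d[ax]); idx }))
      }
      if (n_gel_vox == 0L || n_el_vox == 0L) {
        stop(sprintf("transducer %d could not be placed on the scalp", id))
      }
      centers[[id]] <- data.frame(
        tid = id, array = a_i, side = s, t1 = c1, t2 = c2,
        role = if (a_i == 1L) "active" else "ground",
        n_gel_vox = n_gel_vox, n_electrode_vox = n_el_vox
      )
    }
  }

  spec <- structure(
    list(montage = montage, axis = ax,
         transducers = do.call(rbind, centers),
         pitch = arr$pitch,
         transducer_radius = arr$transducer_radius,
         transducer_height = nel * h,
         gel_radius = arr$gel_radius,
         gel_thickness = ngel * h,
         active_side = arr$active_side,
         insulation = insulate),
    class = "array_spec"
  )
  ph$labels <- lab
  ph$tid <- tid
  ph$arrays <- spec
  ph$insulation <- insulate
  list(phantom = ph, arrays = spec)
}

#' @method print array_spec
#' @export
print.array_spec <- function(x, ...) {
  cat(sprintf(
    "<array_spec> montage %s, 2 x 9 transducers (r=%g mm, gel r=%g mm), %d insulated\n",
    x$montage, x$transducer_radius, x$gel_radius, sum(x$insulation)))
  invisible(x)
}
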