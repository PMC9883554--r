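## Synthetic voxel head phantoms.
##
## The phantom is a 3-D integer label volume on an isotropic grid, emulating
## the structure of a segmented head MRI: nested scalp/skull/CSF/GM/WM
## compartments (idealized as concentric spheres), an embedded
## two-compartment tumor (low-conductivity enhancing shell around a
## high-conductivity necrotic core), an optional circular craniectomy window
## where skull is replaced by scalp tissue, and two opposed 3x3 transducer
## arrays coupled through hydrogel pads (see place_arrays()).
##
## Label codes: 0 = outside (excluded from the computational domain), then
## 1..10 in the order of TISSUE_LABELS (scalp, skull, gray_matter,
## white_matter, csf, tumor_shell, tumor_core, hydrogel, electrode, air).

label_code <- function(label) {
  i <- match(label, TISSUE_LABELS)
  if (anyNA(i)) stop("unknown tissue label(s): ",
                     paste(label[is.na(i)], collapse = ", "))
  i
}

code_label <- function(code) {
  out <- rep("outside", length(code))
  ok <- code >= 1L & code <= length(TISSUE_LABELS)
  out[ok] <- TISSUE_LABELS[code[ok]]
  out
}

#' Phantom configuration
#'
#' Collects the geometry of the synthetic head: outer radii of the five
#' nested tissue layers, grid spacing, tumor geometry, craniectomy window,
#' montage and transducer-array dimensions. Defaults give a human-scale
#' head (scalp outer radius 92 mm) with the array dimensions of the
#' clinical TTFields transducers (10 mm electrode radius, 1 mm height,
#' 12.5 mm gel radius, 1 mm gel thickness).
#'
#' @param radii Named numeric vector of strictly decreasing outer radii in
#'   mm: `scalp`, `skull`, `csf`, `gm`, `wm`.
#' @param spacing Isotropic voxel edge in mm (> 0).
#' @param tumor `NULL`, or `list(center, r_core, t_shell)` in mm; `center`
#'   is a 3-vector relative to the head center.
#' @param defect `NULL`, or `list(diameter, axis_center, side)`; the window
#'   is a cylinder along the montage axis. `axis_center` (tangential
#'   2-vector, mm) defaults to the tumor's tangential position; `side`
#'   (+1/-1) to the tumor's side of the head.
#' @param montage `"LR"` (left-right, x axis) or `"AP"`
#'   (anterior-posterior, y axis).
#' @param array List of transducer-array parameters: `pitch` (center-to-
#'   center spacing of the 3x3 grid, mm), `transducer_radius`,
#'   `transducer_height`, `gel_radius`, `gel_thickness` (mm),
#'   `active_side` (+1/-1), optional `jitter_sd` and `seed` for random
#'   tangential jitter of transducer centers.
#' @return A validated list with class `phantom_config`.
#' @export
phantom_config <- function(radii = c(scalp = 92, skull = 85, csf = 78,
                                     gm = 75, wm = 60),
                           spacing = 2,
                           tumor = NULL,
                           defect = NULL,
                           montage = c("LR", "AP"),
                           array = list()) {
  montage <- match.arg(montage)
  need <- c("scalp", "skull", "csf", "gm", "wm")
  if (!all(need %in% names(radii))) {
    stop("radii must be named: ", paste(need, collapse = ", "))
  }
  radii <- radii[need]
  if (any(diff(radii) >= 0)) {
    stop("layer radii must be strictly decreasing from scalp to wm")
  }
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    stop("spacing must be a single positive number (mm)")
  }
  arr <- utils::modifyList(
    list(pitch = 30, transducer_radius = 10, transducer_height = 1,
         gel_radius = 12.5, gel_thickness = 1, active_side = 1L,
         jitter_sd = 0, seed = NULL),
    array
  )
  if (!is.null(tumor)) {
    tumor <- utils::modifyList(
      list(center = c(55, 0, 0), r_core = 12, t_shell = 6), tumor)
    if (tumor$t_shell <= 0) stop("tumor shell thickness must be > 0")
    if (tumor$r_core < 0) stop("tumor core radius must be >= 0")
    reach <- sqrt(sum(tumor$center^2)) + tumor$r_core + tumor$t_shell
    if (reach > radii[["gm"]]) {
      stop("tumor extends outside the brain compartment (gm radius ",
           radii[["gm"]], " mm)")
    }
  }
  if (!is.null(defect)) {
    defect <- utils::modifyList(
      list(diameter = 50, axis_center = NULL, side = NULL), defect)
  }
  structure(list(radii = radii, spacing = spacing, tumor = tumor,
                 defect = defect, montage = montage, array = arr),
            class = "phantom_config")
}

montage_axis <- function(montage) if (montage == "LR") 1L else 2L

## voxel-center coordinates along each axis for a centered grid of size n
grid_coords <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

#' Build the layered head phantom
#'
#' Voxelizes the concentric tissue layers of the configuration onto an
#' isotropic grid centered on the head. A voxel takes the label of the
#' innermost layer whose outer radius its center lies within; voxels beyond
#' the scalp are labeled "outside" and excluded from the computational
#' domain. The grid is padded along all axes so that gel and electrode
#' layers can later be stacked on the scalp surface.
#'
#' @param cfg A `phantom_config`.
#' @return A `voxel_phantom`: list with `labels` (3-D integer array),
#'   `spacing` (mm), `origin` (mm coordinate of the center of voxel
#'   `[1,1,1]`), `defect_mask`, `tid` (per-voxel transducer id, 0 = none),
#'   `arrays` (an `array_spec` after `place_arrays()`), `insulation`
#'   (per-transducer logical, length 18) and the originating `cfg`.
#' @export
build_head_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  h <- cfg$spacing
  ngel <- max(1L, as.integer(round(cfg$array$gel_thickness / h)))
  nel  <- max(1L, as.integer(round(cfg$array$transducer_height / h)))
  pad  <- (ngel + nel + 2L) * h
  half <- cfg$radii[["scalp"]] + pad
  n <- as.integer(2L * ceiling(half / h) + 1L)
  x <- grid_coords(n, h)
  r2 <- outer(outer(x^2, x^2, `+`), x^2, `+`)  # squared distance to center
  lab <- array(0L, dim = c(n, n, n))
  ord <- c("scalp", "skull", "csf", "gm", "wm")
  codes <- c(label_code("scalp"), label_code("skull"), label_code("csf"),
             label_code("gray_matter"), label_code("white_matter"))
  for (k in seq_along(ord)) {
    lab[r2 <= cfg$radii[[ord[k]]]^2] <- codes[k]
  }
  ph <- structure(
    list(labels = lab, spacing = h,
         origin = rep(x[1], 3),
         defect_mask = NULL,
         tid = NULL,
         arrays = NULL,
         insulation = rep(FALSE, 18L),
         cfg = cfg),
    class = "voxel_phantom"
  )
  ph
}

#' @method print voxel_phantom
#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<voxel_phantom> %d x %d x %d @ %g mm, %d domain voxels\n",
              d[1], d[2], d[3], x$spacing, sum(x$labels != 0L)))
  tabs <- table(code_label(x$labels[x$labels != 0L]))
  print(tabs)
  invisible(x)
}

## physical voxel-center coordinate vectors of a phantom
phantom_coords <- function(ph) {
  d <- dim(ph$labels)
  list(x = ph$origin[1] + (seq_len(d[1]) - 1) * ph$spacing,
       y = ph$origin[2] + (seq_len(d[2]) - 1) * ph$spacing,
       z = ph$origin[3] + (seq_len(d[3]) - 1) * ph$spacing)
}

#' Embed a two-compartment tumor
#'
#' Relabels voxels within `r_core` of `center` as necrotic tumor core and
#' voxels with distance in `[r_core, r_core + t_shell)` as enhancing tumor
#' shell. Overlap with any brain tissue is resolved in favor of the tumor.
#' `r_core = 0` produces a shell-only lesion.
#'
#' @param ph A `voxel_phantom`.
#' @param center Tumor center, mm (3-vector relative to head center).
#' @param r_core Necrotic core radius, mm (>= 0).
#' @param t_shell Shell thickness, mm (> 0).
#' @return The modified phantom.
#' @export
embed_tumor <- function(ph, center, r_core, t_shell) {
  stopifnot(inherits(ph, "voxel_phantom"), length(center) == 3,
            r_core >= 0, t_shell > 0)
  reach <- sqrt(sum(center^2)) + r_core + t_shell
  if (reach > ph$cfg$radii[["gm"]]) {
    stop("tumor extends outside the brain compartment")
  }
  co <- phantom_coords(ph)
  d2 <- outer(outer((co$x - center[1])^2, (co$y - center[2])^2, `+`),
              (co$z - center[3])^2, `+`)
  shell <- d2 < (r_core + t_shell)^2
  core <- d2 < r_core^2
  ph$labels[shell] <- label_code("tumor_shell")
  ph$labels[core] <- label_code("tumor_core")
  ph
}

#' Open a craniectomy window in the skull
#'
#' Relabels skull voxels inside a cylindrical window (axis along the
#' montage axis, on one side of the head) as scalp, emulating a bone flap
#' removal where the defect refills with scalp tissue. The affected voxels
#' are recorded in `defect_mask`. A non-positive diameter is a no-op and
#' raises a warning.
#'
#' @param ph A `voxel_phantom`.
#' @param axis_center Tangential 2-vector (mm): where the cylinder axis
#'   crosses the plane orthogonal to the montage axis.
#' @param diameter Window diameter, mm.
#' @param side +1 or -1: which side of the head carries the window.
#' @param montage Montage defining the cylinder axis; defaults to the
#'   phantom configuration's montage.
#' @return The modified phantom with updated `defect_mask`.
#' @export
apply_skull_defect <- function(ph, axis_center = c(0, 0), diameter = 50,
                               side = 1L, montage = ph$cfg$montage) {
  stopifnot(inherits(ph, "voxel_phantom"))
  if (is.null(ph$defect_mask)) {
    ph$defect_mask <- array(FALSE, dim = dim(ph$labels))
  }
  if (diameter <= 0) {
    warning("skull defect diameter <= 0; phantom unchanged")
    return(ph)
  }
  ax <- montage_axis(montage)
  co <- phantom_coords(ph)
  tang <- setdiff(1:3, ax)
  cvec <- list(co$x, co$y, co$z)
  t1 <- cvec[[tang[1]]] - axis_center[1]
  t2 <- cvec[[tang[2]]] - axis_center[2]
  a <- cvec[[ax]]
  d <- dim(ph$labels)
  ## tangential squared distance to the window axis, per voxel
  dims <- c(1, 2, 3)
  arr_of <- function(v, along) {
    aperm(array(v, dim = d[c(along, setdiff(dims, along))]),
          order(c(along, setdiff(dims, along))))
  }
  t2d <- arr_of(t1, tang[1])^2 + arr_of(t2, tang[2])^2
  aarr <- arr_of(a, ax)
  win <- (t2d <= (diameter / 2)^2) & (sign(aarr) == sign(side)) &
    (ph$labels == label_code("skull"))
  ph$labels[win] <- label_code("scalp")
  ph$defect_mask <- ph$defect_mask | win
  ph
}

## logical mask of voxels whose face-neighbor along any axis is in `other`
face_adjacent <- function(mask, other) {
  d <- dim(mask)
  out <- array(FALSE, d)
  shift <- function(m, ax, by) {
    r <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by == 1) {
      idx_dst[[ax]] <- 2:d[ax];       idx_src[[ax]] <- 1:(d[ax] - 1)
    } else {
      idx_dst[[ax]] <- 1:(d[ax] - 1); idx_src[[ax]] <- 2:d[ax]
    }
    r <- do.call(`[<-`, c(list(r), idx_dst, list(do.call(`[`, c(list(m), idx_src)))))
    r
  }
  for (ax in 1:3) for (by in c(1, -1)) out <- out | shift(other, ax, by)
  out & mask
}

#' Check phantom structural invariants
#'
#' Verifies the topological structure the dose analysis assumes: labels are
#' drawn from the ten-class set plus outside; no white-matter voxel is
#' face-adjacent to scalp or skull; every tumor-core boundary voxel touches
#' tumor shell; defect voxels are scalp; every electrode voxel touches gel
#' and every gel pad touches scalp (once arrays are placed).
#'
#' @param ph A `voxel_phantom`.
#' @return `TRUE` invisibly; errors name the violated invariant.
#' @export
validate_phantom <- function(ph) {
  lab <- ph$labels
  if (!all(lab %in% 0:10)) stop("labels outside the ten-class set")
  wm <- lab == label_code("white_matter")
  hard <- lab == label_code("scalp") | lab == label_code("skull")
  if (any(face_adjacent(wm, hard))) {
    stop("white matter face-adjacent to scalp/skull: nesting violated")
  }
  core <- lab == label_code("tumor_core")
  if (any(core)) {
    notcore <- lab != label_code("tumor_core")
    boundary <- face_adjacent(core, notcore)
    shell <- lab == label_code("tumor_shell")
    bad <- boundary & !face_adjacent(core, shell)
    if (any(bad)) stop("tumor core boundary voxel not adjacent to shell")
  }
  if (!is.null(ph$defect_mask) && any(ph$defect_mask)) {
    if (!all(lab[ph$defect_mask] == label_code("scalp"))) {
      stop("defect voxel not labeled scalp")
    }
  }
  el <- lab == label_code("electrode")
  gel <- lab == label_code("hydrogel")
  if (any(el)) {
    if (!all(face_adjacent(el, gel | el)[el])) {
      stop("electrode voxel not adjacent to gel/electrode")
    }
  }
  if (any(gel)) {
    scalp <- lab == label_code("scalp")
    if (!any(face_adjacent(gel, scalp))) {
      stop("no gel voxel touches scalp")
    }
  }
  invisible(TRUE)
}
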