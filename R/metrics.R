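## Dose and thermogenesis metrics.
##
## Field magnitudes are computed internally in V/m and reported in V/cm
## (divide by 100), the unit of the therapeutic thresholds: 1.0 V/cm is the
## minimum field for inhibition of tumor-cell proliferation and 2.5 V/cm
## the level of maximal effect. Heating is the volumetric Joule power
## Q = 1/2 Re(J . E*) in W/m^3, the quantity the 41 degC scalp-temperature
## regulation responds to.

#' Joule heating map
#'
#' Volumetric heating power `Q = 1/2 Re(J . E*)` (W/m^3). Two estimators of
#' the same continuum quantity are provided:
#'
#' * `"conservative"` (default): each face's exact discrete dissipation
#'   `1/2 |I|^2 Re(1/G)` is attributed to the two adjacent half-links,
#'   `1/2 |I|^2 (h/2A) sigma_c/|kappa_c|^2` per cell `c` (any lossy-film
#'   share splits evenly between the cells). This reduces to
#'   `1/2 sigma |E|^2` in uniform regions and makes the domain integral of
#'   Q equal the electrode input power to solver precision, including
#'   across one-voxel-thin layers where pointwise reconstruction smears.
#' * `"pointwise"`: `1/2 Re(J . E*)` from the flux-reconstructed fields of
#'   [electric_field()]; satisfies the algebraic identity
#'   `1/2 sigma |E|^2` voxel by voxel.
#'
#' Both are nonnegative and vanish wherever the conductivity is zero.
#'
#' @param sol A solved `field_solution`.
#' @param method `"conservative"` or `"pointwise"`.
#' @return A list with class `heating_map`: `Q` (W/m^3, per domain voxel)
#'   and the `sys` it refers to.
#' @export
joule_heating <- function(sol, method = c("conservative", "pointwise")) {
  method <- match.arg(method)
  sys <- sol$sys
  if (method == "pointwise") {
    if (is.null(sol$E)) sol <- electric_field(sol)
    Q <- 0.5 * rowSums(Re(sol$J * Conj(sol$E)))
    Q[Q < 0 & Q > -1e-12 * max(Q)] <- 0   # clamp round-off
    return(structure(list(Q = Q, sys = sys, method = method),
                     class = "heating_map"))
  }
  phi <- sol$phi
  n <- sys$n
  h <- sys$h
  A <- h * h
  kap <- sys$kappa
  ## Re of the half-link impedance per cell: (h/2A) * Re(1/kappa)
  zr <- (h / (2 * A)) * Re(kap) / pmax(Mod(kap)^2, .Machine$double.xmin)
  P <- numeric(n)
  addto <- function(P, rows, val) {
    agg <- rowsum(val, rows)
    i <- as.integer(rownames(agg))
    P[i] <- P[i] + agg[, 1]
    P
  }
  for (ax in 1:3) {
    fc <- sys$faces[[ax]]
    I2 <- Mod(fc$G * (phi[fc$r1] - phi[fc$r2]))^2
    P <- addto(P, fc$r1, 0.5 * I2 * fc$Rz1)
    P <- addto(P, fc$r2, 0.5 * I2 * fc$Rz2)
    ## lossy-film share (zero for a purely dielectric film): split evenly
    lossy <- which(fc$Rf > 0)
    if (length(lossy)) {
      P <- addto(P, fc$r1[lossy], 0.25 * I2[lossy] * fc$Rf[lossy])
      P <- addto(P, fc$r2[lossy], 0.25 * I2[lossy] * fc$Rf[lossy])
    }
  }
  if (!is.null(sys$dirichlet)) {
    dd <- sys$dirichlet
    I2 <- Mod(dd$G * (dd$V - phi[dd$row]))^2
    P <- addto(P, dd$row, 0.5 * I2 * zr[dd$row])
  }
  if (!is.null(sys$neumann)) {
    nn <- sys$neumann
    P <- addto(P, nn$row, 0.5 * Mod(nn$I)^2 * zr[nn$row])
  }
  structure(list(Q = P / h^3, sys = sys, method = method),
            class = "heating_map")
}

#' Total dissipated power
#'
#' Domain integral of the Joule heating, `sum(Q) * voxel volume`, for
#' power-balance checks against [input_power()].
#'
#' @param qmap A `heating_map`.
#' @return Power in watts.
#' @export
dissipated_power <- function(qmap) {
  sum(qmap$Q) * qmap$sys$h^3
}

#' Per-gel-pad heating power statistics
#'
#' Summarizes the Joule heating over each of the 18 hydrogel pads:
#' pad-wise maximum and mean volumetric power and the integrated power
#' (sum of Q times voxel volume). The case-level `W_max` statistic is the
#' maximum over pads of the pad-wise maximum Q; ties resolve to the lowest
#' gel id.
#'
#' @param qmap A `heating_map` from [joule_heating()].
#' @param ph The `voxel_phantom` the solution was computed on.
#' @return A data.frame (class `gel_power_table`) with one row per gel pad:
#'   `gel`, `array`, `n_vox`, `max_Q_W_m3`, `mean_Q_W_m3`, `power_W`, and
#'   attributes `W_max` and `W_max_gel`.
#' @export
gel_power_stats <- function(qmap, ph) {
  sys <- qmap$sys
  gel_code <- label_code("hydrogel")
  isgel <- sys$labels_dom == gel_code
  if (!any(isgel)) stop("phantom has no hydrogel voxels")
  tid <- sys$tid_dom[isgel]
  Q <- qmap$Q[isgel]
  ids <- sort(unique(tid))
  vv <- sys$h^3
  tab <- data.frame(
    gel = ids,
    array = ifelse(ids <= 9L, 1L, 2L),
    n_vox = as.integer(tapply(Q, tid, length)[as.character(ids)]),
    max_Q_W_m3 = as.numeric(tapply(Q, tid, max)[as.character(ids)]),
    mean_Q_W_m3 = as.numeric(tapply(Q, tid, mean)[as.character(ids)]),
    power_W = as.numeric(tapply(Q, tid, sum)[as.character(ids)]) * vv
  )
  w_i <- which(tab$max_Q_W_m3 == max(tab$max_Q_W_m3))[1]  # lowest id tie-break
  attr(tab, "W_max") <- tab$max_Q_W_m3[w_i]
  attr(tab, "W_max_gel") <- tab$gel[w_i]
  class(tab) <- c("gel_power_table", "data.frame")
  tab
}

## domain-voxel mask for a tissue name; "brain" = GM + WM + CSF
tissue_mask <- function(sys, tissue) {
  if (tissue == "brain") {
    sys$labels_dom %in% label_code(c("gray_matter", "white_matter", "csf"))
  } else {
    sys$labels_dom == label_code(tissue)
  }
}

#' Per-tissue field-strength statistics
#'
#' Volume-weighted mean and maximum of |E| (phasor amplitude) over each
#' requested tissue mask, reported in V/cm. `"brain"` is the union of gray
#' matter, white matter and CSF.
#'
#' @param sol A `field_solution` with `emag` computed.
#' @param tissues Character vector of tissue names (or `"brain"`).
#' @return A data.frame: `tissue`, `n_vox`, `mean_vcm`, `max_vcm`.
#' @export
tissue_field_stats <- function(sol,
                               tissues = c("tumor_core", "tumor_shell",
                                           "brain")) {
  if (is.null(sol$emag)) sol <- electric_field(sol)
  sys <- sol$sys
  rows <- lapply(tissues, function(tt) {
    m <- tissue_mask(sys, tt)
    if (!any(m)) stop("empty tissue mask: ", tt)
    e <- sol$emag[m] / 100
    data.frame(tissue = tt, n_vox = sum(m),
               mean_vcm = mean(e), max_vcm = max(e))
  })
  do.call(rbind, rows)
}

#' Above-threshold volume of the tumor shell
#'
#' Percentage of the mask's voxels whose field magnitude meets or exceeds
#' the threshold (inclusive comparison). With uniform voxels this equals
#' the volume fraction.
#'
#' @param sol A `field_solution` with `emag` computed, or a numeric vector
#'   of field magnitudes in V/cm (then `mask` is ignored).
#' @param mask Logical mask over domain voxels (default: tumor shell).
#' @param threshold Threshold in V/cm (>= 0).
#' @return Percentage in `[0, 100]`.
#' @export
atv <- function(sol, mask = NULL, threshold = 1.0) {
  stopifnot(threshold >= 0)
  if (is.numeric(sol) && is.null(dim(sol))) {
    e <- sol
  } else {
    if (is.null(sol$emag)) sol <- electric_field(sol)
    if (is.null(mask)) mask <- tissue_mask(sol$sys, "tumor_shell")
    if (!any(mask)) stop("empty mask for atv()")
    e <- sol$emag[mask] / 100
  }
  if (!length(e)) stop("empty field-magnitude set for atv()")
  100 * sum(e >= threshold) / length(e)
}

#' Power-normalized field strength
#'
#' In clinical use the device lowers the voltage until the hottest
#' transducer sits at the 41 degC regulation point, so cases with
#' different maximum gel heating power are not directly comparable at
#' fixed voltage. The normalized field strength rescales the evaluated
#' case's mean tumor-shell field by `sqrt(W1 / W2)`:
#' `E_normalized = E2 * sqrt(W1 / W2)`, with `W1` the maximum per-gel
#' heating power of the intact-skull benchmark and `W2` that of the
#' evaluated case. When `E2` is expressed relative to the intact-case mean
#' (e.g. 1.491 for a 49.1 percent increase) the result is a fraction of
#' the intact baseline.
#'
#' @param E2 Mean tumor-shell field of the evaluated case (absolute or
#'   relative to the intact baseline).
#' @param W1 Maximum per-gel heating power of the intact case (> 0).
#' @param W2 Maximum per-gel heating power of the evaluated case (> 0).
#' @return `E2 * sqrt(W1 / W2)`, on the scale of `E2`.
#' @examples
#' normalized_field_strength(1.491, 7.26e5, 9.25e5) * 100  # 132.1 %
#' @export
normalized_field_strength <- function(E2, W1, W2) {
  if (!all(is.finite(c(E2, W1, W2)))) stop("non-finite inputs")
  if (any(W1 <= 0) || any(W2 <= 0)) {
    stop("heating powers W1 and W2 must be positive")
  }
  E2 * sqrt(W1 / W2)
}

#' Summarize one treatment case
#'
#' Bundles every per-case statistic: mean/max |E| for tumor core, tumor
#' shell and brain, the above-threshold volumes of the tumor shell, the
#' per-gel heating table and `W_max`.
#'
#' @param sol A solved `field_solution` (after [electric_field()]).
#' @param ph The phantom the solution was computed on.
#' @param case Case label (`"intact"`, `"defect"`, `"insulated"`).
#' @param thresholds ATV thresholds in V/cm.
#' @return A list with class `case_summary`.
#' @export
case_summary <- function(sol, ph, case = "intact",
                         thresholds = c(1.0, 2.5)) {
  if (is.null(sol$emag)) sol <- electric_field(sol)
  stats <- tissue_field_stats(sol)
  qmap <- joule_heating(sol)
  gel <- gel_power_stats(qmap, ph)
  shell <- tissue_mask(sol$sys, "tumor_shell")
  atvs <- vapply(thresholds, function(th) atv(sol, shell, th), numeric(1))
  names(atvs) <- sprintf("atv_%g", thresholds)
  structure(
    list(case = case,
         tissue_stats = stats,
         atv = atvs,
         gel = gel,
         W_max = attr(gel, "W_max"),
         W_max_gel = attr(gel, "W_max_gel"),
         mean_shell_vcm = stats$mean_vcm[stats$tissue == "tumor_shell"],
         residual = sol$residual,
         iterations = sol$iterations,
         n_voxels = sol$sys$n),
    class = "case_summary"
  )
}

#' @method print case_summary
#' @export
print.case_summary <- function(x, ...) {
  cat(sprintf("<case_summary> case=%s  W_max=%.3g W/m^3 (gel %d)\n",
              x$case, x$W_max, x$W_max_gel))
  print(x$tissue_stats, row.names = FALSE)
  cat("ATV (% of tumor shell):",
      paste(sprintf("%s=%.1f", names(x$atv), x$atv), collapse = "  "), "\n")
  invisible(x)
}
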