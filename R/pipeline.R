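## Three-case study orchestration: intact skull / defective skull /
## defective skull with insulating film, all on the same phantom
## configuration, summarized in a comparison table with the
## power-normalized field strength relative to the intact benchmark.

#' Study configuration
#'
#' @param phantom A `phantom_config` (must include a tumor; the defect and
#'   insulation cases need `defect` geometry).
#' @param solver A `solver_config`.
#' @param film A `contact_film` for the insulated case.
#' @param thresholds ATV thresholds, V/cm.
#' @param cases Subset of `c("intact", "defect", "insulated")`.
#' @param insulate_transducers Which active-side transducers (1-9) carry
#'   the film in the insulated case; default all nine.
#' @param seed Seed applied before phantom construction (only relevant when
#'   the config requests random array jitter).
#' @return A list with class `study_config`.
#' @export
study_config <- function(phantom = superficial_fixture_config(),
                         solver = solver_config(),
                         film = contact_film(),
                         thresholds = c(1.0, 2.5),
                         cases = c("intact", "defect", "insulated"),
                         insulate_transducers = 1:9,
                         seed = NULL) {
  stopifnot(inherits(phantom, "phantom_config"),
            inherits(solver, "solver_config"),
            inherits(film, "contact_film"),
            all(cases %in% c("intact", "defect", "insulated")))
  if (any(cases %in% c("defect", "insulated")) && is.null(phantom$defect)) {
    stop("defect/insulated cases require defect geometry in the phantom config")
  }
  if (is.null(phantom$tumor)) stop("study phantom must include a tumor")
  structure(list(phantom = phantom, solver = solver, film = film,
                 thresholds = thresholds, cases = cases,
                 insulate_transducers = insulate_transducers, seed = seed),
            class = "study_config")
}

#' Reference tumor fixtures
#'
#' Two shipped head configurations emulating the superficial
#' (frontal/temporal-like) versus deep (insular/brainstem-like) tumor
#' contrast: identical two-compartment tumors (12 mm core, 6 mm shell)
#' centered 55 mm (superficial) or 15 mm (deep) from the head center along
#' the montage axis, with a 50 mm craniectomy window centered over the
#' tumor projection on the array side.
#'
#' @param spacing Voxel edge, mm.
#' @param montage `"LR"` or `"AP"`.
#' @return A `phantom_config`.
#' @export
superficial_fixture_config <- function(spacing = 2, montage = "LR") {
  ctr <- c(55, 0, 0)
  if (montage == "AP") ctr <- c(0, 55, 0)
  phantom_config(spacing = spacing, montage = montage,
                 tumor = list(center = ctr, r_core = 12, t_shell = 6),
                 defect = list(diameter = 50))
}

#' @rdname superficial_fixture_config
#' @export
deep_fixture_config <- function(spacing = 2, montage = "LR") {
  ctr <- c(15, 0, 0)
  if (montage == "AP") ctr <- c(0, 15, 0)
  phantom_config(spacing = spacing, montage = montage,
                 tumor = list(center = ctr, r_core = 12, t_shell = 6),
                 defect = list(diameter = 50))
}

## build the phantom for one case; returns list(phantom, arrays)
build_case_phantom <- function(cfg, case) {
  ph_cfg <- cfg$phantom
  if (!is.null(cfg$seed)) {
    ph_cfg$array$seed <- ph_cfg$array$seed %||% cfg$seed
  }
  ph <- build_head_phantom(ph_cfg)
  tm <- ph_cfg$tumor
  ph <- embed_tumor(ph, tm$center, tm$r_core, tm$t_shell)
  ax <- montage_axis(ph_cfg$montage)
  tang <- setdiff(1:3, ax)
  side <- sign(tm$center[ax])
  if (side == 0) side <- 1
  if (case %in% c("defect", "insulated")) {
    df <- ph_cfg$defect
    ph <- apply_skull_defect(
      ph,
      axis_center = df$axis_center %||% tm$center[tang],
      diameter = df$diameter,
      side = df$side %||% side,
      montage = ph_cfg$montage
    )
  }
  insulate <- rep(FALSE, 18L)
  if (case == "insulated") insulate[cfg$insulate_transducers] <- TRUE
  ph_cfg$array$active_side <- side
  ph$cfg <- ph_cfg
  place_arrays(ph, montage = ph_cfg$montage, insulate = insulate)
}

#' Run one treatment case end to end
#'
#' Builds the phantom for the case (with/without the craniectomy window,
#' with/without the contact film), assembles and solves the
#' electro-quasistatic system, and computes all dose and heating metrics.
#' Deterministic for a fixed configuration.
#'
#' @param cfg A `study_config`.
#' @param case `"intact"`, `"defect"` or `"insulated"`.
#' @param props A `tissue_table`.
#' @param verbose Log one line per stage.
#' @return A `case_summary`; the solved `field_solution` is attached as
#'   attribute `"solution"` and the phantom as `"phantom"`.
#' @export
run_case <- function(cfg, case = c("intact", "defect", "insulated"),
                     props = tissue_table(), verbose = FALSE) {
  case <- match.arg(case)
  t0 <- proc.time()[3]
  pl <- build_case_phantom(cfg, case)
  ph <- pl$phantom
  say <- function(...) if (verbose) message(sprintf(...))
  say("[%s] phantom: %d domain voxels @ %g mm", case,
      sum(ph$labels != 0L), ph$spacing)
  sys <- assemble_system(ph, props, cfg$solver, cfg$film)
  say("[%s] system: %d unknowns", case, sys$n)
  sol <- solve_potential(sys, cfg$solver)
  say("[%s] solved: residual %.2e (%s iterations)", case, sol$residual,
      format(sol$iterations))
  sol <- electric_field(sol)
  cs <- case_summary(sol, ph, case = case, thresholds = cfg$thresholds)
  say("[%s] metrics done in %.1f s total", case, proc.time()[3] - t0)
  attr(cs, "solution") <- sol
  attr(cs, "phantom") <- ph
  cs
}

#' Compare the intact / defect / insulated cases
#'
#' Runs every requested case on the same configuration and computes the
#' power-normalized field strength per case relative to the intact-skull
#' benchmark: `E_norm = 100 * (E2 / E_intact) * sqrt(W1 / W2)` with `W1`
#' the intact case's maximum per-gel heating power and `W2` the evaluated
#' case's. The intact row is 100 percent by construction.
#'
#' @param cfg A `study_config` whose `cases` include `"intact"`.
#' @param props A `tissue_table`.
#' @param verbose Log per-stage progress.
#' @return A list with class `comparison_table`: `table` (one row per
#'   case: `W_max`, `mean_shell_vcm`, `E2_rel`, `E_norm_pct`, ATVs) and
#'   `summaries` (named list of `case_summary`).
#' @export
compare_cases <- function(cfg, props = tissue_table(), verbose = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  if (!"intact" %in% cfg$cases) {
    stop("comparison requires the intact benchmark case")
  }
  summaries <- lapply(cfg$cases, function(cs) {
    s <- run_case(cfg, cs, props = props, verbose = verbose)
    attr(s, "solution") <- NULL   # keep the comparison object lightweight
    attr(s, "phantom") <- NULL
    s
  })
  names(summaries) <- cfg$cases
  W1 <- summaries[["intact"]]$W_max
  E1 <- summaries[["intact"]]$mean_shell_vcm
  rows <- lapply(summaries, function(s) {
    E2_rel <- s$mean_shell_vcm / E1
    data.frame(case = s$case,
               W_max_W_m3 = s$W_max,
               mean_shell_vcm = s$mean_shell_vcm,
               E2_rel = E2_rel,
               E_norm_pct = 100 * normalized_field_strength(E2_rel, W1, s$W_max),
               t(s$atv),
               check.names = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, summaries = summaries, config = cfg),
            class = "comparison_table")
}

#' @method print comparison_table
#' @export
print.comparison_table <- function(x, ...) {
  tab <- x$table
  tab$W_max_W_m3 <- signif(tab$W_max_W_m3, 3)
  tab$mean_shell_vcm <- round(tab$mean_shell_vcm, 3)
  tab$E2_rel <- round(tab$E2_rel, 3)
  tab$E_norm_pct <- round(tab$E_norm_pct, 1)
  for (cn in grep("^atv_", names(tab))) tab[[cn]] <- round(tab[[cn]], 1)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Serialize a case summary or comparison table
#'
#' @param x A `case_summary` or `comparison_table`.
#' @param path Output path (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass_deep(x), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else if (grepl("\\.csv$", path)) {
    tab <- if (inherits(x, "comparison_table")) x$table
           else if (inherits(x, "gel_power_table")) as.data.frame(x)
           else if (inherits(x, "case_summary")) x$tissue_stats
           else as.data.frame(x)
    write.csv(tab, path, row.names = FALSE)
  } else {
    stop("unsupported output extension (use .json or .csv): ", path)
  }
  invisible(path)
}

## strip classes/attributes so jsonlite serializes plainly
unclass_deep <- function(x) {
  if (inherits(x, "study_config")) {
    x <- x[setdiff(names(x), character(0))]
  }
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, unclass_deep)
    attributes(x) <- list(names = names(x))
    x
  } else if (is.data.frame(x)) {
    cpx <- vapply(x, is.complex, logical(1))
    for (cn in names(x)[cpx]) x[[cn]] <- Mod(x[[cn]])
    as.data.frame(x)
  } else if (is.complex(x)) {
    Mod(x)
  } else {
    x
  }
}

#' Serialize / load a phantom configuration as JSON
#'
#' @param cfg A `phantom_config`.
#' @param path JSON path.
#' @return `read_phantom_config()` returns a `phantom_config`.
#' @export
write_phantom_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$radii <- as.list(x$radii)   # keep layer names in the JSON object
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  phantom_config(radii = unlist(x$radii), spacing = x$spacing,
                 tumor = x$tumor, defect = x$defect,
                 montage = x$montage, array = as.list(x$array %||% list()))
}
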