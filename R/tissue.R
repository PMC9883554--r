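## Electrical tissue properties and complex admittivity.
##
## The ten-class default table lists low-frequency conductivity sigma (S/m)
## and relative permittivity eps_r for every tissue the phantom can contain.
## At the working frequency f the material coefficient of the quasi-static
## volume-conductor equation is the complex admittivity
##     kappa = sigma + i * omega * eps0 * eps_r   (S/m),  omega = 2*pi*f.

TISSUE_LABELS <- c(
  "scalp", "skull", "gray_matter", "white_matter", "csf",
  "tumor_shell", "tumor_core", "hydrogel", "electrode", "air"
)

#' Default tissue property table
#'
#' Reads the packaged per-tissue electrical properties (conductivity
#' `sigma_S_per_m` and relative permittivity `eps_r`) for the ten tissue
#' classes used by the head phantom: scalp, skull, gray/white matter, CSF,
#' tumor shell (enhancing rim), tumor core (necrosis), hydrogel, electrode
#' and air. The electrode is a purely capacitive dielectric
#' (`sigma = 0`, `eps_r = 16000`): current enters it by displacement, which
#' matches driving the array from a voltage applied on its outer face.
#'
#' @param path Optional path to a user CSV with columns
#'   `label`, `sigma_S_per_m`, `eps_r` overriding the packaged defaults.
#' @return A `data.frame` with class `tissue_table`, one row per tissue.
#' @examples
#' tab <- tissue_table()
#' tab[tab$label == "skull", ]
#' @export
tissue_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tissue_properties.csv",
                        package = "ttfieldsim", mustWork = TRUE)
  }
  tab <- read.csv(path, stringsAsFactors = FALSE)
  validate_tissue_table(tab)
  class(tab) <- c("tissue_table", "data.frame")
  tab
}

#' Validate a tissue property table
#'
#' Checks the structural invariants every property table must satisfy:
#' the three required columns, `sigma >= 0`, `eps_r >= 1`, and no duplicate
#' labels. Called on every table the package reads.
#'
#' @param tab A data frame of tissue properties.
#' @return The table, invisibly; errors describe the first violation.
#' @export
validate_tissue_table <- function(tab) {
  need <- c("label", "sigma_S_per_m", "eps_r")
  if (!all(need %in% names(tab))) {
    stop("tissue table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$label)) {
    stop("duplicate tissue label(s): ",
         paste(unique(tab$label[duplicated(tab$label)]), collapse = ", "))
  }
  if (any(!is.finite(tab$sigma_S_per_m)) || any(tab$sigma_S_per_m < 0)) {
    stop("sigma_S_per_m must be finite and >= 0 for every tissue")
  }
  if (any(!is.finite(tab$eps_r)) || any(tab$eps_r < 1)) {
    stop("eps_r must be finite and >= 1 for every tissue")
  }
  invisible(tab)
}

#' Write a tissue table to CSV
#'
#' @param tab A `tissue_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tissue_table <- function(tab, path) {
  validate_tissue_table(tab)
  write.csv(as.data.frame(tab)[, c("label", "sigma_S_per_m", "eps_r")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Working-frequency specification
#'
#' TTFields are delivered at 200 kHz; this object carries the frequency,
#' the angular frequency `omega = 2*pi*frequency` and the vacuum
#' permittivity so that all admittivity evaluations share one constant.
#' `frequency = 0` gives the DC (pure conduction, Laplace) limit used by the
#' analytic validation fixtures.
#'
#' @param frequency Frequency in Hz (default 200 kHz).
#' @return A list with class `frequency_spec`: `frequency`, `omega`, `eps0`.
#' @examples
#' frequency_spec()$omega / (2 * pi)
#' @export
frequency_spec <- function(frequency = 2e5) {
  stopifnot(is.numeric(frequency), length(frequency) == 1L,
            is.finite(frequency), frequency >= 0)
  structure(
    list(frequency = frequency, omega = 2 * pi * frequency, eps0 = EPS0),
    class = "frequency_spec"
  )
}

#' Complex admittivity of a tissue
#'
#' Evaluates `kappa = sigma + i * omega * eps0 * eps_r` (S/m), the
#' coefficient of the electro-quasistatic equation
#' `div(kappa * grad(phi)) = 0`, for one or more tissue labels.
#'
#' @param props A `tissue_table`.
#' @param label Character vector of tissue labels.
#' @param freq A `frequency_spec` (default: 200 kHz).
#' @return Complex vector of admittivities, named by label.
#' @examples
#' admittivity(tissue_table(), "skull")          # 0.0211 + 2.27e-3i
#' admittivity(tissue_table(), "air")            # purely imaginary
#' @export
admittivity <- function(props, label, freq = frequency_spec()) {
  stopifnot(inherits(freq, "frequency_spec"))
  i <- match(label, props$label)
  if (anyNA(i)) {
    stop("unknown tissue label(s): ",
         paste(label[is.na(i)], collapse = ", "))
  }
  kap <- complex(real = props$sigma_S_per_m[i],
                 imaginary = freq$omega * freq$eps0 * props$eps_r[i])
  names(kap) <- label
  kap
}

## Admittivity lookup vector indexed by phantom label code (internal).
## Code 0 ("outside") maps to kappa = 0 and is excluded from the domain.
kappa_by_code <- function(props, freq) {
  kap <- admittivity(props, TISSUE_LABELS, freq)
  c(0 + 0i, kap)   # position 1 <-> code 0
}
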