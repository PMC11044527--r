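#' Arcsinh display scaling for fluorescence intensities
#'
#' Cytometer fluorescence spans several decades and, after compensation,
#' can dip below zero; the inverse hyperbolic sine of `x / cofactor` is the
#' standard monotone map that is linear near zero and logarithmic for large
#' intensities, so that kernel-density estimation (and hence trough-based
#' gating) is well behaved on the scaled axis.
#'
#' @param x Numeric vector of raw intensities (negative values allowed).
#' @param cofactor Positive scalar controlling the width of the linear
#'   region; 150 is a common choice for conventional cytometer channels.
#' @return Numeric vector, `asinh(x / cofactor)`.
#' @examples
#' asinh_scale(0, 150)        # 0
#' asinh_scale(1500, 150)     # about 3.0
#' @seealso [inverse_asinh_scale()]
#' @export
asinh_scale <- function(x, cofactor = 150) {
  check_cofactor(cofactor)
  asinh(x / cofactor)
}

#' Inverse of the arcsinh display scaling
#'
#' @param y Numeric vector of scaled values.
#' @param cofactor Positive scalar; must match the forward transform.
#' @return Raw intensities, `sinh(y) * cofactor`.
#' @export
inverse_asinh_scale <- function(y, cofactor = 150) {
  check_cofactor(cofactor)
  sinh(y) * cofactor
}

check_cofactor <- function(cofactor) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L ||
      !is.finite(cofactor) || cofactor <= 0) {
    stop_cd26("cofactor must be a single positive finite number",
              class = "cd26_parameter_error")
  }
  invisible(cofactor)
}

#' Transform configuration
#'
#' Fixes how raw channel intensities are mapped to the scale on which all
#' gates are placed: fluorescence channels go through [asinh_scale()] with a
#' shared cofactor, scatter channels (FSC, SSC) stay linear.
#'
#' @param cofactor Positive arcsinh cofactor applied to every fluorescence
#'   marker (CD45, CD34, CD38, CD26, CD3).
#' @param scatter_passthrough If `TRUE` (default) FSC and SSC are used on
#'   their native linear scale.
#' @return An object of class `transform_config`.
#' @export
transform_config <- function(cofactor = 150, scatter_passthrough = TRUE) {
  check_cofactor(cofactor)
  structure(
    list(cofactor = cofactor,
         scatter_passthrough = isTRUE(scatter_passthrough)),
    class = "transform_config"
  )
}

SCATTER_MARKERS <- c("FSC", "SSC")
FLUOR_MARKERS <- c("CD45", "CD34", "CD38", "CD26", "CD3")
PANEL_MARKERS <- c(SCATTER_MARKERS, FLUOR_MARKERS)

#' Scale an event matrix onto the gating axis
#'
#' @param em An [event_matrix()].
#' @param panel Marker-to-column mapping from [resolve_panel()]; resolved
#'   from the channel metadata when `NULL`.
#' @param tcfg A [transform_config()].
#' @return Numeric matrix, one column per panel marker (named by marker),
#'   scatter linear and fluorescence arcsinh-scaled.
#' @export
scale_events <- function(em, panel = NULL, tcfg = transform_config()) {
  em <- validate_event_matrix(em)
  if (is.null(panel)) panel <- resolve_panel(em)
  stopifnot(inherits(tcfg, "transform_config"))
  out <- matrix(NA_real_, nrow = nrow(em$data), ncol = length(PANEL_MARKERS),
                dimnames = list(NULL, PANEL_MARKERS))
  for (m in PANEL_MARKERS) {
    x <- em$data[, panel[[m]]]
    if (m %in% SCATTER_MARKERS && tcfg$scatter_passthrough) {
      out[, m] <- x
    } else {
      out[, m] <- asinh_scale(x, tcfg$cofactor)
    }
  }
  out
}

#' @export
print.transform_config <- function(x, ...) {
  cat("Transform: arcsinh(x/", x$cofactor, ") for fluorescence, ",
      if (x$scatter_passthrough) "linear" else "arcsinh",
      " scatter\n", sep = "")
  invisible(x)
}
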