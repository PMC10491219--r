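#' Sigmoidal marker dynamics along latent differentiation time
#'
#' Marker expression along each lineage arm follows a four-parameter logistic
#' mean curve on the arcsinh scale,
#' `mu(t) = b + a / (1 + exp(-(t - t0) / s))`,
#' with baseline `b`, amplitude `a` (negative for downregulation), inflection
#' time `t0` and steepness `s > 0`. The curve is monotone in `t` for every
#' (marker, branch) pair. Measurement noise is Gaussian on the arcsinh scale
#' (so raw intensities are approximately log-normal), and a per-marker
#' zero-inflation probability models the non-detection floor typical of mass
#' cytometry.
#'
#' @param curves data.frame with columns `marker`, `branch`, `b`, `a`, `t0`,
#'   `s`: one logistic curve per marker per lineage arm (branch = leaf name
#'   of the arm in the `LineageSpec`).
#' @param noise data.frame with columns `marker`, `noise_sd`, `zero_p`.
#' @param classes named character vector mapping each marker to its class
#'   (`"surface"` or `"regulator"`); defaults to `"surface"` for all.
#'
#' @return An object of class `MarkerDynamics`.
#' @export
marker_dynamics <- function(curves, noise, classes = NULL) {
  curves <- as.data.frame(curves, stringsAsFactors = FALSE)
  noise <- as.data.frame(noise, stringsAsFactors = FALSE)
  stopifnot(all(c("marker", "branch", "b", "a", "t0", "s") %in% names(curves)),
            all(c("marker", "noise_sd", "zero_p") %in% names(noise)))
  if (any(curves$s <= 0)) stop("steepness s must be > 0")
  if (any(curves$t0 < 0 | curves$t0 > 1)) stop("inflection t0 must lie in [0, 1]")
  if (any(noise$zero_p < 0 | noise$zero_p > 1)) stop("zero_p must lie in [0, 1]")
  if (any(noise$noise_sd < 0)) stop("noise_sd must be >= 0")
  if (!setequal(unique(curves$marker), noise$marker)) {
    stop("curves and noise must cover the same markers")
  }
  markers <- unique(curves$marker)
  if (is.null(classes)) {
    classes <- stats::setNames(rep("surface", length(markers)), markers)
  }
  structure(list(curves = curves, noise = noise, classes = classes,
                 markers = markers),
            class = "MarkerDynamics")
}

#' @export
print.MarkerDynamics <- function(x, ...) {
  cat(sprintf("MarkerDynamics: %d markers x %d branches (logistic curves)\n",
              length(x$markers), length(unique(x$curves$branch))))
  invisible(x)
}

#' Evaluate the logistic mean curve
#'
#' @param dynamics a `MarkerDynamics`.
#' @param marker marker name.
#' @param branch branch (arm leaf) name.
#' @param t latent times.
#' @return numeric vector `mu(t)` on the arcsinh scale.
#' @export
marker_mean <- function(dynamics, marker, branch, t) {
  row <- dynamics$curves[dynamics$curves$marker == marker &
                         dynamics$curves$branch == branch, ]
  if (nrow(row) != 1L) stop("no curve for (", marker, ", ", branch, ")")
  row$b + row$a / (1 + exp(-(t - row$t0) / row$s))
}

# logistic mean for many events at once: par is the curves row for one
# (marker, branch); used internally by the simulator
logistic_mu <- function(b, a, t0, s, t) b + a / (1 + exp(-(t - t0) / s))

#' Default 30-channel panel dynamics for the built-in lineage
#'
#' Defines logistic expression programs over the three arms of the default
#' tree (erythroid arm ending in `Ery`; myeloid arms ending in `pDC` and
#' `McDP`) for 20 surface markers and 10 intracellular regulators. The
#' programs encode the hallmark behaviour of human HSPC differentiation:
#' CD34 falls along every arm while CD38 rises through the progenitor
#' compartment; the erythroid arm gains GATA2 then GATA1 with CD71/CD84/
#' CD235ab surface acquisition; the myeloid arms upregulate IRF8 around the
#' MDP branch point, with CEBPa/CD33/CD14 marking the monocyte/cDC arm and
#' TdT/CD123/CD303 the plasmacytoid-DC arm. Arms share identical curves
#' before their branch point (inflections are placed after the split), so
#' trunk populations are branch-agnostic.
#'
#' @param noise_sd Gaussian noise SD on the arcsinh scale (default 0.25);
#'   set 0 for noise-free simulations.
#' @param zero_p zero-inflation probability for surface markers (default
#'   0.05; regulators use `1.5 * zero_p`). Set 0 to disable.
#' @return a `MarkerDynamics` covering branches `Ery`, `pDC`, `McDP`.
#' @export
default_marker_dynamics <- function(noise_sd = 0.25, zero_p = 0.05) {
  # per-marker per-arm logistic parameters (b, a, t0, s); flat = a 0
  spec <- list(
    #            Ery                     pDC                     McDP
    CD45    = list(c(4.0,  0.0, 0.5, 0.05), c(4.0,  0.0, 0.5, 0.05), c(4.0,  0.0, 0.5, 0.05)),
    CD34    = list(c(2.6, -2.3, 0.72, 0.05), c(2.6, -2.3, 0.78, 0.05), c(2.6, -2.3, 0.78, 0.05)),
    CD38    = list(c(0.7,  2.1, 0.42, 0.06), c(0.7,  2.1, 0.45, 0.06), c(0.7,  2.1, 0.45, 0.06)),
    CD71    = list(c(0.3,  3.4, 0.55, 0.06), c(0.3,  0.0, 0.5, 0.05), c(0.3,  0.0, 0.5, 0.05)),
    CD84    = list(c(0.3,  2.0, 0.50, 0.05), c(0.3,  0.0, 0.5, 0.05), c(0.3,  0.0, 0.5, 0.05)),
    CD164   = list(c(0.5,  1.5, 0.30, 0.05), c(0.5,  0.0, 0.5, 0.05), c(0.5,  0.0, 0.5, 0.05)),
    CD235ab = list(c(0.2,  3.0, 0.86, 0.04), c(0.2,  0.0, 0.5, 0.05), c(0.2,  0.0, 0.5, 0.05)),
    CD41    = list(c(0.3,  0.9, 0.70, 0.05), c(0.3,  0.0, 0.5, 0.05), c(0.3,  0.0, 0.5, 0.05)),
    CD123   = list(c(0.4,  0.0, 0.5, 0.05), c(0.4,  2.5, 0.62, 0.05), c(0.4,  1.1, 0.62, 0.05)),
    CD133   = list(c(1.5, -1.2, 0.50, 0.06), c(1.5,  0.8, 0.35, 0.06), c(1.5,  0.8, 0.35, 0.06)),
    CD33    = list(c(0.4,  0.0, 0.5, 0.05), c(0.4,  0.9, 0.55, 0.05), c(0.4,  2.2, 0.55, 0.05)),
    HLADR   = list(c(0.8,  0.0, 0.5, 0.05), c(0.8,  2.0, 0.50, 0.06), c(0.8,  2.0, 0.50, 0.06)),
    CD90    = list(c(1.8, -1.5, 0.25, 0.05), c(1.8, -1.5, 0.25, 0.05), c(1.8, -1.5, 0.25, 0.05)),
    CD49f   = list(c(1.5, -1.2, 0.30, 0.05), c(1.5, -1.2, 0.30, 0.05), c(1.5, -1.2, 0.30, 0.05)),
    CD45RA  = list(c(0.4,  0.0, 0.5, 0.05), c(0.4,  1.8, 0.45, 0.06), c(0.4,  1.8, 0.45, 0.06)),
    CD10    = list(c(0.25, 0.0, 0.5, 0.05), c(0.25, 0.0, 0.5, 0.05), c(0.25, 0.0, 0.5, 0.05)),
    CD7     = list(c(0.25, 0.0, 0.5, 0.05), c(0.25, 0.0, 0.5, 0.05), c(0.25, 0.0, 0.5, 0.05)),
    CD11c   = list(c(0.3,  0.0, 0.5, 0.05), c(0.3,  0.0, 0.5, 0.05), c(0.3,  2.0, 0.78, 0.05)),
    CD14    = list(c(0.2,  0.0, 0.5, 0.05), c(0.2,  0.0, 0.5, 0.05), c(0.2,  2.5, 0.87, 0.04)),
    CD303   = list(c(0.2,  0.0, 0.5, 0.05), c(0.2,  2.5, 0.82, 0.04), c(0.2,  0.0, 0.5, 0.05)),
    GATA1   = list(c(0.2,  3.0, 0.50, 0.05), c(0.2,  0.0, 0.5, 0.05), c(0.2,  0.0, 0.5, 0.05)),
    GATA2   = list(c(0.3,  2.2, 0.35, 0.05), c(0.3,  0.0, 0.5, 0.05), c(0.3,  0.0, 0.5, 0.05)),
    PBX1    = list(c(1.2,  1.5, 0.28, 0.05), c(1.2, -0.9, 0.30, 0.05), c(1.2, -0.9, 0.30, 0.05)),
    RUNX1   = list(c(0.6,  1.8, 0.30, 0.05), c(0.6,  0.0, 0.5, 0.05), c(0.6,  1.2, 0.75, 0.05)),
    IRF8    = list(c(0.3,  0.0, 0.5, 0.05), c(0.3,  2.5, 0.60, 0.04), c(0.3,  2.5, 0.60, 0.04)),
    CEBPa   = list(c(0.3,  0.0, 0.5, 0.05), c(0.3,  0.8, 0.60, 0.05), c(0.3,  2.2, 0.60, 0.05)),
    TdT     = list(c(0.2,  0.0, 0.5, 0.05), c(0.2,  2.0, 0.76, 0.04), c(0.2,  0.0, 0.5, 0.05)),
    FOXP1   = list(c(0.5,  1.2, 0.30, 0.05), c(0.5,  0.0, 0.5, 0.05), c(0.5,  0.0, 0.5, 0.05)),
    BMI1    = list(c(1.5, -1.0, 0.30, 0.05), c(1.5, -1.0, 0.30, 0.05), c(1.5, -1.0, 0.30, 0.05)),
    MECOM   = list(c(0.3,  1.5, 0.65, 0.05), c(0.3,  0.0, 0.5, 0.05), c(0.3,  0.0, 0.5, 0.05))
  )
  arms <- c("Ery", "pDC", "McDP")
  curves <- do.call(rbind, lapply(names(spec), function(mk) {
    do.call(rbind, lapply(seq_along(arms), function(i) {
      p <- spec[[mk]][[i]]
      data.frame(marker = mk, branch = arms[i],
                 b = p[1], a = p[2], t0 = p[3], s = p[4],
                 stringsAsFactors = FALSE)
    }))
  }))
  regulators <- c("GATA1", "GATA2", "PBX1", "RUNX1", "IRF8", "CEBPa", "TdT",
                  "FOXP1", "BMI1", "MECOM")
  markers <- names(spec)
  noise <- data.frame(
    marker = markers,
    noise_sd = noise_sd,
    zero_p = ifelse(markers %in% regulators, pmin(1, 1.5 * zero_p), zero_p),
    stringsAsFactors = FALSE
  )
  classes <- stats::setNames(
    ifelse(markers %in% regulators, "regulator", "surface"), markers)
  marker_dynamics(curves, noise, classes)
}

#' Default panel definition with trajectory channel subsets
#'
#' One row per channel: marker class, whether the channel enters global
#' clustering, and whether it belongs to the erythroid / myeloid restricted
#' panels used by the arm-specific re-analyses (only the proteins expressed
#' by cells of that arm).
#'
#' @return data.frame with columns `channel`, `class`, `clustering`,
#'   `erythroid`, `myeloid`.
#' @export
default_panel <- function() {
  dyn <- default_marker_dynamics()
  ery <- c("CD34", "CD38", "CD71", "CD84", "CD164", "CD235ab", "CD41",
           "CD90", "CD49f", "CD45", "CD133", "GATA1", "GATA2", "PBX1",
           "RUNX1", "FOXP1", "BMI1", "MECOM")
  mye <- c("CD34", "CD38", "CD45RA", "CD123", "CD133", "CD33", "HLADR",
           "CD11c", "CD14", "CD303", "CD45", "CD90", "CD49f", "IRF8",
           "CEBPa", "TdT", "RUNX1", "PBX1", "BMI1")
  data.frame(channel = dyn$markers,
             class = unname(dyn$classes[dyn$markers]),
             clustering = TRUE,
             erythroid = dyn$markers %in% ery,
             myeloid = dyn$markers %in% mye,
             stringsAsFactors = FALSE)
}
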