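#' Descriptors of a within-plot grain-size distribution
#'
#' Summarises the individual grain projected areas harvested from one
#' micro-plot bulk by the four distribution descriptors used throughout the
#' package: the grain-size mean (GSM, mm2), the grain-size variance (GSV,
#' mm4, sample variance with the n-1 denominator), and the 5th and 95th
#' percentiles (P5, P95, mm2).  Percentiles use the linear-interpolation
#' convention (`stats::quantile` type 7).
#'
#' Projected area is a proxy for individual grain mass; within a plot the
#' variance captures the heterogeneity of the grain population coming from
#' different spikes (main vs secondary tillers) and grain positions.
#'
#' @param areas numeric vector of individual grain projected areas (mm2).
#' @param plot_id optional identifier used in error messages.
#' @return data.frame with one row: `gsm`, `gsv`, `p5`, `p95`, `n_grains`
#'   (plus `plot_id` when given).
#' @examples
#' grain_descriptors(rnorm(400, 17, 2.7))
#' @export
grain_descriptors <- function(areas, plot_id = NULL) {
  lab <- if (is.null(plot_id)) "" else paste0(" in plot '", plot_id, "'")
  areas <- as.numeric(areas)
  if (anyNA(areas)) stop("missing grain areas", lab)
  if (length(areas) < 2L)
    stop("insufficient sample", lab, ": need at least 2 grains, got ",
         length(areas))
  if (any(areas <= 0))
    stop("non-positive grain area", lab)
  q <- stats::quantile(areas, c(0.05, 0.95), names = FALSE, type = 7)
  out <- data.frame(gsm = mean(areas), gsv = stats::var(areas),
                    p5 = q[1], p95 = q[2], n_grains = length(areas))
  if (!is.null(plot_id)) out <- cbind(plot_id = plot_id, out)
  out
}

#' Per-plot grain-distribution metrics from a long grain table
#'
#' @param grains data.frame with columns `plot_id` and `area_mm2`.
#' @return data.frame with one row per plot (`plot_id`, `gsm`, `gsv`, `p5`,
#'   `p95`, `n_grains`).
#' @export
grain_metrics_table <- function(grains) {
  stopifnot(all(c("plot_id", "area_mm2") %in% names(grains)))
  parts <- split(grains$area_mm2, grains$plot_id)
  out <- do.call(rbind, lapply(names(parts), function(id)
    grain_descriptors(parts[[id]], plot_id = id)))
  rownames(out) <- NULL
  out$plot_id <- as.character(out$plot_id)
  out[match(unique(as.character(grains$plot_id)), out$plot_id), , drop = FALSE]
}

#' Express a dry grain mass on a notional moisture basis
#'
#' Field yields and thousand-kernel weights are conventionally reported at
#' 15% humidity; a mass measured after oven-drying is rescaled by
#' `dry_mass / (1 - moisture_target)`.
#'
#' @param dry_mass mass (g) at zero moisture.
#' @param moisture_target moisture fraction of the reporting basis.
#' @return mass on the target moisture basis.
#' @export
to_15pc_humidity <- function(dry_mass, moisture_target = 0.15) {
  if (any(moisture_target < 0) || any(moisture_target >= 1))
    stop("moisture_target must be in [0, 1)")
  if (any(dry_mass < 0)) stop("dry_mass must be non-negative")
  dry_mass / (1 - moisture_target)
}

#' @rdname to_15pc_humidity
#' @param mass mass (g) on the `moisture_target` basis, converted back to dry.
#' @export
to_dry_mass <- function(mass, moisture_target = 0.15) {
  if (any(moisture_target < 0) || any(moisture_target >= 1))
    stop("moisture_target must be in [0, 1)")
  mass * (1 - moisture_target)
}

#' Derive grain number components from measured yield components
#'
#' From the three directly measured quantities -- grain yield GY (t/ha),
#' spikes per m2 (SPM2) and thousand-kernel weight TKW (g), both masses on
#' the same moisture basis -- computes the number of grains per m2
#' (GPM2 = GY expressed in g/m2 divided by the single-grain mass TKW/1000)
#' and the number of grains per spike (GPS = GPM2 / SPM2).
#'
#' @param gy grain yield, t/ha.
#' @param spm2 spikes per m2 (> 0).
#' @param tkw thousand-kernel weight, g (> 0).
#' @return data.frame with columns `gy`, `spm2`, `tkw`, `gpm2`, `gps`.
#' @examples
#' derive_components(10, 500, 50)  # gpm2 = 20000, gps = 40
#' @export
derive_components <- function(gy, spm2, tkw) {
  if (any(spm2 <= 0)) stop("spm2 must be positive")
  if (any(tkw <= 0)) stop("tkw must be positive")
  if (any(gy < 0)) stop("gy must be non-negative")
  g_per_m2 <- gy * 100                      # 1 t/ha = 100 g/m2
  gpm2 <- g_per_m2 / (tkw / 1000)
  gps <- gpm2 / spm2
  data.frame(gy = gy, spm2 = spm2, tkw = tkw, gpm2 = gpm2, gps = gps)
}
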