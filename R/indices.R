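#' Geoaccumulation index
#'
#' `igeo = log2(Cn / (1.5 * Bn))`, the Muller index comparing a measured
#' concentration `Cn` against 1.5 times the geochemical background `Bn`
#' (the 1.5 absorbs natural baseline fluctuation). A zero concentration
#' returns `-Inf`, which the classifier reports as a below-scale
#' sentinel class rather than propagating.
#'
#' @param conc Concentration(s), mg/kg, >= 0.
#' @param background Background value(s), mg/kg, > 0.
#' @return Numeric vector of index values (log2 units).
#' @export
igeo <- function(conc, background) {
  check_conc_background(conc, background)
  log2(conc / (1.5 * background))
}

#' Single-metal potential ecological risk
#'
#' `Er = Tr * Cn / Bn`: the contamination factor `Cn/Bn` weighted by the
#' Hakanson toxic-response coefficient `Tr` of the metal.
#'
#' @inheritParams igeo
#' @param tr Toxic-response coefficient, > 0.
#' @return Nonnegative risk value(s).
#' @export
er_index <- function(conc, background, tr) {
  check_conc_background(conc, background)
  if (any(!is.finite(tr)) || any(tr <= 0)) {
    stop("toxic-response coefficient must be strictly positive")
  }
  tr * conc / background
}

#' Cumulative potential ecological risk
#'
#' Sums `Er` over the full canonical metal set; a partial sum would not
#' be comparable across samples, so missing metals are an error.
#'
#' @param er_values Named numeric vector (or matrix with metal columns)
#'   of per-metal `Er` values covering all 8 canonical metals.
#' @return Scalar (or per-row vector) cumulative risk `RI`.
#' @export
ri_index <- function(er_values) {
  metals <- soil_metals()
  if (is.matrix(er_values) || is.data.frame(er_values)) {
    if (!all(metals %in% colnames(er_values))) {
      stop("RI requires Er for all 8 metals; missing: ",
           paste(setdiff(metals, colnames(er_values)), collapse = ", "))
    }
    return(rowSums(as.matrix(er_values)[, metals, drop = FALSE]))
  }
  if (!all(metals %in% names(er_values))) {
    stop("RI requires Er for all 8 metals; missing: ",
         paste(setdiff(metals, names(er_values)), collapse = ", "))
  }
  sum(er_values[metals])
}

#' Ratio of a mean concentration to its background value
#'
#' The contamination fold-ratio `Cn/Bn` used to report how many times a
#' metal exceeds its geochemical baseline.
#'
#' @inheritParams igeo
#' @export
exceedance_ratio <- function(conc, background) {
  check_conc_background(conc, background)
  conc / background
}

# Classification scales. Boundaries are half-open [lower, upper); the
# igeo scale additionally maps -Inf (zero concentration) to a
# below-scale sentinel class.
index_scales <- function() {
  list(
    igeo = list(
      breaks = c(0, 1, 2, 3, 4, 5),
      labels = c("unpolluted", "unpolluted_to_moderate", "moderate",
                 "moderate_to_heavy", "heavy", "heavy_to_extreme",
                 "extreme")),
    er = list(
      breaks = c(40, 80, 160, 320),
      labels = c("low", "moderate", "strong", "very_strong", "extreme")),
    ri = list(
      breaks = c(150, 300, 600, 1200),
      labels = c("low", "moderate", "strong", "very_strong", "extreme"))
  )
}

#' Classify an index value on its ordinal scale
#'
#' Scales: igeo at 0/1/2/3/4/5 (unpolluted ... extreme), Er at
#' 40/80/160/320 (low ... extreme), RI at 150/300/600/1200. All class
#' boundaries are half-open `[lower, upper)`.
#'
#' @param index One of `"igeo"`, `"er"`, `"ri"`.
#' @param value Numeric vector of index values; `-Inf` is allowed for
#'   igeo and labelled `"below_scale"`.
#' @return Ordered factor of class labels.
#' @export
classify_index <- function(index, value) {
  scales <- index_scales()
  if (!index %in% names(scales)) stop("unknown index: ", index)
  sc <- scales[[index]]
  labs <- sc$labels
  out <- labs[findInterval(value, sc$breaks) + 1L]
  if (index == "igeo") {
    out[is.infinite(value) & value < 0] <- "below_scale"
    labs <- c("below_scale", labs)
  }
  if (any(is.na(value) | (is.infinite(value) & index != "igeo"))) {
    stop("index values must be finite")
  }
  factor(out, levels = labs, ordered = TRUE)
}

#' Per-sample pollution index table
#'
#' Computes igeo, the contamination factor, Er per metal, cumulative RI
#' and their class labels for every sample, using layer-specific
#' background values.
#'
#' @param samples A [sample_table()].
#' @param background A [background_values()] registry.
#' @param tr Named toxic-response coefficients
#'   (default [toxicity_coefficients()]).
#' @return data.frame with one row per sample: `igeo_<m>`, `cf_<m>`,
#'   `er_<m>` columns, `ri`, `ri_class`, and `igeo_class_<m>`.
#' @export
pollution_indices <- function(samples, background = background_values(),
                              tr = toxicity_coefficients()) {
  metals <- soil_metals()
  conc <- as.matrix(samples[, metals])
  bg <- t(background$bgv[metals, samples$layer])  # n x 8
  ig <- log2(conc / (1.5 * bg))
  cf <- conc / bg
  er <- sweep(cf, 2, tr[metals], `*`)
  ri <- rowSums(er)

  out <- data.frame(site_id = samples$site_id, layer = samples$layer,
                    stringsAsFactors = FALSE)
  colnames(ig) <- paste0("igeo_", metals)
  colnames(cf) <- paste0("cf_", metals)
  colnames(er) <- paste0("er_", metals)
  out <- cbind(out, ig, cf, er)
  out$ri <- ri
  out$ri_class <- classify_index("ri", ri)
  for (m in metals) {
    out[[paste0("igeo_class_", m)]] <-
      classify_index("igeo", ig[, paste0("igeo_", m)])
  }
  out
}

check_conc_background <- function(conc, background) {
  if (any(!is.finite(background)) || any(background <= 0)) {
    stop("background must be strictly positive and finite")
  }
  if (any(is.na(conc)) || any(conc < 0)) {
    stop("concentration must be nonnegative")
  }
  invisible(TRUE)
}
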