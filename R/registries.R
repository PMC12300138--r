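#' Canonical heavy metals
#'
#' The eight metals analysed throughout the package, in canonical column
#' order: Cu, Zn, Ni, Pb, Cr, Cd, As, Hg. Every concentration matrix,
#' registry and result uses exactly this set.
#'
#' @return Character vector of length 8.
#' @export
soil_metals <- function() {
  c("Cu", "Zn", "Ni", "Pb", "Cr", "Cd", "As", "Hg")
}

#' Recognised soil layers and crop types
#' @return Character vector of valid values.
#' @export
soil_layers <- function() c("surface", "deep")

#' @rdname soil_layers
#' @export
crop_types <- function() {
  c("leafy", "fruit", "root", "inflorescence", "sugarcane", "banana", "none")
}

#' Layer-specific geochemical background values
#'
#' Background concentrations (mg/kg) for Guangdong province soils, per
#' metal and per sampling layer. Background values differ between the
#' 0-20 cm surface layer and the 150-200 cm deep layer; both are
#' mandatory so that indices are never computed against the wrong
#' horizon.
#'
#' @param path Optional YAML file with a `background` mapping
#'   (metal -> surface/deep values, mg/kg). When `NULL` the shipped
#'   provincial defaults are returned.
#' @return A `background_values` object: a list with an 8 x 2 numeric
#'   matrix `bgv` (metals x layers, mg/kg).
#' @export
background_values <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "background_guangdong.yaml",
                        package = "soilmetals", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$background)) {
    stop("background registry must contain a 'background' mapping")
  }
  metals <- soil_metals()
  bgv <- matrix(NA_real_, nrow = length(metals), ncol = 2,
                dimnames = list(metals, soil_layers()))
  for (m in metals) {
    entry <- cfg$background[[m]]
    if (is.null(entry) || is.null(entry$surface) || is.null(entry$deep)) {
      stop("background registry must give both layers for metal ", m,
           "; single-layer registries are rejected")
    }
    bgv[m, "surface"] <- as.numeric(entry$surface)
    bgv[m, "deep"] <- as.numeric(entry$deep)
  }
  if (any(!is.finite(bgv)) || any(bgv <= 0)) {
    stop("background values must be strictly positive and finite")
  }
  structure(list(bgv = bgv, units = "mg/kg"), class = "background_values")
}

#' Method detection limits
#'
#' ICP-MS detection limits per metal. Declared in ug/g, which is
#' numerically identical to mg/kg; values are stored as mg/kg.
#'
#' @param path Optional YAML file with an `mdl` mapping. Defaults to the
#'   shipped registry.
#' @return Named numeric vector (mg/kg) over the 8 canonical metals.
#' @export
detection_limits <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "detection_limits.yaml",
                        package = "soilmetals", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  mdl <- vapply(soil_metals(), function(m) {
    v <- cfg$mdl[[m]]
    if (is.null(v)) stop("detection limit missing for metal ", m)
    as.numeric(v)
  }, numeric(1))
  if (any(!is.finite(mdl)) || any(mdl <= 0)) {
    stop("detection limits must be strictly positive")
  }
  mdl
}

#' Hakanson toxic-response coefficients
#'
#' Dimensionless toxicity weights used by the potential ecological risk
#' index: Zn 1, Cr 2, Cu/Ni/Pb 5, As 10, Cd 30, Hg 40.
#'
#' @param path Optional YAML file with a `tr` mapping; defaults to the
#'   shipped Hakanson registry.
#' @return Named numeric vector over the 8 canonical metals.
#' @export
toxicity_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "toxicity_hakanson.yaml",
                        package = "soilmetals", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  tr <- vapply(soil_metals(), function(m) {
    v <- cfg$tr[[m]]
    if (is.null(v)) stop("toxic-response coefficient missing for metal ", m)
    as.numeric(v)
  }, numeric(1))
  if (any(!is.finite(tr)) || any(tr <= 0)) {
    stop("toxic-response coefficients must be strictly positive")
  }
  tr
}

#' Reference descriptive statistics for the study region
#'
#' Published layer-wise min/max/mean/CV of the 8 metals (mg/kg) for the
#' Pearl River estuary agricultural area, shipped as a plain CSV. Used
#' to anchor the synthetic generator and for desk-scale index checks.
#'
#' @return data.frame with columns metal, layer, min, max, mean, cv.
#' @export
reference_summary <- function() {
  path <- system.file("extdata", "reference_summary.csv",
                      package = "soilmetals", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$metal <- factor(df$metal, levels = soil_metals())
  df[order(df$layer, df$metal), ]
}

#' Published receptor-model factor profiles for the study region
#'
#' Two-factor profile matrices (concentration of species, mg/kg) per
#' layer, shipped as CSV. Rows are metals, columns factor1/factor2.
#'
#' @param layer `"surface"` or `"deep"`.
#' @return 8 x 2 numeric matrix (metals x factors, mg/kg).
#' @export
reference_profiles <- function(layer = c("surface", "deep")) {
  layer <- match.arg(layer)
  path <- system.file("extdata", "reference_profiles.csv",
                      package = "soilmetals", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$layer == layer, ]
  f <- as.matrix(df[, c("factor1", "factor2")])
  rownames(f) <- df$metal
  f[soil_metals(), , drop = FALSE]
}
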