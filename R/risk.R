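# Dose-response health risk: deterministic and Monte Carlo hazard
# quotients / cancer risks over four exposure pathways (soil ingestion,
# dermal contact, dust inhalation, crop food ingestion).

risk_pathways <- function() c("ingest", "dermal", "inhale", "food")
risk_populations <- function() c("child", "adult")

#' Validate a distribution specification
#'
#' A spec is `list(value = x)`, `list(normal = list(mean, sd))` or
#' `list(triangular = list(min, mode, max))`.
#'
#' @param spec The spec list.
#' @param name Parameter name used in error messages.
#' @return The spec, invisibly, or an error.
#' @export
check_dist_spec <- function(spec, name = "parameter") {
  if (!is.list(spec) || length(spec) != 1) {
    stop("invalid distribution spec for ", name)
  }
  kind <- names(spec)
  if (kind == "value") {
    if (!is.finite(spec$value)) stop(name, ": point value must be finite")
  } else if (kind == "normal") {
    p <- spec$normal
    if (is.null(p$mean) || is.null(p$sd) || p$sd <= 0) {
      stop(name, ": normal spec needs mean and sd > 0")
    }
  } else if (kind == "triangular") {
    p <- spec$triangular
    if (is.null(p$min) || is.null(p$mode) || is.null(p$max) ||
        !(p$min <= p$mode && p$mode <= p$max) || p$min == p$max) {
      stop(name, ": triangular spec needs min <= mode <= max, min < max")
    }
  } else {
    stop(name, ": unknown distribution kind '", kind, "'")
  }
  invisible(spec)
}

#' Central value of a distribution spec
#' @inheritParams check_dist_spec
#' @return Point value, normal mean, or triangular mean
#'   `(min + mode + max) / 3`.
#' @export
dist_mean <- function(spec) {
  check_dist_spec(spec)
  switch(names(spec),
         value = spec$value,
         normal = spec$normal$mean,
         triangular = with(spec$triangular, (min + mode + max) / 3))
}

#' Draw from a distribution spec
#'
#' Normal draws are truncated at zero by redrawing (physical exposure
#' parameters cannot be negative); triangular draws use the inverse CDF.
#'
#' @inheritParams check_dist_spec
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_dist <- function(spec, n) {
  check_dist_spec(spec)
  kind <- names(spec)
  if (kind == "value") return(rep(spec$value, n))
  if (kind == "normal") {
    x <- stats::rnorm(n, spec$normal$mean, spec$normal$sd)
    while (any(x <= 0)) {
      bad <- x <= 0
      x[bad] <- stats::rnorm(sum(bad), spec$normal$mean, spec$normal$sd)
    }
    return(x)
  }
  p <- spec$triangular
  u <- stats::runif(n)
  fc <- (p$mode - p$min) / (p$max - p$min)
  ifelse(u < fc,
         p$min + sqrt(u * (p$max - p$min) * (p$mode - p$min)),
         p$max - sqrt((1 - u) * (p$max - p$min) * (p$max - p$mode)))
}

#' Exposure parameter registry
#'
#' Loads per-population exposure parameters (each a point value or a
#' distribution spec) from YAML; defaults to the shipped registry of
#' standard handbook values.
#'
#' @param path Optional YAML path.
#' @return Named list `child` / `adult` of validated specs.
#' @export
exposure_parameters <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "exposure_default.yaml",
                        package = "soilmetals", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  needed <- c("IngR", "InhR", "SA", "AF", "ABS", "EF", "ED", "BW",
              "AT_nc", "AT_ca", "PEF", "CF", "IR_food")
  for (pop in risk_populations()) {
    if (is.null(cfg[[pop]])) stop("exposure registry missing population ", pop)
    for (nm in needed) {
      if (is.null(cfg[[pop]][[nm]])) {
        stop("exposure registry missing ", nm, " for ", pop)
      }
      check_dist_spec(cfg[[pop]][[nm]], paste(pop, nm))
    }
  }
  cfg[risk_populations()]
}

#' Toxicological reference registry (RfD and slope factors)
#'
#' @param path Optional YAML path; defaults to the shipped registry.
#' @return List with `rfd` and `sf`: 8 x 4 matrices (metal x pathway,
#'   `NA` where a pathway has no reference value and contributes
#'   nothing).
#' @export
tox_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tox_reference.yaml",
                        package = "soilmetals", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  as_mat <- function(entry) {
    m <- matrix(NA_real_, nrow = 8, ncol = 4,
                dimnames = list(soil_metals(), risk_pathways()))
    for (metal in names(entry)) {
      for (pw in names(entry[[metal]])) {
        m[metal, pw] <- as.numeric(entry[[metal]][[pw]])
      }
    }
    if (any(m[!is.na(m)] <= 0)) stop("reference values must be positive")
    m
  }
  list(rfd = as_mat(cfg$rfd), sf = as_mat(cfg$sf))
}

#' Crop bioconcentration factors
#'
#' Dimensionless crop-fresh-weight over soil concentration ratios per
#' crop type and metal. The shipped table holds representative values
#' constructed for this package (synthetic defaults), with the
#' `"none"` crop mapping to zero (food pathway disabled).
#'
#' @param path Optional CSV path (columns `crop_type`, then metals).
#' @return Matrix crops x 8 metals.
#' @export
bioconcentration_factors <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "bcf_synthetic.csv",
                        package = "soilmetals", mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, soil_metals()])
  rownames(m) <- df$crop_type
  if (any(m < 0)) stop("bioconcentration factors must be >= 0")
  m
}

#' Average daily dose for one exposure pathway
#'
#' Canonical dose equations, linear in concentration:
#' \describe{
#'   \item{ingest}{`C * IngR * EF * ED * CF / (BW * AT)`}
#'   \item{dermal}{`C * SA * AF * ABS * EF * ED * CF / (BW * AT)`}
#'   \item{inhale}{`C * InhR * EF * ED / (PEF * BW * AT)`}
#'   \item{food}{`C * BCF * IR_food * EF * ED / (BW * AT)`}
#' }
#'
#' @param conc Soil concentration(s), mg/kg.
#' @param pathway One of `"ingest"`, `"dermal"`, `"inhale"`, `"food"`.
#' @param p Named list/vector of realized parameter values (including
#'   `AT`, the averaging time for the endpoint under study). Vectors
#'   are recycled against `conc` for vectorized evaluation.
#' @param bcf Bioconcentration factor(s); required for the food pathway
#'   (use 0 for crop type `"none"`).
#' @return Average daily dose, mg/(kg day), nonnegative.
#' @export
add_pathway <- function(conc, pathway, p, bcf = NULL) {
  pathway <- match.arg(pathway, risk_pathways())
  if (any(conc < 0)) stop("concentration must be nonnegative")
  p <- as.list(p)
  base <- p$EF * p$ED / (p$BW * p$AT)
  switch(pathway,
    ingest = conc * p$IngR * p$CF * base,
    dermal = conc * p$SA * p$AF * p$ABS * p$CF * base,
    inhale = conc * p$InhR / p$PEF * base,
    food = {
      if (is.null(bcf)) stop("food pathway requires a bcf (0 for 'none')")
      conc * bcf * p$IR_food * base
    })
}

#' Hazard quotient, hazard index, cancer risk, total cancer risk
#'
#' `hq = ADD / RfD`; `hi = sum of HQs`; `cr = ADD * SF`;
#' `tcr = sum of CRs`.
#'
#' @param add Average daily dose, mg/(kg day).
#' @param rfd Reference dose, mg/(kg day), > 0.
#' @return Nonnegative risk quantity.
#' @export
hq <- function(add, rfd) {
  if (any(!is.na(rfd) & rfd <= 0)) stop("rfd must be positive")
  ifelse(is.na(rfd), 0, add / rfd)
}

#' @rdname hq
#' @param hqs Numeric vector/matrix of hazard quotients.
#' @export
hi <- function(hqs) sum(hqs)

#' @rdname hq
#' @param sf Cancer slope factor, (mg/(kg day))^-1.
#' @export
cr <- function(add, sf) {
  if (any(!is.na(sf) & sf <= 0)) stop("sf must be positive")
  ifelse(is.na(sf), 0, add * sf)
}

#' @rdname hq
#' @param crs Numeric vector/matrix of cancer risks.
#' @export
tcr <- function(crs) sum(crs)

# Effective per-metal BCF for a set of sites: by default the mean over
# sites of the BCF of the crop grown there ("site" mode); "area" mode
# uses fixed area shares of the cultivated crops.
effective_bcf <- function(crops, bcf_matrix,
                          food_mode = c("site", "area"),
                          area_shares = NULL) {
  food_mode <- match.arg(food_mode)
  if (food_mode == "site") {
    colMeans(bcf_matrix[crops, , drop = FALSE])
  } else {
    if (is.null(area_shares)) {
      area_shares <- c(sugarcane = 0.458, leafy = 0.166, fruit = 0.094,
                       root = 0.094, inflorescence = 0.094, banana = 0.094)
    }
    area_shares <- area_shares / sum(area_shares)
    drop(area_shares %*% bcf_matrix[names(area_shares), , drop = FALSE])
  }
}

#' Deterministic risk computation for one layer and population
#'
#' Evaluates the dose model at central parameter values and the layer
#' mean concentrations; the food pathway uses the effective mean crop
#' BCF across sites (default) or area-weighted crop shares.
#'
#' @param samples A [sample_table()].
#' @param layer `"surface"` or `"deep"`.
#' @param population `"child"` or `"adult"`.
#' @param exposure Output of [exposure_parameters()].
#' @param tox Output of [tox_reference()].
#' @param bcf Output of [bioconcentration_factors()].
#' @param food_mode `"site"` (per-site crop assignment, default) or
#'   `"area"` (area-weighted crop shares).
#' @return List with matrices `add_nc`, `add_ca`, `hq`, `cr`
#'   (metal x pathway) and scalars `hi`, `tcr`.
#' @export
deterministic_risk <- function(samples, layer, population,
                               exposure = exposure_parameters(),
                               tox = tox_reference(),
                               bcf = bioconcentration_factors(),
                               food_mode = c("site", "area")) {
  layer <- match.arg(layer, soil_layers())
  population <- match.arg(population, risk_populations())
  food_mode <- match.arg(food_mode)
  sub <- samples[samples$layer == layer, , drop = FALSE]
  if (nrow(sub) == 0) stop("no samples in layer ", layer)
  conc <- colMeans(as.matrix(sub[, soil_metals()]))
  bcf_eff <- effective_bcf(sub$crop_type, bcf, food_mode)
  p0 <- lapply(exposure[[population]], dist_mean)

  mats <- risk_matrices(conc, bcf_eff, p0, tox)
  c(mats, list(hi = sum(mats$hq), tcr = sum(mats$cr),
               layer = layer, population = population))
}

# metal x pathway dose/risk matrices at one realized parameter set.
risk_matrices <- function(conc, bcf_eff, p, tox) {
  metals <- soil_metals()
  add_nc <- add_ca <- matrix(0, 8, 4, dimnames = list(metals, risk_pathways()))
  for (pw in risk_pathways()) {
    b <- if (pw == "food") bcf_eff else NULL
    add_nc[, pw] <- add_pathway(conc, pw, c(p, AT = p$AT_nc), bcf = b)
    add_ca[, pw] <- add_pathway(conc, pw, c(p, AT = p$AT_ca), bcf = b)
  }
  list(add_nc = add_nc, add_ca = add_ca,
       hq = hq(add_nc, tox$rfd), cr = cr(add_ca, tox$sf))
}

#' Monte Carlo probabilistic risk for one layer and population
#'
#' Per iteration: stochastic exposure parameters are drawn from their
#' distribution specs, and the concentration term is drawn from the
#' empirical per-layer sample distribution (whole-sample resampling, so
#' metal correlations and the site's crop are preserved). With
#' `conc_mode = "mean"` the layer mean concentration and effective mean
#' BCF are used instead, in which case all-point specs make every
#' iteration identical to the deterministic computation.
#'
#' @inheritParams deterministic_risk
#' @param n_iter Number of iterations (default 10000).
#' @param seed Integer seed (reproducible summaries).
#' @param conc_mode `"resample"` (default) or `"mean"`.
#' @return A `risk_result`: summary data.frame, per-iteration `HI` and
#'   `TCR` vectors, per-metal and per-pathway mean decompositions.
#' @export
monte_carlo_risk <- function(samples, layer, population,
                             exposure = exposure_parameters(),
                             tox = tox_reference(),
                             bcf = bioconcentration_factors(),
                             n_iter = 10000, seed = 1,
                             conc_mode = c("resample", "mean"),
                             food_mode = c("site", "area")) {
  layer <- match.arg(layer, soil_layers())
  population <- match.arg(population, risk_populations())
  conc_mode <- match.arg(conc_mode)
  food_mode <- match.arg(food_mode)
  if (n_iter < 1) stop("n_iter must be >= 1")
  specs <- exposure[[population]]
  for (nm in names(specs)) check_dist_spec(specs[[nm]], nm)

  sub <- samples[samples$layer == layer, , drop = FALSE]
  if (nrow(sub) == 0) stop("no samples in layer ", layer)
  X <- as.matrix(sub[, soil_metals()])

  # substream: one master seed, deterministic offset per (pop, layer)
  offset <- (match(population, risk_populations()) - 1) * 2 +
    match(layer, soil_layers())
  set.seed(as.integer(seed) + offset)

  p <- lapply(specs, draw_dist, n = n_iter)
  if (conc_mode == "resample") {
    idx <- sample.int(nrow(X), n_iter, replace = TRUE)
    C <- X[idx, , drop = FALSE]
    B <- bcf[sub$crop_type[idx], , drop = FALSE]
  } else {
    C <- matrix(colMeans(X), n_iter, 8, byrow = TRUE,
                dimnames = list(NULL, soil_metals()))
    B <- matrix(effective_bcf(sub$crop_type, bcf, food_mode),
                n_iter, 8, byrow = TRUE,
                dimnames = list(NULL, soil_metals()))
  }

  hq_m <- cr_m <- matrix(0, n_iter, 8, dimnames = list(NULL, soil_metals()))
  hq_p <- cr_p <- matrix(0, n_iter, 4, dimnames = list(NULL, risk_pathways()))
  for (pw in risk_pathways()) {
    b <- if (pw == "food") B else NULL
    a_nc <- add_pathway(C, pw, c(p, list(AT = p$AT_nc)), bcf = b)
    a_ca <- add_pathway(C, pw, c(p, list(AT = p$AT_ca)), bcf = b)
    hq_pw <- sweep_hq(a_nc, tox$rfd[, pw])
    cr_pw <- sweep_cr(a_ca, tox$sf[, pw])
    hq_m <- hq_m + hq_pw
    cr_m <- cr_m + cr_pw
    hq_p[, pw] <- rowSums(hq_pw)
    cr_p[, pw] <- rowSums(cr_pw)
  }
  HI <- rowSums(hq_m)
  TCR <- rowSums(cr_m)

  summ <- function(x) c(mean = mean(x), sd = stats::sd(x),
                        p05 = unname(stats::quantile(x, 0.05)),
                        p50 = unname(stats::quantile(x, 0.50)),
                        p95 = unname(stats::quantile(x, 0.95)))
  structure(list(
    population = population, layer = layer, n_iter = n_iter, seed = seed,
    summary = rbind(HI = summ(HI), TCR = summ(TCR)),
    HI = HI, TCR = TCR,
    hq_metal_mean = colMeans(hq_m), cr_metal_mean = colMeans(cr_m),
    hq_pathway_mean = colMeans(hq_p), cr_pathway_mean = colMeans(cr_p)),
    class = "risk_result")
}

sweep_hq <- function(add, rfd) {
  out <- sweep(add, 2, rfd, `/`)
  out[, is.na(rfd)] <- 0
  out
}

sweep_cr <- function(add, sf) {
  out <- sweep(add, 2, sf, `*`)
  out[, is.na(sf)] <- 0
  out
}

#' Cumulative probability curve of a risk endpoint
#'
#' @param result A `risk_result`.
#' @param endpoint `"HI"` or `"TCR"`.
#' @return data.frame with sorted `value` and cumulative probability
#'   `prob` (monotone nondecreasing from 1/n to 1).
#' @export
risk_curve <- function(result, endpoint = c("HI", "TCR")) {
  endpoint <- match.arg(endpoint)
  x <- sort(result[[endpoint]])
  data.frame(value = x, prob = seq_along(x) / length(x))
}

#' Contribution fractions to HI and TCR
#'
#' @param result A `risk_result`.
#' @param by `"metal"` or `"pathway"`.
#' @return data.frame of nonnegative fractions summing to 1 per
#'   endpoint; a zero total raises an error rather than silent NaN.
#' @export
risk_contributions <- function(result, by = c("metal", "pathway")) {
  by <- match.arg(by)
  hqv <- if (by == "metal") result$hq_metal_mean else result$hq_pathway_mean
  crv <- if (by == "metal") result$cr_metal_mean else result$cr_pathway_mean
  if (sum(hqv) == 0 || sum(crv) == 0) {
    stop("zero total risk: contribution fractions undefined")
  }
  data.frame(name = rep(names(hqv), 2),
             endpoint = rep(c("HI", "TCR"), each = length(hqv)),
             fraction = c(hqv / sum(hqv), crv / sum(crv)),
             row.names = NULL)
}
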