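#' Build a validated sample table
#'
#' Central data container: one row per (site, layer) with concentrations
#' (mg/kg) of the 8 canonical metals and a crop type describing what is
#' cultivated at the site. Missing crop type defaults to `"none"`,
#' which disables the food-ingestion pathway for that sample instead of
#' guessing a crop.
#'
#' @param df data.frame with columns `site_id`, `layer`, optional
#'   `crop_type`, and one numeric column per canonical metal.
#' @return A `sample_table`: the validated data.frame with canonical
#'   column order.
#' @export
sample_table <- function(df) {
  metals <- soil_metals()
  missing_cols <- setdiff(c("site_id", "layer", metals), names(df))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$crop_type)) df$crop_type <- "none"
  df$crop_type[is.na(df$crop_type) | df$crop_type == ""] <- "none"
  bad_crop <- setdiff(unique(df$crop_type), crop_types())
  if (length(bad_crop) > 0) {
    stop("unknown crop_type value(s): ", paste(bad_crop, collapse = ", "))
  }
  bad_layer <- setdiff(unique(df$layer), soil_layers())
  if (length(bad_layer) > 0) {
    stop("layer must be one of ", paste(soil_layers(), collapse = "/"),
         "; got: ", paste(bad_layer, collapse = ", "))
  }

  conc <- as.matrix(df[, metals])
  storage.mode(conc) <- "double"
  bad_rows <- which(apply(conc, 1, function(x) any(!is.finite(x) | x < 0)))
  if (length(bad_rows) > 0) {
    stop("integrity error: negative or non-numeric concentration in row(s): ",
         paste(bad_rows, collapse = ", "))
  }
  key <- paste(df$site_id, df$layer)
  if (anyDuplicated(key)) {
    stop("integrity error: duplicate (site_id, layer) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }

  out <- data.frame(site_id = as.character(df$site_id),
                    layer = df$layer,
                    crop_type = df$crop_type,
                    stringsAsFactors = FALSE)
  out[, metals] <- as.data.frame(conc)
  class(out) <- c("sample_table", "data.frame")
  out
}

#' Read a sample table from CSV
#'
#' @param path CSV with header `site_id, layer, crop_type, Cu, ..., Hg`.
#' @return A validated [sample_table()].
#' @export
load_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sample_table(df)
}

#' Write a sample table to CSV
#' @param samples A `sample_table`.
#' @param path Output CSV path.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE)
  invisible(path)
}

#' Per-metal, per-layer descriptive statistics
#'
#' Computes min, max, arithmetic mean, sample standard deviation and the
#' coefficient of variation (sd/mean, with the n-1 standard deviation, the
#' usual geochemical reporting convention) for each metal within each
#' layer.
#'
#' @param samples A `sample_table` with at least 2 samples per layer.
#' @return data.frame with columns metal, layer, n, min, max, mean, sd,
#'   cv. A zero mean yields `cv = NA` with a warning rather than a
#'   silent drop.
#' @export
summarize_metals <- function(samples) {
  metals <- soil_metals()
  layers <- intersect(soil_layers(), unique(samples$layer))
  rows <- list()
  for (l in layers) {
    sub <- samples[samples$layer == l, metals, drop = FALSE]
    if (nrow(sub) < 2) {
      stop("need at least 2 samples per layer; layer '", l, "' has ",
           nrow(sub))
    }
    for (m in metals) {
      x <- sub[[m]]
      mu <- mean(x)
      s <- stats::sd(x)
      if (mu == 0) {
        warning("zero mean for ", m, " (", l, "): CV undefined")
        cv <- NA_real_
      } else {
        cv <- s / mu
      }
      rows[[length(rows) + 1]] <- data.frame(
        metal = m, layer = l, n = length(x), min = min(x), max = max(x),
        mean = mu, sd = s, cv = cv, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Split a paired table into aligned layer matrices
#'
#' Sites lacking either layer are dropped with a warning, so that the
#' two returned matrices share an identical site ordering — the form
#' needed for surface-vs-deep comparison and per-layer source runs.
#'
#' @param samples A `sample_table`.
#' @return List with `surface` and `deep` (n_sites x 8 matrices, mg/kg),
#'   `sites` (character vector, the shared row order) and per-layer
#'   `crop_type` (from the surface rows).
#' @export
pair_layers <- function(samples) {
  metals <- soil_metals()
  s_ids <- samples$site_id[samples$layer == "surface"]
  d_ids <- samples$site_id[samples$layer == "deep"]
  sites <- intersect(s_ids, d_ids)
  dropped <- setdiff(union(s_ids, d_ids), sites)
  if (length(dropped) > 0) {
    warning("dropping ", length(dropped),
            " site(s) lacking one layer: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  if (length(sites) == 0) stop("no complete surface/deep pairs")

  take <- function(layer) {
    sub <- samples[samples$layer == layer, , drop = FALSE]
    sub <- sub[match(sites, sub$site_id), , drop = FALSE]
    m <- as.matrix(sub[, metals])
    rownames(m) <- sites
    m
  }
  surf_rows <- samples[samples$layer == "surface", , drop = FALSE]
  crops <- surf_rows$crop_type[match(sites, surf_rows$site_id)]
  list(surface = take("surface"), deep = take("deep"),
       sites = sites, crop_type = stats::setNames(crops, sites))
}
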