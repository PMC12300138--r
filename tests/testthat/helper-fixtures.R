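# Small in-code fixtures shared across test files.

# minimal valid table: n paired sites with constant-ish concentrations
tiny_table <- function(n = 4, base = NULL) {
  metals <- soil_metals()
  if (is.null(base)) {
    base <- c(Cu = 50, Zn = 120, Ni = 40, Pb = 45, Cr = 80,
              Cd = 0.4, As = 25, Hg = 0.12)
  }
  df <- expand.grid(site_id = sprintf("T%02d", seq_len(n)),
                    layer = c("surface", "deep"),
                    stringsAsFactors = FALSE)
  df$crop_type <- "leafy"
  for (m in metals) df[[m]] <- base[[m]] * seq(0.8, 1.2, length.out = nrow(df))
  sample_table(df)
}

# exposure registry with every parameter collapsed to its central value
point_exposure <- function() {
  ex <- exposure_parameters()
  lapply(ex, function(pop) {
    lapply(pop, function(spec) list(value = dist_mean(spec)))
  })
}

# align a fitted 2 x metals percentage matrix with a truth matrix by
# the factor permutation minimizing total absolute difference
align_factors <- function(est, truth) {
  d_id <- sum(abs(est - truth))
  d_sw <- sum(abs(est[2:1, ] - truth))
  if (d_sw < d_id) est[2:1, ] else est
}
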