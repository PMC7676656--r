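# Shared fixtures, built in code at test time.

# Exact uniform[0, 20] TMB distribution on a fine grid.
uniform_dist <- function(n_grid = 8192) {
  x <- seq(0, 20, length.out = n_grid)
  grid_distribution(x, rep(1 / 20, n_grid), histology = "UNIF")
}

# KDE fit of a preset cohort, cached per session to keep tests fast.
preset_dist <- local({
  cache <- list()
  function(preset, n = 5000, seed = 11) {
    key <- paste(preset, n, seed, sep = "_")
    if (is.null(cache[[key]])) {
      co <- generate_synthetic_cohort(preset, n, seed = seed)
      cache[[key]] <<- fit_histology_distribution(
        co, tmb_preset_params(preset)$histology)
    }
    cache[[key]]
  }
})

# A small cohort CSV on disk; returns the path.
write_fixture_csv <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# 23 lognormal histology distributions spanning the TCGA-like median range
# 0.4 - 13 mutations/Mb (sdlog 0.7), used by the regression-variability
# analyses.
histology_panel_23 <- function() {
  meds <- exp(seq(log(0.4), log(13), length.out = 23))
  dists <- lapply(seq_along(meds), function(i) {
    x <- seq(0, stats::qlnorm(0.9999, log(meds[i]), 0.7) * 1.5,
             length.out = 4096)
    grid_distribution(x, stats::dlnorm(x, log(meds[i]), 0.7),
                      histology = sprintf("H%02d", i))
  })
  names(dists) <- vapply(dists, function(d) d$histology, character(1))
  dists
}
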