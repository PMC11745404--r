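# Regenerates the plain-text fixtures under inst/extdata/. Everything here
# is synthetic and produced by the package itself; covers are rounded to
# integer percent to mimic the discretization of satellite vegetation-cover
# products.

library(borealstate)

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)

# A small panel along the full boreal MAT gradient: warm-dense / cold-sparse
# carrying cover, moderate process noise, cover-independent observation
# noise.
gt <- ground_truth("logistic", r = 0.3, K = 60, process_noise = 2,
                   obs_noise = 2)
cfg <- synthetic_config(n_plots = 150, years = 21, seed = 2025,
                        mat_range = c(-14, 6),
                        mat_gradient = list(K = c(25, 70)),
                        strata = list(region = c("NAm", "Eurasia")))
p <- generate_panel(gt, cfg)
V <- round(panel_cover(p))
p_int <- cover_panel(p$plot_id, round(p$mat, 2), V, panel_years(p),
                     strata = p["region"])
write_panel(p_int, "inst/extdata/synthetic_panel.csv")

# Synthetic cover-biomass calibration pairs from an exponential truth with
# multiplicative-scale scatter.
set.seed(2025)
cov <- round(runif(300, 0, 95), 1)
agb <- round(5 * exp(0.04 * cov) + rnorm(300, 0, 2), 2)
write.csv(data.frame(cover = cov, agb = pmax(0, agb),
                     region = sample(c("NAm", "Eurasia"), 300, TRUE)),
          "inst/extdata/synthetic_biomass_pairs.csv", row.names = FALSE,
          quote = FALSE)

# A ready-to-run pipeline configuration (self-contained: synthesizes its
# own panel).
writeLines(c(
  "out: pipeline_out",
  "synth:",
  "  drift: logistic",
  "  r: 0.3",
  "  K: 60",
  "  process_noise: 2",
  "  obs_noise: 2",
  "  n_plots: 600",
  "  mat_range: [-1, 1]",
  "bins: {low: -1, high: 1, width: 2}",
  "trend: {min_n: 50}",
  "noise: {min_n: 10}",
  "sim: {steps: 200}",
  "seeds: {synthesize: 11, simulate: 12, observation: 13}"
), "inst/extdata/pipeline.yaml")

cat("fixtures written\n")
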