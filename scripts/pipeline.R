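#!/usr/bin/env Rscript
# Thin command-line wrapper over coastimpact::run_pipeline(): generates a
# synthetic study (or uses a YAML configuration) and writes all stage outputs
# plus a manifest to --out.
#   Rscript scripts/pipeline.R --seed 1 --out results/run1
#   Rscript scripts/pipeline.R --config my_config.yaml --out results/run2

suppressPackageStartupMessages({
  library(optparse)
  library(coastimpact)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--config", type = "character", default = NULL,
              help = "YAML configuration (overrides --seed)"),
  make_option("--n-ocean-cells", type = "integer", default = 20L,
              dest = "n_ocean_cells"),
  make_option("--window", type = "integer", default = 11L),
  make_option("--n-boot", type = "integer", default = 1000L, dest = "n_boot"),
  make_option("--scenarios", type = "character", default = NULL,
              help = "comma-separated subset, e.g. ssp585"),
  make_option("--out", type = "character", default = "results/pipeline")
)))

cfg <- if (!is.null(opts$config)) read_config_yaml(opts$config)
       else synthetic_config(seed = opts$seed)
scen <- if (!is.null(opts$scenarios)) strsplit(opts$scenarios, ",")[[1]]

res <- run_pipeline(cfg, scenarios = scen, n_ocean_cells = opts$n_ocean_cells,
                    window = opts$window, n_boot = opts$n_boot,
                    output_dir = opts$out)
print(res)
cat("outputs written to", opts$out, "\n")
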