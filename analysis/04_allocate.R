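#!/usr/bin/env Rscript
# Step 4 -- CA spatial allocation of the scenario demands.
#
# Walks each scenario from 2015 to 2035 in 5-year steps, allocating the
# Markov demand (step 2) with the suitability-driven cellular automaton, and
# writes a land-use raster per scenario-year.

suppressPackageStartupMessages(library(modses))

seed <- 2026
bundle <- generate_landscape(synthetic_config(100, 100, seed = seed))
lu_2015 <- read_ascii_grid("results/demand/landuse_2015.asc")
factors <- generate_driving_factors(bundle, 16, seed = seed + 2)
surface <- train_suitability(factors, lu_2015, seed = seed + 3)

years <- seq(2015, 2035, by = 5)
out <- "results/landuse"
for (sname in names(default_scenarios())) {
  dem <- read.csv(file.path("results/demand",
                            paste0("demand_", sname, ".csv")),
                  check.names = FALSE)
  sdir <- file.path(out, sname)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  map <- lu_2015
  write_ascii_grid(map, file.path(sdir, "landuse_2015.asc"))
  for (i in seq_along(years)[-1]) {
    target <- round(as.numeric(dem[i, mods_classes()]))
    names(target) <- mods_classes()
    map <- ca_allocate(map, surface,
                       ca_params(seed = seed + 10 * i + nchar(sname)),
                       target)
    if (!attr(map, "converged")) {
      cat("  [!] non-convergence:", sname, years[i], "deficit:",
          paste(attr(map, "deficit"), collapse = " "), "\n")
    }
    write_ascii_grid(map, file.path(sdir,
                                    paste0("landuse_", years[i], ".asc")))
  }
  ch <- (class_counts(map) - class_counts(lu_2015)) * 100^2 / 1e6
  cat(sprintf("%s: 2035 allocation done; cropland %+0.2f km2, built %+0.2f km2, bare %+0.2f km2\n",
              sname, ch["cropland"], ch["built"], ch["bare"]))
}
cat("Scenario land-use rasters written to", out, "\n")
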