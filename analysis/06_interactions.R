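#!/usr/bin/env Rscript
# Step 6 -- Multi-service trade-offs and synergies.
#
# Regional scale: min-max-normalized service series per scenario (the
# flower-diagram data) with increase/decrease/unchanged trend labels and the
# pairwise synergy/trade-off matrix. Grid scale: per-pixel six-digit change
# codes (order WY, CP, SC, SF, CS, AV), an area filter on the legend, and
# attribution of each retained interaction class to the dominant land-use
# transition beneath it.

suppressPackageStartupMessages(library(modses))

# The area filter is scaled to the 100 km2 synthetic extent (the published
# convention of dropping legend classes below a fixed share of the study
# area): retain codes covering > 1 km2 here.
min_area_km2 <- 1

out <- "results/interactions"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (sname in names(default_scenarios())) {
  sdir <- file.path("results/es", sname)
  series <- read.csv(file.path(sdir, "series.csv"), check.names = FALSE)
  slist <- as.list(series[, es_order()])
  trends <- classify_regional_trends(slist, unchanged_threshold = 0.01)
  flower <- data.frame(
    scenario = sname,
    year = rep(series$year, length(es_order())),
    es = rep(es_order(), each = nrow(series)),
    raw = unlist(slist, use.names = FALSE),
    normalized = unlist(lapply(slist, minmax_normalize), use.names = FALSE))
  write.csv(flower, file.path(out, paste0("flower_", sname, ".csv")),
            row.names = FALSE)

  digits <- setNames(lapply(es_order(), function(nm) {
    t0 <- read_ascii_grid(file.path(sdir, paste0(nm, "_2015.asc")))
    t1 <- read_ascii_grid(file.path(sdir, paste0(nm, "_2035.asc")))
    reclass_change(t0, t1, epsilon = 0)
  }), es_order())
  codes <- filter_codes_by_area(encode_overlay(digits, pixel_size = 100),
                                min_area_km2)
  lu0 <- read_ascii_grid(file.path("results/landuse", sname,
                                   "landuse_2015.asc"))
  lu1 <- read_ascii_grid(file.path("results/landuse", sname,
                                   "landuse_2035.asc"))
  causes <- attribute_causes(codes, lu0, lu1)
  write.csv(codes$legend, file.path(out, paste0("legend_", sname, ".csv")),
            row.names = FALSE)
  write.csv(causes$table, file.path(out, paste0("causes_", sname, ".csv")),
            row.names = FALSE)

  cat("\n==", sname, "==\n")
  cat("Regional trends:",
      paste(names(trends$trend), trends$trend, collapse = ", "), "\n")
  top <- head(codes$legend[codes$legend$retained &
                             codes$legend$code != "333333", ], 3)
  if (nrow(top)) {
    cat("Largest interaction classes beyond 'no change':\n")
    print(top[, c("label", "area_km2")], row.names = FALSE)
    dom <- causes$dominant
    dom <- dom[dom$interaction %in% top$code, ]
    cat("Dominant land-use transitions under them:\n")
    print(dom, row.names = FALSE)
  } else {
    cat("No interaction class beyond 'no change' exceeds",
        min_area_km2, "km2\n")
  }
}
cat("\nInteraction tables written to", out, "\n")
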