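#!/usr/bin/env Rscript
# Posterior-probability signal maps (five classes at the 0.90/0.80/0.20/0.10
# cut-offs) per stage, choropleth-ready GeoJSON, and the cross-stage
# concordance summaries: do areas with elevated (or lowered) signals for a
# later stage also show SIR > 1 (< 1) for the earlier stage?

suppressPackageStartupMessages(library(stagemap))
dat <- "results/data"; tab <- "results/tables"
geo <- read_geography(file.path(dat, "geography.geojson"),
                      file.path(dat, "adjacency.csv"))

smoothed <- list(); signals <- list()
for (s in stage_levels()) {
  key <- gsub("[^A-Za-z0-9]", "", s)
  sm <- read.csv(file.path(tab, sprintf("smoothed_stage_%s.csv", key)))
  smoothed[[s]] <- sm
  sig <- classify_signals(setNames(sm$pp, sm$area_id))
  signals[[s]] <- sig
  write.csv(cbind(sig, stage = s),
            file.path(tab, sprintf("signals_stage_%s.csv", key)),
            row.names = FALSE)
  write_signal_geojson(sig, geo,
                       file.path(tab, sprintf("signals_stage_%s.geojson", key)))
  cat(sprintf("Stage %s signal classes: %s\n", s,
              paste(names(table(sig$class)), table(sig$class),
                    collapse = ", ", sep = "=")))
}

for (pair in list(c("II", "I"), c("III-IV", "II"))) {
  a <- pair[1]; b <- pair[2]
  sir_b <- setNames(smoothed[[b]]$smoothed_sir, smoothed[[b]]$area_id)
  for (dir in c("elevated", "lowered")) {
    cc <- tryCatch(concordance(signals[[a]], sir_b, dir),
                   warning = function(w) list(n_signalling = 0L,
                                              n_concordant = 0L,
                                              fraction = NA_real_))
    cat(sprintf(
      "Stage %s %s signals vs stage %s SIR: %d of %d concordant (%s)\n",
      a, dir, b, cc$n_concordant, cc$n_signalling,
      ifelse(is.na(cc$fraction), "no signalling areas",
             sprintf("%.0f%%", 100 * cc$fraction))))
  }
}
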