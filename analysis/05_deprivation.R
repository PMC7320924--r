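#!/usr/bin/env Rscript
# Deprivation analyses. (a) Ecological regression of log smoothed SIR on
# income quintile, weighted by inverse posterior variance of the log SIR —
# the area-level inequality estimate. (b) The case-level logistic regression
# of late-stage odds on age, sex and quintile — the proportion-based analysis
# whose interpretation the incidence mapping is designed to correct.

suppressPackageStartupMessages(library(stagemap))
dat <- "results/data"; tab <- "results/tables"
geo <- read_geography(file.path(dat, "geography.geojson"),
                      file.path(dat, "adjacency.csv"))
pop <- read_population(file.path(dat, "population.csv"))
cases <- read_cases(file.path(dat, "cases.csv"),
                    known_areas = geo$areas$area_id)
quint <- setNames(as.character(geo$areas$quintile), geo$areas$area_id)
mc <- mcmc_control(n_iter = 8000, burn_in = 4000, thin = 2, n_chains = 2,
                   seed = 2027L)

for (s in c("I", "II")) {
  sir <- suppressWarnings(compute_sir(expected_counts(cases, pop, s)))
  fit <- suppressWarnings(fit_bym(sir, geo$adjacency, mcmc = mc))
  er <- suppressWarnings(ecological_regression(fit, quint))
  er$stage <- s
  write.csv(er, file.path(tab, sprintf("ecoreg_stage_%s.csv",
                                       gsub("[^A-Za-z0-9]", "", s))),
            row.names = FALSE)
  cat(sprintf("Stage %s incidence ratios vs Q1 (WLS on smoothed SIR):\n", s))
  print(as.data.frame(er)[, c("quintile", "ratio", "ci_low", "ci_high")],
        digits = 3)
}

lo <- late_stage_logistic(cases, late = "II-IV", quintile = quint)
write.csv(lo, file.path(tab, "late_stage_or.csv"), row.names = FALSE)
cat("\nLate-stage (II-IV) odds ratios (ref: age 30-34, female, Q5):\n")
print(as.data.frame(lo[lo$term == "quintile", ]), digits = 3)
# the compositional mechanism: stage I incidence rises with wealth while
# late-stage incidence is flat, so the late-stage share among cases falls
# with wealth even though late-stage risk does not
by_q <- table(quint[cases$area_id], cases$stage != "I")
share <- by_q[, 2] / rowSums(by_q)
cat(sprintf("\nObserved late-stage share among cases, Q1 -> Q5: %s\n",
            paste(sprintf("%.2f", share), collapse = ", ")))
cat("Under the generative model the share falls with wealth only through\n")
cat("the stage I incidence gradient (late-stage incidence is flat), so any\n")
cat("such gradient in case shares is compositional - the artefact that\n")
cat("incidence mapping avoids. At this region's case count the expected\n")
cat(sprintf("shift is ~%.02f and may sit within sampling noise.\n",
            0.30 - 0.245))
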