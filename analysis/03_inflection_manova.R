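#!/usr/bin/env Rscript
# Omnibus multivariate inflection tests: all four biomarkers regressed
# jointly on covariates and CAMCOG, with a level-shift indicator and a
# hinge (slope-change) term at CAMCOG 89.

suppressPackageStartupMessages(library(csfchange))
tab <- read_cohort("results/cohort.csv")

mv <- inflection_manova(tab, inflect_at = 89)
print(mv$levels)
print(mv$slopes)

res <- data.frame(
  term = c("level shift", "slope change"),
  wilks = c(mv$levels$wilks, mv$slopes$wilks),
  f = c(mv$levels$f, mv$slopes$f),
  df1 = c(mv$levels$df[1], mv$slopes$df[1]),
  df2 = c(mv$levels$df[2], mv$slopes$df[2]),
  p = c(mv$levels$p_value, mv$slopes$p_value))
utils::write.csv(res, "results/inflection_manova.csv", row.names = FALSE)

cat("\nThe generator bends each biomarker's slope near CAMCOG 89-94 while\n")
cat("keeping the mean continuous, so the slope-change term should carry\n")
cat("the signal and the level-shift term should not.\n")
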