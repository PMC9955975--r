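#!/usr/bin/env Rscript
# Simulate a study-sized synthetic cohort and write it to results/cohort.csv.
#
# The generator emulates the structure the half-life analysis assumes:
# ~37% normal baseline DCP, ~71% complete response among response-assessed
# patients, fast marker clearance (median half-life 30 h) in complete
# responders versus slow clearance (median 90 h) with possible regrowth in
# incomplete responders, ~15 h draw intervals, 5% measurement noise, and
# 12-month recurrence fractions of 0.39 / 0.92 by half-life group.

library(dcpkinetics)

cfg <- synthetic_config(n_patients = 174, seed = 1)
cohort <- generate_cohort(cfg)

dir.create("results", showWarnings = FALSE)
write.csv(cohort, "results/cohort.csv", row.names = FALSE, na = "")

cat(sprintf("Simulated %d patients -> results/cohort.csv\n", nrow(cohort)))
cat(sprintf("  normal baseline (<40 mAU/mL): %d\n", sum(cohort$dcp_d0 < 40)))
resp <- table(cohort$response_1mo, useNA = "no")
cat(sprintf("  response-assessed: %d (%d complete / %d incomplete)\n",
            sum(resp), resp[["complete"]], resp[["incomplete"]]))
exp_cls <- expected_classification(cfg)
cat(sprintf("  generative expectation at the 48 h cutoff: sens %.3f, spec %.3f\n",
            exp_cls$sensitivity, exp_cls$specificity))
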