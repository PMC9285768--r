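#!/usr/bin/env Rscript
# Step 5: the literature-review side of the study -- generate the synthetic
# observation table that carries the published aggregate counts of
# warming-induced size-structure shifts in zooplankton, and tally it.

library(thermostage)
dir.create("results", showWarnings = FALSE)

fx <- generate_review_fixture(seed = 1)
write.csv(fx, "results/review_fixture.csv", row.names = FALSE)

tl <- tally_review(fx)
tab <- as.data.frame(tl$counts)
write.csv(tab, "results/review_tally.csv", row.names = FALSE)

cat(sprintf("%d observations from %d articles\n",
            tl$total, attr(fx, "n_articles")))
cat("level x outcome counts:\n")
print(tl$by_level_outcome)
cat("Interspecific studies overwhelmingly report shifts to smaller species",
    sprintf("(%d of %d);\n", tl$by_level_outcome["interspecific", "smaller"],
            tl$by_level["interspecific"]),
    "intraspecific studies split between smaller",
    sprintf("(%d)", tl$by_level_outcome["intraspecific", "smaller"]),
    "and larger",
    sprintf("(%d) stages.\n", tl$by_level_outcome["intraspecific", "larger"]))
cat("wrote results/review_fixture.csv, results/review_tally.csv\n")
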