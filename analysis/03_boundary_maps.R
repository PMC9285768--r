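#!/usr/bin/env Rscript
# Step 3: boundary structure of the temperature x diet-preference plane with
# the size-temperature interactions on. Maps the persistence boundaries of
# both Community I consumers, the species- and stage-level dominance
# boundaries, the Community II bistability region, and a classified raster
# of the Community III plane.

library(thermostage)
dir.create("results", showWarnings = FALSE)

sc1 <- scenario("I")
sc2 <- scenario("II")
sc3 <- scenario("III")

for (subject in c("CS", "CL")) {
  pb <- persistence_boundary(sc1, subject, T_range = c(0, 45),
                             p_range = c(0.5, 1), n_grid = c(19, 6),
                             tol_T = 0.05)
  write.csv(pb, sprintf("results/persistence_%s.csv", subject),
            row.names = FALSE)
  if (nrow(pb) > 0)
    cat(sprintf("%s persistence boundary: %d points, upper limit %.2f C\n",
                subject, nrow(pb), suppressWarnings(
                  max(pb$T[pb$direction == "upper"]))))
}

db1 <- dominance_boundary(sc1, "species", T_range = c(15, 38),
                          p_range = c(0.6, 1), n_grid = c(13, 5),
                          tol_T = 0.05)
write.csv(db1, "results/dominance_species_I.csv", row.names = FALSE)
db2 <- dominance_boundary(sc2, "stage", T_range = c(15, 38),
                          p_range = c(0.6, 1), n_grid = c(13, 5),
                          tol_T = 0.05)
write.csv(db2, "results/dominance_stage_II.csv", row.names = FALSE)
cat(sprintf("Dominance boundaries: Community I %d points, Community II %d points\n",
            nrow(db1), nrow(db2)))

bi <- bistability_region(sc2, T_range = c(22, 36), p_range = c(0.8, 1),
                         n_grid = c(8, 5), tol_T = 0.5, seed = 1,
                         n_random = 2)
write.csv(bi$grid, "results/bistability_grid_II.csv", row.names = FALSE)
cat(sprintf("Community II bistability: %d of %d cells hold two stable states\n",
            nrow(bi$region), nrow(bi$grid)))

plane3 <- map_T_p_plane(sc3, T_range = c(2, 44), p_range = c(0.1, 0.9),
                        n_grid = c(15, 5))
write.csv(plane3, "results/plane_III.csv", row.names = FALSE)
cat("Community III raster labels:\n")
print(table(plane3$label))
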