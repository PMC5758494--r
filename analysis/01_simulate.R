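#!/usr/bin/env Rscript
# Stage 1: simulate the default desk-scale landscape and write its layers.
#
# The generator emulates the study system the pipeline expects: clustered
# waterbodies on a projected km plane, streams carrying kittle-style route
# ids, major roads, two-census invasion histories for the two species, a
# watercraft-inspection survey, and an accessibility-biased reporting
# process. Everything below is reproducible from the single seed.

suppressPackageStartupMessages(library(aiskrige))

cfg <- landscape_config(seed = 1)
ls <- simulate_landscape(cfg)

out <- "results/landscape"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
wb <- cbind(ls$waterbodies, ls$reported[, -1])
write_geojson_points(wb, file.path(out, "waterbodies.geojson"))
write_geojson_lines(ls$streams, file.path(out, "streams.geojson"))
write_geojson_lines(ls$roads, file.path(out, "roads.geojson"))
write.csv(ls$surveys, file.path(out, "surveys.csv"), row.names = FALSE)

cat("simulated", nrow(ls$waterbodies), "waterbodies on a",
    paste(cfg$extent[c(2, 4)], collapse = " x "), "km extent\n")
cat("reported infestations (t1 -> t2):\n")
cat(sprintf("  zm : %3d -> %3d  (true %d -> %d)\n",
            sum(ls$reported$zm_t1), sum(ls$reported$zm_t2),
            sum(ls$truth$zm_t1), sum(ls$truth$zm_t2)))
cat(sprintf("  ewm: %3d -> %3d  (true %d -> %d)\n",
            sum(ls$reported$ewm_t1), sum(ls$reported$ewm_t2),
            sum(ls$truth$ewm_t1), sum(ls$truth$ewm_t2)))
cat(sprintf("surveys: %d records, %.1f%% eligible; network: %d edges over %d surveyed waterbodies\n",
            nrow(ls$surveys), 100 * mean(ls$surveys$eligible),
            nrow(ls$network$edges),
            length(unique(c(ls$network$edges$from, ls$network$edges$to)))))
cat("layers written under", out, "\n")
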