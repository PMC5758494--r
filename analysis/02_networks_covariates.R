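#!/usr/bin/env Rscript
# Stage 2: boater-traffic network, centrality choice, and the six
# waterbody-specific covariates for both censuses, with the Pearson
# screening that decides which variables may enter the co-kriging models.

suppressPackageStartupMessages(library(aiskrige))

ls <- simulate_landscape(landscape_config(seed = 1))
wb <- ls$waterbodies

cents <- list(
  eigenvector = eigenvector_centrality(ls$network),
  betweenness = betweenness_centrality(ls$network),
  degree = degree_centrality(ls$network)
)
choice <- select_centrality(
  cents, list(zm = ls$reported$zm_t2, ewm = ls$reported$ewm_t2)
)
cat("centrality correlations with reported status:\n")
print(round(choice$correlations, 3))
cat("chosen measure:", choice$measure, "\n\n")
v5 <- cents[[choice$measure]]$score[wb$id]

conn <- function(yr, sp) {
  inv <- wb$id[ls$reported[[paste0(sp, "_", yr)]] == 1]
  asg <- assign_streams(wb, ls$streams, invaded_ids = inv)
  unname(connectivity_to_invaded(asg, inv))
}
cov <- lapply(c(t1 = "t1", t2 = "t2"), function(yr) {
  assemble_covariates(
    wb, ls$reported[[paste0("zm_", yr)]], ls$reported[[paste0("ewm_", yr)]],
    conn(yr, "zm"), conn(yr, "ewm"), unname(v5), unname(ls$road_access),
    year = yr
  )
})

dir.create("results", showWarnings = FALSE)
write.csv(cov$t1, "results/covariates_t1.csv", row.names = FALSE)
write.csv(cov$t2, "results/covariates_t2.csv", row.names = FALSE)

cat("waterbody counts with each characteristic (t1 / t2):\n")
for (v in c("v1_zm", "v2_ewm", "v3_conn_zm", "v4_conn_ewm")) {
  cat(sprintf("  %-12s %4d / %4d\n", v, sum(cov$t1[[v]]), sum(cov$t2[[v]])))
}
cat(sprintf("  %-12s %4d (surveyed, shared across censuses)\n",
            "v5_eig", sum(cov$t1$v5_eig > 0)))

scr <- pearson_screen(cov$t1, threshold = 0.1)
cat("\nPearson correlations (first census):\n")
print(round(scr$matrix, 2))
write.csv(as.data.frame(scr$matrix), "results/correlations.csv")
cat("\nscreened candidates (r >= 0.1):\n")
cat("  zm :", paste(scr$candidates$zm, collapse = ", "), "\n")
cat("  ewm:", paste(scr$candidates$ewm, collapse = ", "), "\n")
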