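#!/usr/bin/env Rscript
# Step 1: reproduce the bundled SWOT-AHP case study (home-based exercise in
# China) end to end and write its tables, reports and figures to results/.

suppressPackageStartupMessages(library(swotahp))

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

cfg <- load_config(home_exercise_path())
res <- run_full_analysis(cfg)

print(res)

# per-group weight and consistency table (the published "comparison matrix
# and weights" layout)
weights_tab <- do.call(rbind, lapply(c("S", "W", "O", "T"), function(g) {
  blk <- res$groups[[g]]
  data.frame(
    group = g,
    factor = blk$factors$id,
    weight = round_half_away(blk$factors$weight, 4),
    lambda_max = blk$consistency$lambda_max,
    ci = round_half_away(blk$consistency$ci, 4),
    cr = blk$consistency$cr,
    consistent = blk$consistency$passes
  )
}))
write.csv(weights_tab, "results/group_weights.csv", row.names = FALSE)

# factor intensity table (weights x estimated strengths, signed)
intens_tab <- do.call(rbind, lapply(c("S", "W", "O", "T"), function(g) {
  blk <- res$groups[[g]]
  data.frame(
    group = g, factor = blk$factors$id,
    weight = round_half_away(blk$factors$weight, 4),
    strength = blk$factors$strength,
    intensity = blk$factors$intensity,
    total_intensity = blk$total_intensity
  )
}))
write.csv(intens_tab, "results/factor_intensities.csv", row.names = FALSE)

write_report(res, "results/report.json", format = "json")
write_report(res, "results/report.md", format = "markdown")
render_plots(res, "results/figures", format = "svg")

cat(sprintf(
  paste0(
    "\nFindings: every group passes the consistency check (max CR %.4f),\n",
    "the positive side dominates (U %.4f > V %.4f, rho %.4f), and the\n",
    "centroid lies in the first quadrant (theta %.2f deg): the %s strategy,\n",
    "pursued %sly, is the supported call.\n"
  ),
  max(vapply(res$groups, function(g) g$consistency$cr, numeric(1))),
  res$vector$U, res$vector$V, res$vector$rho, res$vector$theta_deg,
  res$strategy$quadrant_type, res$strategy$intensity_class
))
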