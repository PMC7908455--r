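# build the plain-list report payload with stable key order and pinned
# rounding (4 d.p. everywhere, azimuth 2 d.p.), shared by JSON and Markdown
report_payload <- function(analysis, digits = 4) {
  stopifnot(inherits(analysis, "swot_analysis"))
  r <- function(x, d = digits) as.numeric(round_half_away(x, d))
  groups <- lapply(analysis$groups[c("S", "W", "O", "T")], function(blk) {
    rep <- blk$consistency
    list(
      weights = stats::setNames(r(blk$factors$weight), blk$factors$id),
      lambda_max = r(rep$lambda_max),
      ci = r(rep$ci),
      ri = rep$ri,
      cr = r(rep$cr),
      consistent = rep$passes,
      factors = lapply(seq_len(nrow(blk$factors)), function(i) {
        list(
          id = blk$factors$id[i],
          label = blk$factors$label[i],
          weight = r(blk$factors$weight[i]),
          strength = blk$factors$strength[i],
          intensity = r(blk$factors$intensity[i])
        )
      }),
      total_intensity = r(blk$total_intensity)
    )
  })
  vec <- analysis$vector
  call <- analysis$strategy
  list(
    title = analysis$metadata$title,
    groups = groups,
    totals = as.list(stats::setNames(r(analysis$totals),
                                     names(analysis$totals))),
    strategic_vector = list(
      centroid = list(X = r(vec$centroid[["X"]]), Y = r(vec$centroid[["Y"]])),
      theta_deg = r(vec$theta_deg, 2),
      U = r(vec$U),
      V = r(vec$V),
      rho = r(vec$rho)
    ),
    strategy = list(
      quadrant_type = call$quadrant_type,
      adjacent = call$adjacent,
      intensity_class = call$intensity_class
    )
  )
}

#' Write an analysis report
#'
#' Serialises a [run_full_analysis()] result. The JSON form has stable key
#' order and pinned rounding (4 decimals; azimuth 2), so identical analyses
#' produce byte-identical files. The Markdown form mirrors the layout of
#' published SWOT-AHP tables: per-group weights with the consistency
#' diagnostics, factor strengths and intensities with group totals, and the
#' strategic vector with the strategy call. All numbers use `.` as the
#' decimal mark regardless of locale.
#'
#' @param analysis a `swot_analysis`.
#' @param path output file path.
#' @param format `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @examples
#' res <- run_full_analysis(load_config(home_exercise_path()))
#' write_report(res, file.path(tempdir(), "report.json"))
#' @export
write_report <- function(analysis, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  payload <- report_payload(analysis)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    swot_abort(paste0("output directory does not exist: ", dir),
               "swotahp_io_error")
  }
  if (format == "json") {
    txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                            null = "null", pretty = TRUE)
    writeLines(txt, path, useBytes = TRUE)
  } else {
    writeLines(report_markdown(payload), path, useBytes = TRUE)
  }
  invisible(path)
}

report_markdown <- function(p) {
  lines <- c(
    paste0("# ", p$title), "",
    "## Group weights and consistency", "",
    "| Group | Factor | Weight | lambda_max | CI | CR | Consistent |",
    "|---|---|---|---|---|---|---|"
  )
  for (g in c("S", "W", "O", "T")) {
    blk <- p$groups[[g]]
    for (i in seq_along(blk$factors)) {
      f <- blk$factors[[i]]
      first <- i == 1L
      lines <- c(lines, sprintf(
        "| %s | %s | %s | %s | %s | %s | %s |",
        if (first) g else "", f$id, fmt_num(f$weight),
        if (first) fmt_num(blk$lambda_max) else "",
        if (first) fmt_num(blk$ci) else "",
        if (first) fmt_num(blk$cr) else "",
        if (first) (if (blk$consistent) "yes" else "no") else ""
      ))
    }
  }
  lines <- c(
    lines, "",
    "## Factor intensities", "",
    "| Group | Factor | Weight | Estimated strength | Intensity | Total |",
    "|---|---|---|---|---|---|"
  )
  for (g in c("S", "W", "O", "T")) {
    blk <- p$groups[[g]]
    for (i in seq_along(blk$factors)) {
      f <- blk$factors[[i]]
      lines <- c(lines, sprintf(
        "| %s | %s | %s | %s | %s | %s |",
        if (i == 1L) g else "", f$id, fmt_num(f$weight),
        fmt_num(f$strength, 0), fmt_num(f$intensity),
        if (i == 1L) fmt_num(blk$total_intensity) else ""
      ))
    }
  }
  sv <- p$strategic_vector
  strat <- p$strategy
  c(
    lines, "",
    "## Strategic vector", "",
    sprintf("- Centroid: (%s, %s)", fmt_num(sv$centroid$X),
            fmt_num(sv$centroid$Y)),
    sprintf("- Azimuth theta: %s deg", fmt_num(sv$theta_deg, 2)),
    sprintf("- Positive intensity U: %s", fmt_num(sv$U)),
    sprintf("- Negative intensity V: %s", fmt_num(sv$V)),
    sprintf("- Intensity coefficient rho: %s", fmt_num(sv$rho)),
    sprintf(
      "- Strategy call: **%s**, %s",
      if (strat$quadrant_type == "boundary") {
        paste0("boundary (", paste(strat$adjacent, collapse = "/"), ")")
      } else {
        strat$quadrant_type
      },
      strat$intensity_class
    )
  )
}
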