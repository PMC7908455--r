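default_options <- function() {
  list(
    reciprocity_tol = 1e-6,
    strict_saaty = FALSE,
    cr_gate = "error",
    digits = 4
  )
}

#' Assemble a SWOT analysis configuration in code
#'
#' The programmatic equivalent of [load_config()]: four group blocks, each a
#' list with a `factors` data frame (columns `id`, `label`, optional
#' `description`, `strength`) and a `matrix` (anything accepted by
#' [comparison_matrix()]).
#'
#' @param groups named list with elements `S`, `W`, `O`, `T` as above.
#' @param metadata list with optional `title`, `analyst`, `date`.
#' @param options list overriding the defaults (reciprocity_tol 1e-6,
#'   strict_saaty FALSE, cr_gate "error", digits 4).
#' @return a validated `swot_config`.
#' @export
swot_config <- function(groups, metadata = list(), options = list()) {
  cfg <- list(
    metadata = utils::modifyList(
      list(title = "SWOT-AHP analysis", analyst = "", date = ""),
      metadata
    ),
    options = utils::modifyList(default_options(), options),
    groups = groups
  )
  validate_swot_config(cfg)
}

validate_swot_config <- function(cfg, dir = ".") {
  opts <- utils::modifyList(default_options(), cfg$options %||% list())
  groups <- cfg$groups
  missing <- setdiff(c("S", "W", "O", "T"), names(groups))
  if (length(missing)) {
    swot_abort(
      paste0("config is missing group(s): ", paste(missing, collapse = ", ")),
      "swotahp_schema_error"
    )
  }
  out <- list()
  for (g in c("S", "W", "O", "T")) {
    block <- groups[[g]]
    fac <- block$factors
    if (is.null(fac) || (is.data.frame(fac) && nrow(fac) == 0) ||
        (!is.data.frame(fac) && length(fac) == 0)) {
      swot_abort(paste0("groups$", g, "$factors is empty"),
                 "swotahp_schema_error")
    }
    if (!is.data.frame(fac)) {
      fac <- do.call(rbind, lapply(fac, function(f) {
        data.frame(
          id = f$id %||% NA_character_,
          label = f$label %||% (f$id %||% NA_character_),
          description = f$description %||% "",
          strength = as.numeric(f$strength %||% NA_real_),
          stringsAsFactors = FALSE
        )
      }))
    }
    if (!"description" %in% names(fac)) fac$description <- ""
    if (anyNA(fac$id) || anyNA(fac$strength)) {
      swot_abort(paste0("groups$", g, "$factors needs id and strength fields"),
                 "swotahp_schema_error")
    }
    presigned <- fac$strength < 0
    if (any(presigned)) {
      if (g %in% c("W", "T")) {
        warning(sprintf(
          "groups$%s: pre-signed strengths normalised to magnitudes", g
        ), call. = FALSE)
        fac$strength <- abs(fac$strength)
      } else {
        swot_abort(paste0("groups$", g, ": negative strength for a positive group"),
                   "swotahp_schema_error")
      }
    }
    if (any(fac$strength > 5)) {
      swot_abort(paste0("groups$", g, ": strength outside [0, 5]"),
                 "swotahp_schema_error")
    }

    mat <- block[["matrix"]]
    if (is.null(mat) && !is.null(block[["matrix_csv"]])) {
      mat <- read_matrix_csv(
        file.path(dir, block[["matrix_csv"]]),
        tol = opts$reciprocity_tol,
        check_saaty = if (opts$strict_saaty) "strict" else "warn"
      )
    }
    if (is.null(mat)) {
      swot_abort(paste0("groups$", g, " has neither matrix nor matrix_csv"),
                 "swotahp_schema_error")
    }
    if (!inherits(mat, "comparison_matrix")) {
      mat <- tryCatch(
        comparison_matrix(
          mat, labels = fac$id, tol = opts$reciprocity_tol,
          check_saaty = if (opts$strict_saaty) "strict" else "warn"
        ),
        swotahp_shape_error = function(e) {
          swot_abort(paste0("groups$", g, "$matrix: ", conditionMessage(e)),
                     "swotahp_schema_error")
        }
      )
    }
    if (nrow(mat) != nrow(fac)) {
      swot_abort(
        sprintf("groups$%s: %d factors but a matrix of order %d",
                g, nrow(fac), nrow(mat)),
        "swotahp_schema_error"
      )
    }
    if (!identical(unname(rownames(mat)), unname(fac$id))) {
      swot_abort(paste0("groups$", g, ": matrix labels do not match factor ids"),
                 "swotahp_schema_error")
    }
    out[[g]] <- list(factors = fac, matrix = mat)
  }
  structure(
    list(
      metadata = utils::modifyList(
        list(title = "SWOT-AHP analysis", analyst = "", date = ""),
        cfg$metadata %||% list()
      ),
      options = opts,
      groups = out
    ),
    class = "swot_config"
  )
}

#' Load a SWOT analysis configuration
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) configuration with four
#' group blocks (`S`, `W`, `O`, `T`), each holding a factor list (id, label,
#' optional description, strength on the 0-5 scale) and a pairwise-comparison
#' matrix, given inline as rows (cells may be decimals or fraction strings
#' like `"1/3"`) or as a `matrix_csv` path resolved relative to the config
#' file. Everything is validated on load; schema violations report the
#' offending field.
#'
#' @param path config file path.
#' @return a `swot_config` object.
#' @seealso [swot_config()], [run_full_analysis()], [write_config()]
#' @examples
#' cfg <- load_config(home_exercise_path())
#' names(cfg$groups)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    swot_abort(paste0("config file not found: ", path), "swotahp_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    swot_abort(paste0("unsupported config format: .", ext), "swotahp_io_error")
  }
  validate_swot_config(raw, dir = dirname(path))
}

# serialize a judgment losslessly and readably: integers and unit fractions in
# questionnaire notation, anything else as a full-precision decimal
format_judgment <- function(v) {
  if (abs(v - round(v)) < 1e-12 && round(v) >= 1) {
    return(as.character(as.integer(round(v))))
  }
  inv <- 1 / v
  if (abs(inv - round(inv)) < 1e-9 && round(inv) >= 2) {
    return(paste0("1/", as.integer(round(inv))))
  }
  sprintf("%.17g", v)
}

#' Write a SWOT analysis configuration to YAML
#'
#' Inverse of [load_config()]: matrices are serialised cell-by-cell in
#' questionnaire notation (integers, `"1/3"`-style fractions, or
#' full-precision decimals), so a written config reloads to exactly the same
#' numbers. Output is deterministic: the same config always yields the same
#' bytes.
#'
#' @param config a `swot_config`.
#' @param path output file path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "swot_config"))
  ser_group <- function(block) {
    fac <- block$factors
    list(
      factors = lapply(seq_len(nrow(fac)), function(i) {
        f <- list(
          id = fac$id[i], label = fac$label[i],
          strength = fac$strength[i]
        )
        if (nzchar(fac$description[i])) f$description <- fac$description[i]
        f
      }),
      matrix = lapply(seq_len(nrow(block$matrix)), function(i) {
        lapply(block$matrix[i, ], format_judgment)
      })
    )
  }
  doc <- list(
    metadata = config$metadata,
    options = config$options,
    groups = lapply(config$groups, ser_group)
  )
  txt <- yaml::as.yaml(doc, indent.mapping.sequence = TRUE, precision = 12)
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

#' Path to the bundled home-based-exercise case study
#'
#' The package ships, as a worked fixture, the published SWOT-AHP study of
#' the development strategy of home-based exercise in China: 13 factors in
#' four groups, the four expert comparison matrices, and the 0-5 estimated
#' strengths.
#'
#' @return file path of the bundled YAML config.
#' @examples
#' cfg <- load_config(home_exercise_path())
#' @export
home_exercise_path <- function() {
  system.file("extdata", "home_exercise_china.yaml", package = "swotahp",
              mustWork = TRUE)
}
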