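# Severity categories, band schemes and criterion schemes: the configurable
# "what to measure and how to band it" layer of the framework.

#' The five severity categories
#'
#' Severity of deviation from normality is graded on five ordinal categories
#' mirroring the legal severity classes of Directive 2010/63/EU plus the two
#' operationally necessary extremes: no change, and change beyond the upper
#' severe limit (which includes death).
#'
#' @return Character vector of the five category labels, in ordinal order
#'   (ordinals 0 to 4).
#' @examples
#' severity_levels()
#' @export
severity_levels <- function() {
  c("normal", "mild", "moderate", "severe", "beyond_severe")
}

#' Coerce labels or ordinals to a severity category factor
#'
#' @param x Character labels (see [severity_levels()]), integers 0-4, or an
#'   existing severity factor.
#' @return An ordered factor with the five severity levels.
#' @examples
#' as_severity(c("mild", "severe"))
#' as_severity(c(0, 4))
#' @export
as_severity <- function(x) {
  lv <- severity_levels()
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    bad <- !is.na(x) & (x < 0 | x > 4 | x != round(x))
    if (any(bad)) {
      rlang::abort(sprintf(
        "severity ordinals must be integers in 0..4; offending value(s): %s",
        paste(unique(x[bad]), collapse = ", ")
      ))
    }
    x <- lv[as.integer(x) + 1L]
  } else {
    x <- as.character(x)
    bad <- !is.na(x) & !(x %in% lv)
    if (any(bad)) {
      rlang::abort(sprintf(
        "unknown severity label(s): %s (expected one of %s)",
        paste(unique(x[bad]), collapse = ", "),
        paste(lv, collapse = ", ")
      ))
    }
  }
  factor(x, levels = lv, ordered = TRUE)
}

#' Ordinal score of a severity category
#'
#' @param x Anything [as_severity()] accepts.
#' @return Integer vector of ordinals 0-4 (`normal` = 0, ...,
#'   `beyond_severe` = 4).
#' @examples
#' severity_ordinal("severe")
#' @export
severity_ordinal <- function(x) {
  as.integer(as_severity(x)) - 1L
}

#' Define a band scheme
#'
#' A band scheme partitions the non-negative deviation axis into five bands
#' via four strictly increasing upper boundaries `b0 < b1 < b2 < b3`:
#' `[0, b0]`, `(b0, b1]`, `(b1, b2]`, `(b2, b3]`, `(b3, Inf)`. Bands are
#' closed on the right, so a deviation exactly at a boundary falls in the
#' lower (less severe) band. Band indices 0-4 are the ordinal severity
#' scores.
#'
#' @param boundaries Numeric vector of four strictly increasing, finite,
#'   non-negative thresholds, in deviation units.
#' @param deviation_kind How deviation from baseline is measured:
#'   `"absolute"` (criterion units) or `"percent"` (percent of baseline).
#' @param direction Which direction of change counts as a deviation:
#'   `"increase"`, `"decrease"`, or `"either"`. One-sided modes map
#'   opposite-direction excursions to zero deviation.
#' @return A `band_scheme` object.
#' @examples
#' band_scheme(c(0.2, 1, 2, 3), "absolute", "increase")
#' @export
band_scheme <- function(boundaries,
                        deviation_kind = c("absolute", "percent"),
                        direction = c("increase", "decrease", "either")) {
  deviation_kind <- rlang::arg_match(deviation_kind)
  direction <- rlang::arg_match(direction)
  problems <- validate_band_boundaries(boundaries)
  if (length(problems)) {
    rlang::abort(c("invalid band scheme", problems))
  }
  structure(
    list(
      boundaries = as.numeric(boundaries),
      deviation_kind = deviation_kind,
      direction = direction
    ),
    class = "band_scheme"
  )
}

validate_band_boundaries <- function(boundaries) {
  problems <- character()
  if (!is.numeric(boundaries) || length(boundaries) != 4L) {
    return("boundaries: exactly four numeric thresholds are required")
  }
  if (any(!is.finite(boundaries))) {
    problems <- c(problems, "boundaries: all thresholds must be finite")
  }
  if (any(boundaries < 0, na.rm = TRUE)) {
    problems <- c(problems, "boundaries: thresholds must be non-negative")
  }
  if (all(is.finite(boundaries)) && any(diff(boundaries) <= 0)) {
    problems <- c(problems, "boundaries not strictly increasing")
  }
  problems
}

#' @export
print.band_scheme <- function(x, ...) {
  cat(sprintf(
    "<band_scheme> %s %s; bands [0,%g] (%g,%g] (%g,%g] (%g,%g] (%g,Inf)\n",
    x$deviation_kind, x$direction,
    x$boundaries[1], x$boundaries[1], x$boundaries[2], x$boundaries[2],
    x$boundaries[3], x$boundaries[3], x$boundaries[4], x$boundaries[4]
  ))
  invisible(x)
}

#' Define a criterion scheme
#'
#' A criterion scheme names one scorable sign (e.g. body temperature),
#' states its measurement units, and attaches the band scheme that converts
#' its deviations from baseline into ordinal scores.
#'
#' @param name Identifier, unique within a scheme set.
#' @param units Free-text measurement units (e.g. `"°C"`, `"g"`).
#' @param boundaries,deviation_kind,direction Passed to [band_scheme()];
#'   alternatively supply a ready-made scheme via `bands`.
#' @param bands A `band_scheme`; overrides the three arguments above.
#' @param baseline_source Where the "normal" reference value comes from:
#'   `"self_baseline"` (each animal's own pre-treatment value, the default)
#'   or `"control_mean"` (mean of a designated control group at the same
#'   timepoint).
#' @return A `criterion_scheme` object.
#' @examples
#' criterion_scheme("temperature", "°C", c(0.2, 1, 2, 3),
#'                  "absolute", "increase")
#' @export
criterion_scheme <- function(name, units, boundaries = NULL,
                             deviation_kind = "absolute",
                             direction = "increase",
                             bands = NULL,
                             baseline_source = c("self_baseline", "control_mean")) {
  baseline_source <- rlang::arg_match(baseline_source)
  if (is.null(bands)) {
    bands <- band_scheme(boundaries, deviation_kind, direction)
  }
  if (!inherits(bands, "band_scheme")) {
    rlang::abort("`bands` must be a band_scheme object")
  }
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    rlang::abort("`name` must be a non-empty string")
  }
  structure(
    list(
      name = name,
      units = as.character(units),
      bands = bands,
      baseline_source = baseline_source
    ),
    class = "criterion_scheme"
  )
}

#' @export
print.criterion_scheme <- function(x, ...) {
  cat(sprintf(
    "<criterion_scheme> %s [%s], %s %s, boundaries %s, baseline: %s\n",
    x$name, x$units, x$bands$deviation_kind, x$bands$direction,
    paste(x$bands$boundaries, collapse = "/"), x$baseline_source
  ))
  invisible(x)
}

#' Assemble a scheme set
#'
#' A scheme set bundles the criterion schemes of a study with the per-group
#' severity limits (the maximum severity an individual animal may reach
#' before action is mandated) and the predicted severity classifications
#' recorded on the project licence.
#'
#' @param criteria List of [criterion_scheme()] objects (at least one),
#'   with unique names.
#' @param severity_limits Named character (or ordinal) vector mapping
#'   group id to the group's individual severity limit. May be empty.
#' @param predicted_classifications Named vector mapping group id to the
#'   predicted severity classification. May be empty.
#' @return A validated `scheme_set` object.
#' @examples
#' ss <- scheme_set(
#'   criteria = list(
#'     criterion_scheme("temperature", "°C", c(0.2, 1, 2, 3),
#'                      "absolute", "increase")
#'   ),
#'   severity_limits = c(low_dose = "mild"),
#'   predicted_classifications = c(low_dose = "mild")
#' )
#' @export
scheme_set <- function(criteria,
                       severity_limits = character(),
                       predicted_classifications = character()) {
  problems <- character()
  if (!is.list(criteria) || length(criteria) == 0L) {
    problems <- c(problems, "criteria: at least one criterion scheme is required")
  } else {
    ok <- vapply(criteria, inherits, logical(1), "criterion_scheme")
    if (!all(ok)) {
      problems <- c(problems,
                    sprintf("criteria[%s]: not a criterion_scheme",
                            paste(which(!ok), collapse = ",")))
    } else {
      nms <- vapply(criteria, function(cr) cr$name, character(1))
      dup <- unique(nms[duplicated(nms)])
      if (length(dup)) {
        problems <- c(problems,
                      sprintf("criteria: duplicate name(s): %s",
                              paste(dup, collapse = ", ")))
      }
      names(criteria) <- nms
    }
  }
  severity_limits <- coerce_group_map(severity_limits, "severity_limits")
  predicted_classifications <-
    coerce_group_map(predicted_classifications, "predicted_classifications")
  if (length(problems)) {
    rlang::abort(c("invalid scheme set", problems))
  }
  structure(
    list(
      criteria = criteria,
      severity_limits = severity_limits,
      predicted_classifications = predicted_classifications
    ),
    class = "scheme_set"
  )
}

coerce_group_map <- function(x, what) {
  if (length(x) == 0L) {
    out <- character()
    return(out)
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    rlang::abort(sprintf("%s: every entry must be named by group id", what))
  }
  out <- as.character(as_severity(unlist(x, use.names = FALSE)))
  names(out) <- names(x)
  out
}

#' @export
print.scheme_set <- function(x, ...) {
  cat(sprintf("<scheme_set> %d criteria\n", length(x$criteria)))
  for (cr in x$criteria) print(cr)
  if (length(x$severity_limits)) {
    cat("severity limits: ",
        paste(sprintf("%s=%s", names(x$severity_limits), x$severity_limits),
              collapse = ", "), "\n", sep = "")
  }
  if (length(x$predicted_classifications)) {
    cat("predicted classifications: ",
        paste(sprintf("%s=%s", names(x$predicted_classifications),
                      x$predicted_classifications),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Validate a raw scheme configuration
#'
#' Turns a parsed configuration (nested lists, as produced by reading the
#' YAML/JSON scheme file, or built programmatically) into a validated
#' [scheme_set()]. All violations are collected and reported together with
#' their field paths.
#'
#' The expected structure is a list with a `criteria` element (a list of
#' entries with fields `name`, `units`, `deviation_kind`, `direction`,
#' `boundaries` (length-4), and optional `baseline_source`) and an optional
#' `groups` element (a named list with per-group `severity_limit` and
#' `predicted_classification`).
#'
#' @param raw_scheme Nested list configuration.
#' @return A `scheme_set`.
#' @examples
#' raw <- list(criteria = list(list(
#'   name = "temperature", units = "C", deviation_kind = "absolute",
#'   direction = "increase", boundaries = c(0.2, 1, 2, 3)
#' )))
#' validate_scheme(raw)
#' @export
validate_scheme <- function(raw_scheme) {
  if (!is.list(raw_scheme)) {
    rlang::abort("scheme configuration must be a list")
  }
  problems <- character()
  criteria <- list()
  raw_criteria <- raw_scheme$criteria
  if (is.null(raw_criteria) || length(raw_criteria) == 0L) {
    problems <- c(problems, "criteria: empty or missing criteria list")
  } else {
    for (i in seq_along(raw_criteria)) {
      cr <- raw_criteria[[i]]
      path <- sprintf("criteria[%d]", i)
      local_problems <- character()
      if (!is.list(cr)) {
        problems <- c(problems, sprintf("%s: must be a mapping", path))
        next
      }
      for (field in c("name", "units", "deviation_kind", "direction",
                      "boundaries")) {
        if (is.null(cr[[field]])) {
          local_problems <- c(local_problems,
                              sprintf("%s.%s: missing", path, field))
        }
      }
      if (!is.null(cr$deviation_kind) &&
          !cr$deviation_kind %in% c("absolute", "percent")) {
        local_problems <- c(local_problems,
                            sprintf("%s.deviation_kind: unknown kind '%s'",
                                    path, cr$deviation_kind))
      }
      if (!is.null(cr$direction) &&
          !cr$direction %in% c("increase", "decrease", "either")) {
        local_problems <- c(local_problems,
                            sprintf("%s.direction: unknown direction '%s'",
                                    path, cr$direction))
      }
      if (!is.null(cr$boundaries)) {
        bp <- validate_band_boundaries(unlist(cr$boundaries))
        if (length(bp)) {
          local_problems <- c(local_problems,
                              sprintf("%s.%s", path, bp))
        }
      }
      bs <- cr$baseline_source %||% "self_baseline"
      if (!bs %in% c("self_baseline", "control_mean")) {
        local_problems <- c(local_problems,
                            sprintf("%s.baseline_source: unknown source '%s'",
                                    path, bs))
      }
      if (length(local_problems)) {
        problems <- c(problems, local_problems)
      } else {
        criteria[[length(criteria) + 1L]] <- criterion_scheme(
          name = cr$name, units = cr$units,
          boundaries = as.numeric(unlist(cr$boundaries)),
          deviation_kind = cr$deviation_kind, direction = cr$direction,
          baseline_source = bs
        )
      }
    }
    raw_names <- unlist(lapply(raw_criteria, function(cr) {
      if (is.list(cr) && !is.null(cr$name)) cr$name else NULL
    }))
    dup <- unique(raw_names[duplicated(raw_names)])
    if (length(dup)) {
      problems <- c(problems,
                    sprintf("criteria: duplicate name(s): %s",
                            paste(dup, collapse = ", ")))
    }
  }
  limits <- character()
  preds <- character()
  if (!is.null(raw_scheme$groups)) {
    for (g in names(raw_scheme$groups)) {
      entry <- raw_scheme$groups[[g]]
      for (field in c("severity_limit", "predicted_classification")) {
        val <- entry[[field]]
        if (is.null(val)) next
        parsed <- tryCatch(as.character(as_severity(val)), error = function(e) NA)
        if (is.na(parsed)) {
          problems <- c(problems,
                        sprintf("groups.%s.%s: unknown severity category '%s'",
                                g, field, val))
        } else if (field == "severity_limit") {
          limits[[g]] <- parsed
        } else {
          preds[[g]] <- parsed
        }
      }
    }
  }
  if (length(problems)) {
    rlang::abort(c("scheme validation failed", problems))
  }
  scheme_set(criteria, severity_limits = limits,
             predicted_classifications = preds)
}

#' Read and write scheme configuration files
#'
#' The on-disk format is YAML (or JSON, selected by file extension) with a
#' top-level `criteria:` list and an optional `groups:` map, plus a
#' `format_version` field. See [validate_scheme()] for the schema.
#'
#' @param path File path. `.json` is parsed with jsonlite, anything else
#'   with yaml.
#' @return `read_scheme()` returns a validated `scheme_set`;
#'   `write_scheme()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_scheme(rat_toxicity_scheme(), f)
#' ss <- read_scheme(f)
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("scheme file not found: %s", path))
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  raw$format_version <- NULL
  validate_scheme(raw)
}

#' @param scheme A `scheme_set` to serialise.
#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "scheme_set"))
  raw <- list(
    format_version = 1L,
    criteria = unname(lapply(scheme$criteria, function(cr) {
      list(
        name = cr$name,
        units = cr$units,
        deviation_kind = cr$bands$deviation_kind,
        direction = cr$bands$direction,
        boundaries = cr$bands$boundaries,
        baseline_source = cr$baseline_source
      )
    }))
  )
  groups <- union(names(scheme$severity_limits),
                  names(scheme$predicted_classifications))
  if (length(groups)) {
    raw$groups <- lapply(stats::setNames(groups, groups), function(g) {
      entry <- list()
      if (g %in% names(scheme$severity_limits)) {
        entry$severity_limit <- scheme$severity_limits[[g]]
      }
      if (g %in% names(scheme$predicted_classifications)) {
        entry$predicted_classification <- scheme$predicted_classifications[[g]]
      }
      entry
    })
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(raw, path)
  }
  invisible(path)
}

#' The built-in two-criterion rat toxicity scheme
#'
#' The worked example scheme: body temperature scored on absolute increase
#' above baseline with band boundaries 0.2/1/2/3 degrees C, and body weight
#' scored on percent loss with boundaries 5/10/20/30 %. The low-dose group
#' carries a mild severity limit and classification; the high-dose group a
#' severe one.
#'
#' @return A `scheme_set` with criteria `temperature` and `body_weight` and
#'   groups `low_dose` and `high_dose`.
#' @examples
#' rat_toxicity_scheme()
#' @export
rat_toxicity_scheme <- function() {
  scheme_set(
    criteria = list(
      criterion_scheme(
        "temperature", "°C",
        boundaries = c(0.2, 1, 2, 3),
        deviation_kind = "absolute", direction = "increase"
      ),
      criterion_scheme(
        "body_weight", "g",
        boundaries = c(5, 10, 20, 30),
        deviation_kind = "percent", direction = "decrease"
      )
    ),
    severity_limits = c(low_dose = "mild", high_dose = "severe"),
    predicted_classifications = c(low_dose = "mild", high_dose = "severe")
  )
}

#' Tidy a scheme set into a tibble
#'
#' @param x A `scheme_set`.
#' @param ... Unused.
#' @return A tibble with one row per criterion: name, units, deviation kind,
#'   direction, the four band boundaries `b0`-`b3`, and baseline source.
#' @examples
#' tidy(rat_toxicity_scheme())
#' @export
tidy.scheme_set <- function(x, ...) {
  purrr::map_dfr(x$criteria, function(cr) {
    tibble::tibble(
      criterion = cr$name,
      units = cr$units,
      deviation_kind = cr$bands$deviation_kind,
      direction = cr$bands$direction,
      b0 = cr$bands$boundaries[1],
      b1 = cr$bands$boundaries[2],
      b2 = cr$bands$boundaries[3],
      b3 = cr$bands$boundaries[4],
      baseline_source = cr$baseline_source
    )
  })
}
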