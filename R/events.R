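# Raw analytics records and psychosocial measures: validation and file I/O.
# A page visit is one timestamped view of one program page by one user, with
# a flag marking login events; timestamps carry whole-second resolution.

VISIT_COLUMNS <- c("user_id", "timestamp", "is_login", "component_id")
PSYCH_COLUMNS <- c(
  "user_id", "timepoint", "distress", "depressive", "intrusive_avoidant",
  "sc_partner", "sc_family"
)
TIMEPOINTS <- c("baseline", "m1", "m2", "m3")

# ISO-8601 UTC, whole seconds only ("2024-01-02T08:30:05Z" or with a space).
parse_timestamp <- function(x) {
  x <- trimws(x)
  out <- rep(as.POSIXct(NA), length(x))
  ok <- grepl(
    "^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}:\\d{2}Z?$", x
  ) & !grepl("\\.", x)
  if (any(ok)) {
    clean <- gsub("Z$", "", gsub("T", " ", x[ok]))
    parsed <- as.POSIXct(clean, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
    out[ok] <- parsed
  }
  attr(out, "tzone") <- "UTC"
  out
}

format_timestamp <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

parse_logical_flag <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

validate_visits <- function(visits) {
  if (!is.data.frame(visits)) stop("visits must be a data frame", call. = FALSE)
  missing_cols <- setdiff(VISIT_COLUMNS, names(visits))
  if (length(missing_cols) > 0) {
    stop("visits are missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!inherits(visits$timestamp, "POSIXct")) {
    stop("visits$timestamp must be POSIXct", call. = FALSE)
  }
  if (anyNA(visits$timestamp) || anyNA(visits$user_id) ||
    anyNA(visits$is_login)) {
    stop("visits contain missing user_id, timestamp or is_login",
      call. = FALSE
    )
  }
  invisible(visits)
}

#' Attach component categories from a catalog
#'
#' Adds a `category` column to a visit table via catalog lookup. Visits with
#' no component (for example the landing page recorded at login) get `NA`;
#' visits referencing an id absent from the catalog are kept with category
#' `"unknown"` (excluded from activity counts) and raise one warning.
#'
#' @param visits A visit tibble (see [read_visits()]).
#' @param catalog A catalog tibble.
#' @return `visits` with a `category` column.
#' @export
attach_categories <- function(visits, catalog) {
  validate_visits(visits)
  validate_catalog(catalog)
  idx <- match(visits$component_id, catalog$component_id)
  category <- catalog$category[idx]
  unknown <- !is.na(visits$component_id) & is.na(idx)
  if (any(unknown)) {
    warning(
      sum(unknown), " visit(s) reference component ids absent from the ",
      "catalog (kept with category 'unknown'): ",
      paste(unique(visits$component_id[unknown]), collapse = ", "),
      call. = FALSE
    )
    category[unknown] <- "unknown"
  }
  visits$category <- category
  visits
}

#' Read timestamped page-visit logs
#'
#' Reads a page-visit log from CSV or JSONL (one JSON object per line) with
#' fields `user_id`, `timestamp` (ISO-8601 UTC, second resolution),
#' `is_login` and `component_id` (may be empty for landing pages). Rows are
#' returned sorted by user and timestamp; ties at equal timestamps keep file
#' order. Parse failures are reported with their row number.
#'
#' @param path File path; format inferred from the extension (`.jsonl`/
#'   `.json` for JSON lines, anything else CSV) unless `format` is given.
#' @param catalog Optional catalog tibble; when supplied, a `category`
#'   column is attached via [attach_categories()].
#' @param format `"csv"`, `"jsonl"` or `NULL` (infer).
#' @return A tibble of visits.
#' @export
read_visits <- function(path, catalog = NULL, format = NULL) {
  format <- format %||% infer_format(path)
  raw <- if (format == "jsonl") {
    read_jsonl_raw(path, VISIT_COLUMNS)
  } else {
    readr::read_csv(path,
      col_types = readr::cols(.default = readr::col_character())
    )
  }
  missing_cols <- setdiff(VISIT_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("visit file is missing columns: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  ts <- parse_timestamp(raw$timestamp)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))
    stop("malformed timestamp in row(s): ",
      paste(head(bad, 10), collapse = ", "),
      if (length(bad) > 10) " ..." else "",
      call. = FALSE
    )
  }
  logins <- parse_logical_flag(raw$is_login)
  if (anyNA(logins)) {
    bad <- which(is.na(logins))
    stop("malformed is_login flag in row(s): ",
      paste(head(bad, 10), collapse = ", "),
      call. = FALSE
    )
  }
  comp <- as.character(raw$component_id)
  comp[!is.na(comp) & !nzchar(comp)] <- NA_character_
  visits <- tibble(
    user_id = as.character(raw$user_id),
    timestamp = ts,
    is_login = logins,
    component_id = comp
  )
  visits <- visits[order(visits$user_id, visits$timestamp), , drop = FALSE]
  validate_visits(visits)
  if (!is.null(catalog)) visits <- attach_categories(visits, catalog)
  visits
}

#' Write a page-visit log
#'
#' Serializes visits as CSV or JSONL with ISO-8601 UTC timestamps; a
#' write-then-read round trip reproduces the table exactly.
#'
#' @inheritParams read_visits
#' @param visits A visit tibble.
#' @return `path`, invisibly.
#' @export
write_visits <- function(visits, path, format = NULL) {
  validate_visits(visits)
  format <- format %||% infer_format(path)
  out <- tibble(
    user_id = visits$user_id,
    timestamp = format_timestamp(visits$timestamp),
    is_login = visits$is_login,
    component_id = visits$component_id
  )
  if (format == "jsonl") {
    write_jsonl_raw(out, path)
  } else {
    readr::write_csv(out, path, na = "")
  }
  invisible(path)
}

infer_format <- function(path) {
  if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
}

read_jsonl_raw <- function(path, columns) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(as_tibble(setNames(
      rep(list(character()), length(columns)), columns
    )))
  }
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
      error = function(e) stop("malformed JSON in row ", i, call. = FALSE)
    )
    vapply(columns, function(col) {
      v <- rec[[col]]
      if (is.null(v) || length(v) == 0 || is.na(v)) NA_character_ else as.character(v)
    }, character(1))
  })
  as_tibble(do.call(rbind, rows))
}

write_jsonl_raw <- function(df, path) {
  lines <- vapply(seq_len(nrow(df)), function(i) {
    jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path)
}

validate_psychosocial <- function(records) {
  if (!is.data.frame(records)) {
    stop("psychosocial records must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(PSYCH_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stop("psychosocial records missing columns: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  bad_tp <- !records$timepoint %in% TIMEPOINTS
  if (any(bad_tp)) {
    stop("invalid timepoint in row(s): ",
      paste(head(which(bad_tp), 10), collapse = ", "),
      call. = FALSE
    )
  }
  bad_dt <- !is.na(records$distress) &
    (records$distress < 0 | records$distress > 10)
  if (any(bad_dt)) {
    stop("distress outside [0, 10] in row(s): ",
      paste(head(which(bad_dt), 10), collapse = ", "),
      call. = FALSE
    )
  }
  for (col in c("depressive", "intrusive_avoidant", "sc_partner", "sc_family")) {
    bad <- !is.na(records[[col]]) & records[[col]] < 0
    if (any(bad)) {
      stop(col, " negative in row(s): ",
        paste(head(which(bad), 10), collapse = ", "),
        call. = FALSE
      )
    }
  }
  key <- paste(records$user_id, records$timepoint)
  if (anyDuplicated(key)) {
    stop("duplicate (user_id, timepoint): ",
      paste(unique(key[duplicated(key)]), collapse = "; "),
      call. = FALSE
    )
  }
  invisible(records)
}

#' Read or write psychosocial measure tables
#'
#' One row per user and timepoint (`baseline`, `m1`, `m2`, `m3`) holding
#' instrument totals: `distress` (0-10 single-item rating), `depressive`
#' (CES-D total), `intrusive_avoidant` (IES total) and the two
#' social-constraints totals `sc_partner` / `sc_family` (may be missing,
#' e.g. for unpartnered users). Bounds and duplicate records are validated.
#'
#' @param path CSV file path.
#' @return `read_psychosocial()` returns a validated tibble;
#'   `write_psychosocial()` returns `path` invisibly.
#' @export
read_psychosocial <- function(path) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character())
  )
  missing_cols <- setdiff(PSYCH_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("psychosocial file missing columns: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  num <- function(col) {
    x <- trimws(as.character(raw[[col]]))
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & nzchar(x) & is.na(out))
    if (length(bad) > 0) {
      stop("malformed ", col, " in row(s): ",
        paste(head(bad, 10), collapse = ", "),
        call. = FALSE
      )
    }
    out
  }
  records <- tibble(
    user_id = as.character(raw$user_id),
    timepoint = trimws(as.character(raw$timepoint)),
    distress = num("distress"),
    depressive = num("depressive"),
    intrusive_avoidant = num("intrusive_avoidant"),
    sc_partner = num("sc_partner"),
    sc_family = num("sc_family")
  )
  validate_psychosocial(records)
  records[order(records$user_id, match(records$timepoint, TIMEPOINTS)), ,
    drop = FALSE
  ]
}

#' @rdname read_psychosocial
#' @param records A psychosocial tibble.
#' @export
write_psychosocial <- function(records, path) {
  validate_psychosocial(records)
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' Access windows
#'
#' One row per user giving the instant credentials were issued and the
#' length of the access period (84 days = 12 weeks by default). Study months
#' are counted in 28-day blocks from `access_start`.
#'
#' @param user_id Character vector of user ids.
#' @param access_start POSIXct start instants (recycled if length 1).
#' @param access_days Positive integer access period length in days.
#' @return A tibble with columns `user_id`, `access_start`, `access_days`.
#' @export
access_windows <- function(user_id, access_start, access_days = 84L) {
  if (any(access_days <= 0)) stop("access_days must be positive", call. = FALSE)
  tibble(
    user_id = as.character(user_id),
    access_start = rep_len(access_start, length(user_id)),
    access_days = as.integer(rep_len(access_days, length(user_id)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
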