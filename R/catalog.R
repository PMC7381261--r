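# Component catalog: the inventory of program pages. The four countable
# categories form the denominator of every "activity" percentage; intro and
# home pages are navigational and never counted.

CATALOG_COLUMNS <- c("component_id", "category", "title", "parent_module")

COUNTABLE_CATEGORIES <- c("module_section", "exercise", "video", "resource")
NAV_CATEGORIES <- c("intro", "home")
ALL_CATEGORIES <- c(COUNTABLE_CATEGORIES, NAV_CATEGORIES)

CATEGORY_PREFIX <- c(
  module_section = "sec", exercise = "ex", video = "vid",
  resource = "res", intro = "intro", home = "home"
)

#' Countable component categories
#'
#' The component categories that enter the activity denominator: module
#' sections, exercises, videos and resource pages. Intro and home pages are
#' representable in a catalog (so logs may reference them) but are
#' navigational and never counted toward activity.
#'
#' @return Character vector of the four countable category names.
#' @export
countable_categories <- function() COUNTABLE_CATEGORIES

validate_catalog <- function(catalog) {
  if (!is.data.frame(catalog)) {
    stop("catalog must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(CATALOG_COLUMNS, names(catalog))
  if (length(missing_cols) > 0) {
    stop("catalog is missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(catalog$component_id)) {
    dup <- unique(catalog$component_id[duplicated(catalog$component_id)])
    stop("duplicate component_id in catalog: ", paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- setdiff(unique(catalog$category), ALL_CATEGORIES)
  if (length(bad) > 0) {
    stop("unknown catalog categories: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(catalog)
}

empty_catalog <- function() {
  tibble(
    component_id = character(), category = character(),
    title = character(), parent_module = character()
  )
}

#' Build a component catalog with synthetic identifiers
#'
#' Constructs a catalog holding the requested number of components per
#' category, with opaque per-category identifiers and generic titles. Useful
#' for simulations and for programs whose real page inventory is not needed.
#'
#' @param counts Named vector or list mapping category names (see
#'   [countable_categories()], plus `"intro"` and `"home"`) to non-negative
#'   integer component counts. An empty `counts` yields an empty catalog.
#' @return A tibble with columns `component_id`, `category`, `title`,
#'   `parent_module`.
#' @examples
#' build_catalog(c(module_section = 17, exercise = 20, video = 90, resource = 13))
#' @export
build_catalog <- function(counts = integer()) {
  counts <- unlist(counts)
  if (length(counts) == 0) {
    return(empty_catalog())
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be named by category", call. = FALSE)
  }
  bad <- setdiff(names(counts), ALL_CATEGORIES)
  if (length(bad) > 0) {
    stop("unknown categories: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  rows <- lapply(names(counts), function(cat) {
    k <- as.integer(counts[[cat]])
    if (k == 0) {
      return(empty_catalog())
    }
    tibble(
      component_id = sprintf("%s_%03d", CATEGORY_PREFIX[[cat]], seq_len(k)),
      category = cat,
      title = sprintf("%s %03d", gsub("_", " ", cat), seq_len(k)),
      parent_module = NA_character_
    )
  })
  validate_catalog(bind_rows(rows))
}

# The five learning modules and their 17 topical section pages. A module
# heading is a tab, not itself a tracked page; every named section below is
# one countable module_section page.
program_outline <- function() {
  list(
    "Are my reactions normal?" = c(
      "Fears and anger",
      "Exploring other emotions",
      "Why might I think about cancer differently than other women?"
    ),
    "What does this diagnosis mean?" = c(
      "Why me? or Why not me?",
      "Questions and misconceptions"
    ),
    "Who am I now?" = c(
      "Self-concept",
      "Accepting support",
      "Is a support group right for me?",
      "The meaning of survivor",
      "Body image and sexuality",
      "How will people act toward me now?"
    ),
    "What are strategies to care for myself?" = c(
      "Coping with cancer",
      "Talking with people around you",
      "Personal control strategies",
      "Moving forward",
      "Personal growth from this experience"
    ),
    "How much will cancer be a part of my life?" = c(
      "Setting healthy goals"
    )
  )
}

exercise_titles <- function() {
  c(
    "Visualization", "Cognitive reframing", "Thought record",
    "Challenging unhelpful thoughts", "Worry time scheduling",
    "Problem-solving steps", "Relaxation breathing",
    "Progressive muscle relaxation", "Gratitude journal",
    "Strengths inventory", "Communication rehearsal", "Asking for support",
    "Goal setting", "Activity scheduling", "Self-talk inventory",
    "Mindful observation", "Coping card", "Values clarification",
    "Letter to myself", "Reviewing my progress"
  )
}

resource_titles <- function() {
  c(
    "Glossary of terms", "All program exercises list",
    "Full-length video library", "Breast cancer risk factors",
    "Signs of depression and anxiety", "Cancer information resources",
    "Myths and facts about breast cancer",
    "Common questions about breast cancer",
    "Mindfulness-based stress reduction", "Questions to ask your doctor",
    "First appointments - talking with your doctors",
    "Cancer support organizations", "Practical and financial help"
  )
}

#' Built-in program component catalog
#'
#' The default catalog of an unguided distress self-management program:
#' 5 learning modules divided into 17 topical section pages, 20
#' cognitive-behavioral exercises, 90 video vignettes and 13 resource pages
#' (140 countable components in total), plus three introductory pages and a
#' personalized home page that are navigational only.
#'
#' @return A catalog tibble (see [build_catalog()]).
#' @examples
#' catalog <- default_catalog()
#' catalog_denominator(catalog) # 140
#' @export
default_catalog <- function() {
  outline <- program_outline()
  sections <- tibble(
    title = unlist(outline, use.names = FALSE),
    parent_module = rep(names(outline), lengths(outline)),
    category = "module_section"
  )
  sections$component_id <- sprintf("sec_%03d", seq_len(nrow(sections)))
  exercises <- tibble(
    component_id = sprintf("ex_%03d", seq_along(exercise_titles())),
    category = "exercise", title = exercise_titles(),
    parent_module = NA_character_
  )
  videos <- tibble(
    component_id = sprintf("vid_%03d", 1:90),
    category = "video", title = sprintf("Survivor vignette %02d", 1:90),
    parent_module = NA_character_
  )
  resources <- tibble(
    component_id = sprintf("res_%03d", seq_along(resource_titles())),
    category = "resource", title = resource_titles(),
    parent_module = NA_character_
  )
  nav <- tibble(
    component_id = c("intro_001", "intro_002", "intro_003", "home_001"),
    category = c("intro", "intro", "intro", "home"),
    title = c(
      "Welcome video", "Instructions for use", "Tailoring exercise",
      "Personalized homepage"
    ),
    parent_module = NA_character_
  )
  validate_catalog(bind_rows(
    sections[, CATALOG_COLUMNS], exercises, videos, resources, nav
  ))
}

#' Activity denominator of a catalog
#'
#' Number of countable components (module sections, exercises, videos,
#' resources). This is the denominator of all activity percentages;
#' intro/home pages are excluded.
#'
#' @param catalog A catalog tibble.
#' @return Integer count.
#' @export
catalog_denominator <- function(catalog) {
  validate_catalog(catalog)
  sum(catalog$category %in% COUNTABLE_CATEGORIES)
}

#' Read or write a component catalog as CSV
#'
#' @param path File path. Columns: `component_id`, `category`, `title`,
#'   `parent_module`.
#' @return `read_catalog()` returns a validated catalog tibble;
#'   `write_catalog()` returns `path` invisibly.
#' @export
read_catalog <- function(path) {
  catalog <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character())
  )
  validate_catalog(as_tibble(catalog))
}

#' @rdname read_catalog
#' @param catalog A catalog tibble.
#' @export
write_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  readr::write_csv(catalog, path, na = "")
  invisible(path)
}
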