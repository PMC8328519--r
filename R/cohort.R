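#' One participant-session's retrieval record
#'
#' Holds the retrieved location for every landmark plus the explicitly
#' reported centre (the gist response) for a single participant and session.
#'
#' @param participant_id Character id.
#' @param session Session label (e.g. `"S1"`, `"S2"`, `"S3"`).
#' @param delay_group Delay-group label (e.g. `"24h"`, `"1week"`, `"1month"`,
#'   or `"within_subject"` for repeated-measures designs).
#' @param retrieved Matrix of retrieved `(x, y)` coordinates with row names
#'   equal to the layout's item labels (any order; stored in layout order).
#' @param reported_center Length-2 numeric: the clicked centre.
#' @param layout The `spatial_layout` the record refers to (used to check
#'   completeness and fix the item order).
#' @return A `retrieval_record` object.
#' @export
retrieval_record <- function(participant_id, session, delay_group,
                             retrieved, reported_center, layout) {
  labels <- layout_labels(layout)
  m <- as_point_matrix(retrieved, "retrieved")
  if (is.null(rownames(m))) {
    if (nrow(m) != length(labels)) {
      stop("`retrieved` must have one row per layout item", call. = FALSE)
    }
    rownames(m) <- labels
  }
  if (!setequal(rownames(m), labels) || nrow(m) != length(labels)) {
    stop("`retrieved` must cover exactly the layout's labels", call. = FALSE)
  }
  m <- m[labels, , drop = FALSE]
  check_finite(m, "retrieved")
  structure(
    list(participant_id = as.character(participant_id),
         session = as.character(session),
         delay_group = as.character(delay_group),
         retrieved = m,
         reported_center = check_finite(as.numeric(reported_center), "reported_center")),
    class = "retrieval_record"
  )
}

#' @export
print.retrieval_record <- function(x, ...) {
  cat(sprintf("<retrieval_record> %s / %s (%s): %d items, reported centre (%.1f, %.1f)\n",
              x$participant_id, x$session, x$delay_group, nrow(x$retrieved),
              x$reported_center[1], x$reported_center[2]))
  invisible(x)
}

#' A cohort: one layout plus many retrieval records
#'
#' @param layout A `spatial_layout`.
#' @param records List of `retrieval_record` objects, all referring to
#'   `layout`; each (participant, session) pair must be unique.
#' @return A `memory_cohort` object.
#' @export
memory_cohort <- function(layout, records) {
  stopifnot(inherits(layout, "spatial_layout"))
  if (!all(vapply(records, inherits, logical(1), "retrieval_record"))) {
    stop("`records` must be a list of retrieval_record objects", call. = FALSE)
  }
  keys <- vapply(records, function(r) paste(r$participant_id, r$session, sep = "\r"),
                 character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate (participant, session) pairs in cohort", call. = FALSE)
  }
  labels <- layout_labels(layout)
  ok <- vapply(records, function(r) identical(rownames(r$retrieved), labels), logical(1))
  if (!all(ok)) stop("all records must use the cohort layout's labels", call. = FALSE)
  structure(list(layout = layout, records = records), class = "memory_cohort")
}

#' @export
print.memory_cohort <- function(x, ...) {
  ids <- vapply(x$records, `[[`, character(1), "participant_id")
  sess <- vapply(x$records, `[[`, character(1), "session")
  cat(sprintf("<memory_cohort> %d participants x sessions {%s} on %d items\n",
              length(unique(ids)), paste(sort(unique(sess)), collapse = ", "),
              n_items(x$layout)))
  invisible(x)
}

#' Tidy table view of a cohort
#'
#' One row per (participant, session, item) plus one `center` row per
#' (participant, session) — the same schema used by the trials CSV.
#'
#' @param cohort A `memory_cohort`.
#' @return A tibble with columns `participant_id`, `session`, `delay_group`,
#'   `record_type` (`"item"` or `"center"`), `item_label`, `x`, `y`.
#' @export
cohort_table <- function(cohort) {
  rows <- lapply(cohort$records, function(r) {
    tibble::tibble(
      participant_id = r$participant_id,
      session = r$session,
      delay_group = r$delay_group,
      record_type = c(rep("item", nrow(r$retrieved)), "center"),
      item_label = c(rownames(r$retrieved), NA_character_),
      x = c(r$retrieved[, 1], r$reported_center[1]),
      y = c(r$retrieved[, 2], r$reported_center[2])
    )
  })
  dplyr::bind_rows(rows)
}

#' Read / write a cohort trials CSV
#'
#' The trials table has columns `participant_id`, `session`, `delay_group`,
#' `record_type` (`item` / `center`), `item_label` (empty on center rows),
#' `x`, `y`. `read_cohort()` validates completeness against the layout and
#' names the offending participant/session/label on failure.
#'
#' @param path CSV file path.
#' @param layout The `spatial_layout` the trials refer to.
#' @return A `memory_cohort`.
#' @export
read_cohort <- function(path, layout) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    session = readr::col_character(),
    delay_group = readr::col_character(),
    record_type = readr::col_character(),
    item_label = readr::col_character(),
    x = readr::col_double(),
    y = readr::col_double()
  ))
  required <- c("participant_id", "session", "delay_group", "record_type",
                "item_label", "x", "y")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("trials table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_type <- !tab$record_type %in% c("item", "center")
  if (any(bad_type)) {
    stop("invalid record_type at row ", which(bad_type)[1], call. = FALSE)
  }
  labels <- layout_labels(layout)
  records <- list()
  for (key in unique(paste(tab$participant_id, tab$session, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- tab[tab$participant_id == parts[1] & tab$session == parts[2], ]
    where <- sprintf("participant '%s' session '%s'", parts[1], parts[2])
    items <- sub[sub$record_type == "item", ]
    centers <- sub[sub$record_type == "center", ]
    unknown <- setdiff(items$item_label, labels)
    if (length(unknown)) {
      stop("unknown item label '", unknown[1], "' for ", where, call. = FALSE)
    }
    if (anyDuplicated(items$item_label)) {
      stop("duplicate item row '", items$item_label[anyDuplicated(items$item_label)],
           "' for ", where, call. = FALSE)
    }
    absent <- setdiff(labels, items$item_label)
    if (length(absent)) {
      stop("missing item row(s) ", paste(absent, collapse = ", "), " for ", where,
           call. = FALSE)
    }
    if (nrow(centers) != 1L) {
      stop("expected exactly one center row for ", where, " (found ",
           nrow(centers), ")", call. = FALSE)
    }
    m <- as.matrix(items[, c("x", "y")])
    rownames(m) <- items$item_label
    records[[length(records) + 1L]] <- retrieval_record(
      parts[1], parts[2], sub$delay_group[1], m,
      c(centers$x, centers$y), layout
    )
  }
  memory_cohort(layout, records)
}

#' @rdname read_cohort
#' @param cohort A `memory_cohort`.
#' @return `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort_table(cohort), path, na = "")
  invisible(path)
}

# Look up one record by participant and session.
cohort_record <- function(cohort, participant_id, session) {
  for (r in cohort$records) {
    if (r$participant_id == participant_id && r$session == session) return(r)
  }
  NULL
}
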