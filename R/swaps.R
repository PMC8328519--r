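#' Detect misbound (swapped) item pairs
#'
#' Identifies pairs of items whose labels were exchanged at retrieval
#' (recalling A's location at B's encoded place and vice versa). A pair
#' (A, B) qualifies when all four conditions hold:
#' \enumerate{
#'   \item the retrieval of A is strictly closest to encoded B,
#'   \item the retrieval of B is strictly closest to encoded A,
#'   \item both retrievals lie within d(encoded A, encoded B) / 2 of the
#'     encoded location each is closest to (with `rule = "both"`, within
#'     that range of \emph{both} encoded locations),
#'   \item no other retrieval lies within that range of encoded A or B.
#' }
#' Pairs are disjoint by construction (conditions 1-2 fix each member's
#' partner) and returned in label order.
#'
#' @param record A `retrieval_record`.
#' @param layout The `spatial_layout`.
#' @param rule Reading of condition (3); the default `"nearest"` requires
#'   each retrieval to be within half the encoded separation of its nearest
#'   encoded location, `"both"` additionally of the other one.
#' @param g Minkowski exponent for distances.
#' @return Tibble with columns `label_a`, `label_b` (possibly zero rows).
#' @export
detect_swaps <- function(record, layout, rule = c("nearest", "both"), g = 2) {
  rule <- match.arg(rule)
  labels <- layout_labels(layout)
  enc <- layout_points(layout)
  ret <- record$retrieved
  n <- length(labels)
  if (n < 2L) return(tibble::tibble(label_a = character(), label_b = character()))
  # D[i, j] = distance from retrieval of item i to encoded location of item j
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (j in seq_len(n)) D[, j] <- mink_dist(ret, enc[j, ], g = g)
  nearest <- apply(D, 1L, which.min) # first index on ties = label order
  out_a <- character()
  out_b <- character()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (nearest[i] != j || nearest[j] != i) next
      half <- mink_dist(enc[i, ], enc[j, ], g = g) / 2
      ok3 <- if (rule == "nearest") {
        D[i, j] <= half && D[j, i] <= half
      } else {
        D[i, j] <= half && D[j, i] <= half && D[i, i] <= half && D[j, j] <= half
      }
      if (!ok3) next
      others <- setdiff(seq_len(n), c(i, j))
      if (length(others) && any(D[others, i] <= half | D[others, j] <= half)) next
      out_a <- c(out_a, labels[i])
      out_b <- c(out_b, labels[j])
    }
  }
  tibble::tibble(label_a = out_a, label_b = out_b)
}

#' Swap back the retrieved locations of detected pairs
#'
#' Exchanges the two retrieved points of each pair label-wise, leaving all
#' other items untouched. Applying the correction and re-detecting yields no
#' further pairs (fixed point after one application).
#'
#' @param record A `retrieval_record`.
#' @param pairs Tibble from [detect_swaps()] (columns `label_a`, `label_b`).
#' @return The corrected `retrieval_record`.
#' @export
apply_swap_correction <- function(record, pairs) {
  if (nrow(pairs) == 0L) return(record)
  touched <- c(pairs$label_a, pairs$label_b)
  if (anyDuplicated(touched)) stop("overlapping swap pairs", call. = FALSE)
  if (!all(touched %in% rownames(record$retrieved))) {
    stop("swap pair labels not present in record", call. = FALSE)
  }
  ret <- record$retrieved
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$label_a[k]
    b <- pairs$label_b[k]
    tmp <- ret[a, ]
    ret[a, ] <- ret[b, ]
    ret[b, ] <- tmp
  }
  record$retrieved <- ret
  record
}

#' Apply swap correction across a whole cohort
#'
#' @param cohort A `memory_cohort`.
#' @param rule,g Passed to [detect_swaps()].
#' @return A list with `cohort` (corrected) and `swaps` (tibble of detected
#'   pairs with participant and session).
#' @export
correct_cohort_swaps <- function(cohort, rule = c("nearest", "both"), g = 2) {
  rule <- match.arg(rule)
  found <- list()
  records <- lapply(cohort$records, function(r) {
    pairs <- detect_swaps(r, cohort$layout, rule = rule, g = g)
    if (nrow(pairs)) {
      found[[length(found) + 1L]] <<- dplyr::mutate(
        pairs, participant_id = r$participant_id, session = r$session,
        .before = 1L
      )
    }
    apply_swap_correction(r, pairs)
  })
  list(
    cohort = memory_cohort(cohort$layout, records),
    swaps = if (length(found)) dplyr::bind_rows(found)
            else tibble::tibble(participant_id = character(), session = character(),
                                label_a = character(), label_b = character())
  )
}
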