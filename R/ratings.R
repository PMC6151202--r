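#' The eight-property semantic-differential schema
#'
#' The core set of aesthetic antonym pairs and their layer assignment:
#' three affective properties (first-glance feelings), four judgment
#' properties (the nature of the texture), and one emotional property (the
#' like-dislike decision).
#'
#' @return Tibble with columns `property` (G1..G3, T1..T4, Q), `antonyms`,
#'   `layer`.
#' @examples
#' property_schema()
#' @export
property_schema <- function() {
  tibble::tibble(
    property = c("G1", "G2", "G3", "T1", "T2", "T3", "T4", "Q"),
    antonyms = c("cold-warm", "rough-smooth", "dark-light",
                 "mussy-harmonious", "inelegant-elegant", "simple-complex",
                 "artificial-natural", "like-dislike"),
    layer = c(rep("affective", 3), rep("judgment", 4), "emotional")
  )
}

#' Screen a set of rater scores for outliers
#'
#' Retains scores within mean +/- 2 SD of the full set (single pass). If the
#' standard deviation is zero all scores are retained. As a guard against
#' degenerate mass deletion, at most 25% of the scores are removed; when more
#' are flagged, only the most extreme quarter is dropped.
#'
#' @param scores Numeric vector, length `>= 3`.
#' @return Numeric vector of retained scores, in input order. The logical
#'   attribute `"retained"` marks which inputs were kept.
#' @examples
#' remove_outliers(c(rep(10, 19), 90))
#' @export
remove_outliers <- function(scores) {
  n <- length(scores)
  if (n < 3L) stop("need at least 3 scores", call. = FALSE)
  m <- mean(scores); s <- stats::sd(scores)
  keep <- rep(TRUE, n)
  if (s > 0) {
    dev <- abs(scores - m)
    flag <- dev > 2 * s
    cap <- floor(0.25 * n)
    if (sum(flag) > cap) {
      worst <- order(-dev)[seq_len(cap)]
      flag <- rep(FALSE, n)
      flag[worst] <- TRUE
    }
    keep <- !flag
  }
  structure(scores[keep], retained = keep)
}

#' Aggregate a rating panel to per-texture property scores
#'
#' For every (texture, property) group, screens the rater scores with
#' [remove_outliers()] and averages the retained ones — the final rating used
#' for model building. Scores must lie strictly inside (-100, 100), the range
#' of the continuous rating scale.
#'
#' @param records Tibble/data frame of rating records with columns
#'   `texture_id`, `property`, `rater_id`, `score`; every group needs at
#'   least 3 records.
#' @param properties Property vocabulary (default [property_schema()]).
#' @return Tibble with columns `texture_id`, `property`, `rating`,
#'   `n_retained`, `n_raters`, sorted by texture then property.
#' @export
aggregate_ratings <- function(records, properties = property_schema()) {
  req <- c("texture_id", "property", "rater_id", "score")
  if (!all(req %in% names(records))) {
    stop("`records` needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  bad_prop <- setdiff(unique(records$property), properties$property)
  if (length(bad_prop)) {
    stop("unknown property id(s): ", paste(bad_prop, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(records$score)) ||
      any(abs(records$score) >= 100)) {
    stop("scores must lie strictly inside (-100, 100)", call. = FALSE)
  }
  counts <- dplyr::count(records, .data$texture_id, .data$property)
  small <- dplyr::filter(counts, .data$n < 3L)
  if (nrow(small)) {
    stop("group(s) with fewer than 3 ratings: ",
         paste(paste0(small$texture_id, "/", small$property),
               collapse = ", "), call. = FALSE)
  }
  missing_n <- nrow(tidyr::expand_grid(
    texture_id = unique(records$texture_id),
    property = properties$property
  )) - nrow(counts)
  if (missing_n > 0) {
    rlang::inform(sprintf("%d (texture, property) group(s) have no ratings",
                          missing_n))
  }
  records |>
    dplyr::group_by(.data$texture_id, .data$property) |>
    dplyr::summarise(
      rating = mean(remove_outliers(.data$score)),
      n_retained = length(remove_outliers(.data$score)),
      n_raters = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$texture_id,
                   match(.data$property, properties$property))
}
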