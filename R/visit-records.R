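#' Build a consumption matrix from focal-tree visit records
#'
#' Converts a log of frugivore visits to fruiting trees into the weighted
#' consumption matrix: for each (plant, frugivore) pair the estimated number
#' of fruits handled is
#' \deqn{X_{ij} = \left(\sum \text{duration}\right) \times \bar r \times
#'   60/\text{interval},}
#' total feeding time in minutes multiplied by the average feeding rate,
#' where \eqn{\bar r} is the mean fruits manipulated per focal interval
#' (30 s focal intervals for primates, 10 s for birds) and
#' \eqn{60/\text{interval}} converts it to fruits per minute.
#'
#' A visit-record table has one row per visit with columns:
#' \describe{
#'   \item{plant, frugivore}{species labels (normalized at ingest).}
#'   \item{duration_min}{visit duration in minutes, >= 0.}
#'   \item{focal_counts}{list-column of integer vectors: fruits manipulated
#'     in each focal interval sampled during the visit (may be empty).}
#'   \item{focal_interval_s}{focal interval length in seconds (10 or 30);
#'     must be constant within a frugivore species.}
#' }
#'
#' @param records visit-record data frame (see Details).
#' @param pooling `"pooled"` (default): the mean rate for a pair pools all
#'   focal counts across its visits; `"per_visit"`: per-visit means are
#'   averaged. Pooling makes the matrix additive over arbitrary splits of
#'   the log.
#' @return a count-scale [consumption_matrix()] (plants x frugivores).
#' @examples
#' rec <- tibble::tibble(
#'   plant = "Ficus", frugivore = "Lagothrix", duration_min = 10,
#'   focal_counts = list(c(3L, 5L)), focal_interval_s = 30L)
#' fruits_handled(rec)  # 10 min x 4 fruits/30s x 2 = 80 fruits
#' @export
fruits_handled <- function(records, pooling = c("pooled", "per_visit")) {
  pooling <- match.arg(pooling)
  records <- validate_visit_records(records)

  # focal interval must be unambiguous per frugivore species
  iv <- dplyr::distinct(records, .data$frugivore, .data$focal_interval_s)
  dup <- iv$frugivore[duplicated(iv$frugivore)]
  if (length(dup))
    stop("mixed focal_interval_s within frugivore species: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)

  per_pair <- records |>
    dplyr::group_by(.data$plant, .data$frugivore) |>
    dplyr::summarise(
      total_min = sum(.data$duration_min),
      rate_per_int = if (pooling == "pooled") {
        pooled <- unlist(.data$focal_counts)
        if (length(pooled)) mean(pooled) else NA_real_
      } else {
        pv <- vapply(.data$focal_counts,
                     function(v) if (length(v)) mean(v) else NA_real_, 0)
        if (all(is.na(pv))) NA_real_ else mean(pv, na.rm = TRUE)
      },
      interval_s = .data$focal_interval_s[1],
      .groups = "drop"
    )

  missing_rate <- per_pair$total_min > 0 & is.na(per_pair$rate_per_int)
  if (any(missing_rate)) {
    p <- per_pair[missing_rate, ][1, ]
    stop(sprintf(
      "pair (%s, %s) has positive feeding time but no focal counts",
      p$plant, p$frugivore), call. = FALSE)
  }

  per_pair <- per_pair |>
    dplyr::mutate(fruits = ifelse(
      .data$total_min > 0,
      .data$total_min * .data$rate_per_int * 60 / .data$interval_s, 0))

  plants <- sort(unique(records$plant))
  frugs <- sort(unique(records$frugivore))
  m <- matrix(0, length(plants), length(frugs),
              dimnames = list(plants, frugs))
  m[cbind(match(per_pair$plant, plants),
          match(per_pair$frugivore, frugs))] <- per_pair$fruits
  consumption_matrix(m, scale = "counts")
}

validate_visit_records <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("plant", "frugivore", "duration_min", "focal_counts",
            "focal_interval_s")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("visit records missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.list(records$focal_counts))
    records$focal_counts <- as.list(records$focal_counts)
  records$focal_counts <- lapply(records$focal_counts,
                                 function(v) as.numeric(v[!is.na(v)]))
  if (any(records$duration_min < 0))
    stop("negative visit duration", call. = FALSE)
  if (any(records$focal_interval_s <= 0))
    stop("focal_interval_s must be positive", call. = FALSE)
  if (any(unlist(records$focal_counts) < 0))
    stop("negative focal counts", call. = FALSE)
  records$plant <- normalize_labels(records$plant)
  records$frugivore <- normalize_labels(records$frugivore)
  records
}

#' Reallocate a frugivore group's consumption by external proportions
#'
#' Keeps the total consumption of a group of frugivores (e.g. the primates)
#' on each plant fixed but redistributes it among the group members using
#' proportions from an external source such as long-term focal-animal
#' studies. Non-members are untouched and per-plant group sums are conserved
#' exactly.
#'
#' @param matrix a [consumption_matrix()].
#' @param group_members character vector of frugivore labels in the group.
#' @param proportions data frame with columns `plant`, then one column per
#'   group member, rows summing to 1 (tolerance 1e-6). Plants absent from
#'   `proportions` keep their observed split.
#' @return a [consumption_matrix()] with the reallocated weights.
#' @export
reallocate_group <- function(matrix, group_members, proportions) {
  m <- as.matrix(matrix)
  group_members <- normalize_labels(group_members)
  absent <- setdiff(group_members, colnames(m))
  if (length(absent))
    stop("group members absent from matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  proportions <- tibble::as_tibble(proportions)
  proportions$plant <- normalize_labels(proportions$plant)
  miss <- setdiff(group_members, names(proportions))
  if (length(miss))
    stop("proportions table missing member columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  pm <- as.matrix(proportions[, group_members])
  bad <- abs(rowSums(pm) - 1) > 1e-6
  if (any(bad))
    stop("proportions do not sum to 1 for plant(s): ",
         paste(proportions$plant[bad], collapse = ", "), call. = FALSE)
  unknown <- setdiff(proportions$plant, rownames(m))
  if (length(unknown))
    stop("proportions given for plants absent from matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (k in seq_len(nrow(proportions))) {
    pl <- proportions$plant[k]
    grp_total <- sum(m[pl, group_members])
    m[pl, group_members] <- grp_total * pm[k, ]
  }
  consumption_matrix(m, scale = matrix_scale(matrix))
}
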