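#' Pulp-biomass energy flow from each plant to the frugivore level
#'
#' An abundance-aware keystone score: the dry pulp biomass a plant
#' population delivers to frugivores per hectare per day,
#' \deqn{flow = \text{consumption rate} \times \text{active hours} \times
#'   \text{pulp mass} \times \text{density}}
#' with consumption rate in fruits h\eqn{^{-1}} tree\eqn{^{-1}}, pulp dry
#' mass per fruit in g, density in reproductive trees ha\eqn{^{-1}} and
#' `active_hours` the feeding hours per day over which the hourly rate is
#' extrapolated. With `annualize = TRUE` the daily value is averaged over
#' the year by the fruiting-season factor `crop_duration / 12` (crop
#' duration in months).
#'
#' @param traits data frame with columns `species`, `consumption_rate`,
#'   `pulp_dry_mass_per_fruit`, `density`, and `crop_duration` when
#'   annualizing. All values must be non-negative.
#' @param active_hours daylight feeding hours per day (> 0; default 12).
#' @param annualize average the daily flow over the year using crop
#'   duration.
#' @return a tibble: `species`, `flow` (g dry pulp ha^-1 day^-1; `NA` with
#'   a `reason` when an ingredient is missing), `rank` (1 = largest flow,
#'   ties broken by label).
#' @examples
#' pulp_flow(tibble::tibble(species = "A", consumption_rate = 2,
#'                          pulp_dry_mass_per_fruit = 5, density = 10))
#' @export
pulp_flow <- function(traits, active_hours = 12, annualize = FALSE) {
  if (active_hours <= 0) stop("active_hours must be positive", call. = FALSE)
  traits <- tibble::as_tibble(traits)
  need <- c("consumption_rate", "pulp_dry_mass_per_fruit", "density")
  if (annualize) need <- c(need, "crop_duration")
  miss_cols <- setdiff(need, names(traits))
  if (length(miss_cols))
    stop("trait table missing columns: ", paste(miss_cols, collapse = ", "),
         call. = FALSE)
  for (cl in need)
    if (any(traits[[cl]] < 0, na.rm = TRUE))
      stop("negative values in ", cl, call. = FALSE)
  ingredients <- as.matrix(traits[, need])
  missing_row <- apply(ingredients, 1, anyNA)
  reason <- ifelse(missing_row,
                   apply(ingredients, 1, function(x)
                     paste("missing:", paste(need[is.na(x)], collapse = ", "))),
                   NA_character_)
  flow <- traits$consumption_rate * active_hours *
    traits$pulp_dry_mass_per_fruit * traits$density
  if (annualize) flow <- flow * traits$crop_duration / 12
  flow[missing_row] <- NA_real_
  out <- tibble::tibble(species = normalize_labels(traits$species),
                        flow = flow, reason = reason)
  ord <- order(-out$flow, out$species, na.last = TRUE)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  out
}

#' Top-k keystone candidates and list overlap
#'
#' @param flow a flow table from [pulp_flow()] (or any tibble with
#'   `species` and `flow`).
#' @param k list length (<= number of plants with a flow value).
#' @return `rank_keystones()`: character vector of the `k` species with the
#'   largest flow (descending, ties by label).
#' @export
rank_keystones <- function(flow, k) {
  flow <- tibble::as_tibble(flow)
  flow <- flow[!is.na(flow$flow), ]
  if (k > nrow(flow)) stop("k exceeds number of scored plants", call. = FALSE)
  flow$species[order(-flow$flow, flow$species)][seq_len(k)]
}

#' @rdname rank_keystones
#' @param list_a,list_b character vectors of species labels (normalized
#'   before matching).
#' @return `keystone_overlap()`: character vector of shared species.
#' @export
keystone_overlap <- function(list_a, list_b) {
  intersect(normalize_labels(list_a), normalize_labels(list_b))
}

#' Per-plant regression of visit time on frugivore abundance
#'
#' For each plant, ordinary least squares of the total feeding time it
#' received from each frugivore on that frugivore's abundance. Reports the
#' coefficient of determination and the slope sign per plant, plus a
#' community summary (fraction of plants with a positive slope and the mean
#' R-squared).
#'
#' @param visit_times data frame with columns `plant`, `frugivore`,
#'   `minutes` (or a [consumption_matrix()] whose weights are feeding
#'   times).
#' @param abundance data frame with columns `frugivore`, `abundance`.
#' @param min_partners minimum number of frugivores with data required per
#'   plant (default 3); plants below it are skipped.
#' @return a tibble: `plant`, `n`, `r_squared`, `slope_sign`; attribute
#'   `"summary"` holds `frac_positive` and `mean_r2`.
#' @export
abundance_r2 <- function(visit_times, abundance, min_partners = 3) {
  if (inherits(visit_times, "consumption_matrix") ||
      is.matrix(visit_times)) {
    visit_times <- tidy.consumption_matrix(visit_times)
    names(visit_times)[names(visit_times) == "weight"] <- "minutes"
  }
  visit_times <- tibble::as_tibble(visit_times)
  abundance <- tibble::as_tibble(abundance)
  abundance$frugivore <- normalize_labels(abundance$frugivore)
  visit_times$frugivore <- normalize_labels(visit_times$frugivore)
  df <- dplyr::inner_join(visit_times, abundance, by = "frugivore")
  res <- df |>
    dplyr::group_by(.data$plant) |>
    dplyr::group_modify(function(g, key) {
      g <- g[stats::complete.cases(g$minutes, g$abundance), ]
      if (nrow(g) < min_partners || stats::sd(g$abundance) == 0) {
        if (nrow(g) >= min_partners)
          warning("zero abundance variance for plant ", key$plant,
                  "; skipped", call. = FALSE)
        return(tibble::tibble(n = nrow(g), r_squared = NA_real_,
                              slope_sign = NA_real_))
      }
      fit <- stats::lm(minutes ~ abundance, data = g)
      tibble::tibble(n = nrow(g),
                     r_squared = summary(fit)$r.squared,
                     slope_sign = unname(sign(stats::coef(fit)[2])))
    }) |>
    dplyr::ungroup()
  ok <- !is.na(res$r_squared)
  attr(res, "summary") <- tibble::tibble(
    frac_positive = mean(res$slope_sign[ok] > 0),
    mean_r2 = mean(res$r_squared[ok]))
  res
}

#' Seven regressions testing the specialized-dispersal hypothesis
#'
#' Under the specialized vs. generalized dispersal-system hypothesis, pulp
#' quality (% lipids) should associate positively with crop duration, seed
#' size and frugivore size, and negatively with crop size, visitation rate,
#' visitor richness and the probability of recruiting below parents. Each
#' prediction is tested by simple OLS of `pct_lipids` on the predictor.
#'
#' @param traits data frame with `species`, `pct_lipids` and any of the
#'   predictor columns `crop_duration`, `seed_width`, `frugivore_size`,
#'   `crop_size`, `visitation_rate`, `richness`,
#'   `recruit_below_parents`. Absent predictors are reported as untested
#'   rows, not errors.
#' @param min_n minimum complete pairs required per regression (default 3).
#' @return a tibble: `prediction`, `predictor`, `expected_sign`, `n`,
#'   `r_squared`, `sign`, `p_value` (`NA` rows for untested predictors).
#' @export
prediction_battery <- function(traits, min_n = 3) {
  traits <- tibble::as_tibble(traits)
  if (!"pct_lipids" %in% names(traits))
    stop("trait table needs a pct_lipids column", call. = FALSE)
  preds <- tibble::tibble(
    prediction = 1:7,
    predictor = c("crop_duration", "seed_width", "frugivore_size",
                  "crop_size", "visitation_rate", "richness",
                  "recruit_below_parents"),
    expected_sign = c("+", "+", "+", "-", "-", "-", "-"))
  purrr::pmap_dfr(preds, function(prediction, predictor, expected_sign) {
    base <- tibble::tibble(prediction = prediction, predictor = predictor,
                           expected_sign = expected_sign)
    if (!predictor %in% names(traits))
      return(dplyr::mutate(base, n = 0L, r_squared = NA_real_,
                           sign = NA_character_, p_value = NA_real_))
    g <- traits[stats::complete.cases(traits$pct_lipids,
                                      traits[[predictor]]), ]
    if (nrow(g) < min_n || stats::sd(g$pct_lipids) == 0 ||
        stats::sd(g[[predictor]]) == 0)
      return(dplyr::mutate(base, n = nrow(g), r_squared = NA_real_,
                           sign = NA_character_, p_value = NA_real_))
    fit <- stats::lm(stats::reformulate(predictor, "pct_lipids"), data = g)
    sm <- summary(fit)
    dplyr::mutate(base, n = nrow(g), r_squared = sm$r.squared,
                  sign = unname(ifelse(stats::coef(fit)[2] >= 0, "+", "-")),
                  p_value = sm$coefficients[2, 4])
  })
}

#' Derive per-plant consumption rates from a matrix and effort table
#'
#' Converts total fruits handled into fruits h^-1 tree^-1 by dividing each
#' plant's matrix row total by its observation hours and the number of
#' focal trees watched.
#'
#' @param matrix a count-scale [consumption_matrix()].
#' @param effort data frame with `species`, `hours`, `n_trees`.
#' @return a tibble `species`, `consumption_rate`.
#' @export
consumption_rates <- function(matrix, effort) {
  effort <- tibble::as_tibble(effort)
  effort$species <- normalize_labels(effort$species)
  tot <- tibble::tibble(species = rownames(as.matrix(matrix)),
                        fruits = rowSums(as.matrix(matrix)))
  out <- dplyr::left_join(tot, effort, by = "species")
  tibble::tibble(species = out$species,
                 consumption_rate = unname(out$fruits / (out$hours * out$n_trees)))
}
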