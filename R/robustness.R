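#' Secondary-extinction curve for one removal order
#'
#' Removes species of one trophic level in the given order; after each
#' removal, species at the opposite level left without any partner are
#' counted as secondarily extinct. The curve records, for
#' \eqn{k = 0, \dots, S}, the fraction of the focal level removed and the
#' fraction of the opposite level still surviving, starting at (0, 1) and
#' ending at (1, 0).
#'
#' @param matrix a [consumption_matrix()] (binary structure is what
#'   matters).
#' @param removal_level which level is removed: `"plants"` or
#'   `"frugivores"`.
#' @param order character vector: a permutation of the level's species.
#' @return a tibble with columns `removed_frac`, `surviving_frac`.
#' @export
extinction_sequence <- function(matrix, removal_level = "plants", order) {
  m <- level_matrix(matrix, removal_level)  # removed level on rows
  if (!setequal(order, rownames(m)) || length(order) != nrow(m))
    stop("order must be a permutation of the removed level's species",
         call. = FALSE)
  b <- m > 0
  n_rem <- nrow(b); n_oth <- ncol(b)
  partners_left <- colSums(b)
  alive <- partners_left > 0  # species never connected count as lost at start
  surv <- numeric(n_rem + 1)
  surv[1] <- sum(alive) / n_oth
  for (k in seq_along(order)) {
    gone <- b[order[k], ]
    partners_left <- partners_left - gone
    alive <- alive & partners_left > 0
    surv[k + 1] <- sum(alive) / n_oth
  }
  tibble::tibble(removed_frac = (0:n_rem) / n_rem, surviving_frac = surv)
}

#' Area under an extinction curve
#'
#' Trapezoidal integral of the survivors-vs-removed curve over
#' \eqn{x \in [0, 1]}; 1 means a maximally robust network.
#'
#' @param curve tibble from [extinction_sequence()] (columns
#'   `removed_frac`, `surviving_frac`).
#' @return robustness R in \[0, 1\].
#' @export
robustness_area <- function(curve) {
  x <- curve$removed_frac; y <- curve$surviving_frac
  if (is.unsorted(x)) stop("curve x values must be sorted", call. = FALSE)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Random-removal robustness
#'
#' Averages the extinction curve and its area over `n_orders` uniformly
#' random removal orders.
#'
#' @inheritParams extinction_sequence
#' @param n_orders number of random orders (>= 1).
#' @param seed integer master seed (per-order seeds derived by counter).
#' @return an object of class `robustness`: list with `curve` (mean curve
#'   tibble), `R` (mean area), `R_sd`, `R_values`, `removal_level`,
#'   `n_orders`, `seed`.
#' @export
random_robustness <- function(matrix, removal_level = "plants",
                              n_orders = 100, seed = 1) {
  if (n_orders < 1) stop("n_orders must be >= 1", call. = FALSE)
  m <- level_matrix(matrix, removal_level)
  species <- rownames(m)
  curves <- matrix(0, n_orders, length(species) + 1)
  rs <- numeric(n_orders)
  for (o in seq_len(n_orders)) {
    ord <- withr::with_seed(as.integer(seed) + o, sample(species))
    cur <- extinction_sequence(matrix, removal_level, ord)
    curves[o, ] <- cur$surviving_frac
    rs[o] <- robustness_area(cur)
  }
  structure(list(
    curve = tibble::tibble(
      removed_frac = (0:length(species)) / length(species),
      surviving_frac = colMeans(curves)),
    R = mean(rs), R_sd = stats::sd(rs), R_values = rs,
    removal_level = removal_level, n_orders = n_orders, seed = seed),
    class = "robustness")
}

#' @export
print.robustness <- function(x, ...) {
  cat(sprintf(
    "<robustness> removing %s: R = %.3f (SD %.3f over %d random orders)\n",
    x$removal_level, x$R, x$R_sd %||% NA, x$n_orders))
  invisible(x)
}

#' One-plant ablation experiment
#'
#' Replicates the matrix, removes one focal plant at a time (frugivores
#' left partnerless remain as structural zero columns), and recomputes
#' random-removal robustness in both directions for each ablated web.
#' "Plant-level R" is the robustness of the plant level when frugivores are
#' removed, and vice versa.
#'
#' @param matrix a [consumption_matrix()].
#' @param plants_to_remove character vector of plant labels to ablate, one
#'   at a time.
#' @param n_orders,seed passed to [random_robustness()].
#' @return a tibble with columns `removed_plant`, `R_plant_level`,
#'   `R_frugivore_level`; attribute `"summary"` holds the mean and variance
#'   of each column.
#' @export
single_removal_experiment <- function(matrix, plants_to_remove,
                                      n_orders = 100, seed = 1) {
  m <- as.matrix(matrix)
  plants_to_remove <- normalize_labels(plants_to_remove)
  absent <- setdiff(plants_to_remove, rownames(m))
  if (length(absent))
    stop("plants not in matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  if (nrow(m) < 2) stop("cannot remove the only plant", call. = FALSE)
  res <- purrr::map_dfr(plants_to_remove, function(pl) {
    sub <- consumption_matrix(m[setdiff(rownames(m), pl), , drop = FALSE],
                              scale = matrix_scale(matrix))
    tibble::tibble(
      removed_plant = pl,
      R_plant_level = random_robustness(sub, "frugivores", n_orders, seed)$R,
      R_frugivore_level = random_robustness(sub, "plants", n_orders, seed)$R)
  })
  attr(res, "summary") <- tibble::tibble(
    level = c("plant", "frugivore"),
    mean_R = c(mean(res$R_plant_level), mean(res$R_frugivore_level)),
    var_R = c(stats::var(res$R_plant_level), stats::var(res$R_frugivore_level)))
  res
}
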