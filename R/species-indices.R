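#' @keywords internal
#' Orient the matrix so the focal trophic level is on rows.
level_matrix <- function(matrix, level = c("plants", "frugivores")) {
  level <- match.arg(level)
  m <- as.matrix(matrix)
  if (level == "frugivores") m <- t(m)
  m
}

#' Degree and normalized degree
#'
#' `D` counts the partners a species interacts with (weight > 0); `ND`
#' scales it by the number of possible partners at the other level.
#'
#' @param matrix a [consumption_matrix()].
#' @param level which trophic level to score: `"plants"` (rows) or
#'   `"frugivores"` (columns).
#' @return a tibble with columns `species`, `D`, `ND`.
#' @export
degree_indices <- function(matrix, level = "plants") {
  m <- level_matrix(matrix, level)
  D <- unname(rowSums(m > 0))
  tibble::tibble(species = rownames(m), D = as.integer(D), ND = D / ncol(m))
}

#' Nested rank
#'
#' Position of each species in the nestedness-ordered matrix: species are
#' sorted by decreasing degree (ties broken by decreasing total weight, then
#' label), given ranks \eqn{r = 0, \dots, S-1} and normalized as
#' \eqn{NR = r/(S-1)}, so 0 marks the most generalist species. The converted
#' value `NR_conv = 1 - NR` puts generalists at 1.
#'
#' @inheritParams degree_indices
#' @return a tibble with columns `species`, `NR`, `NR_conv`.
#' @export
nested_rank <- function(matrix, level = "plants") {
  m <- level_matrix(matrix, level)
  if (nrow(m) < 2) stop("nested rank needs at least 2 species", call. = FALSE)
  deg <- rowSums(m > 0)
  tot <- rowSums(m)
  ord <- order(-deg, -tot, rownames(m))
  r <- integer(nrow(m))
  r[ord] <- seq_len(nrow(m)) - 1L
  nr <- r / (nrow(m) - 1)
  tibble::tibble(species = rownames(m), NR = nr, NR_conv = 1 - nr)
}

#' Weighted betweenness and closeness on the one-mode projection
#'
#' Projects the bipartite web onto the focal level (edge weight between
#' species *i* and *k* is \eqn{w_{ik} = \sum_j X_{ij} X_{kj}} over shared
#' partners, or the sum of minima with `projection = "min"`), runs weighted
#' shortest paths on distances \eqn{1/w}, and returns Brandes betweenness
#' (`WB`) and closeness \eqn{WC_i = (S-1)/\sum_k d_{ik}}. Unreachable pairs
#' contribute ten times the largest finite distance; isolated species score
#' 0. Both indices are rescaled to sum to 1 across the level.
#'
#' @inheritParams degree_indices
#' @param projection co-use weight: `"product"` (default) or `"min"`.
#' @return a tibble with columns `species`, `WB`, `WC`.
#' @export
bipartite_centrality <- function(matrix, level = "plants",
                                 projection = c("product", "min")) {
  projection <- match.arg(projection)
  m <- level_matrix(matrix, level)
  s <- nrow(m)
  if (projection == "product") {
    P <- m %*% t(m)
  } else {
    P <- matrix(0, s, s)
    for (i in seq_len(s)) for (k in seq_len(s))
      P[i, k] <- sum(pmin(m[i, ], m[k, ]))
  }
  diag(P) <- 0
  dimnames(P) <- list(rownames(m), rownames(m))
  g <- igraph::graph_from_adjacency_matrix(P, mode = "undirected",
                                           weighted = TRUE)
  dist_w <- 1 / igraph::E(g)$weight
  wb <- if (s >= 3) igraph::betweenness(g, weights = dist_w) else
    stats::setNames(rep(0, s), rownames(m))
  dd <- igraph::distances(g, weights = dist_w)
  finite <- dd[is.finite(dd) & dd > 0]
  cap <- if (length(finite)) max(finite) * 10 else 1
  dd[!is.finite(dd)] <- cap
  isolated <- igraph::degree(g) == 0
  wc <- (s - 1) / rowSums(dd)
  wc[isolated] <- 0
  rescale1 <- function(v) if (sum(v) > 0) v / sum(v) else v
  tibble::tibble(species = rownames(m),
                 WB = rescale1(as.numeric(wb)),
                 WC = rescale1(as.numeric(wc)))
}

#' Species strength
#'
#' Sum over partners of the focal species' share of each partner's total
#' interactions: \eqn{SS_i = \sum_j X_{ij}/A_j}. Dependencies on partners
#' with zero total are 0. Over a whole level the strengths sum to the
#' number of non-empty partners.
#'
#' @inheritParams degree_indices
#' @return a tibble with columns `species`, `SS`.
#' @export
species_strength <- function(matrix, level = "plants") {
  m <- level_matrix(matrix, level)
  ct <- colSums(m)
  dep <- sweep(m, 2, ifelse(ct > 0, ct, 1), "/")
  dep[, ct == 0] <- 0
  tibble::tibble(species = rownames(m), SS = unname(rowSums(dep)))
}

#' Effective partners and species specificity
#'
#' `EP` is the exponential of the Shannon entropy of a species' interaction
#' weights (the "numbers equivalent" of partner diversity); `SSP` is the
#' coefficient of variation of its weights across all potential partners
#' (zeros included), divided by its maximum \eqn{\sqrt{m-1}} so that
#' \eqn{SSP \in [0,1]}: 1 when all weight is on one partner, 0 for a
#' perfectly even spread. `SSP_conv = 1 - SSP`. Zero-total species get `NA`.
#'
#' @inheritParams degree_indices
#' @return a tibble with columns `species`, `EP`, `SSP`, `SSP_conv`.
#' @export
diversity_indices <- function(matrix, level = "plants") {
  m <- level_matrix(matrix, level)
  n_part <- ncol(m)
  res <- apply(m, 1, function(x) {
    tot <- sum(x)
    if (tot == 0) return(c(EP = NA_real_, SSP = NA_real_))
    p <- x[x > 0] / tot
    ep <- exp(-sum(p * log(p)))
    # population CV, whose maximum over m partners is sqrt(m - 1)
    cv <- sqrt(mean((x - mean(x))^2)) / mean(x)
    c(EP = ep, SSP = cv / sqrt(n_part - 1))
  })
  tibble::tibble(species = rownames(m), EP = unname(res["EP", ]),
                 SSP = unname(res["SSP", ]),
                 SSP_conv = 1 - unname(res["SSP", ]))
}

#' Kullback-Leibler specialization d and standardized d'
#'
#' \eqn{d_i = \sum_j p'_{ij} \ln(p'_{ij}/q_j)} compares a species' partner
#' use \eqn{p'_{ij} = X_{ij}/A_i} with partner availability
#' \eqn{q_j = A_j/M}. `d_max` concentrates the species' total on the
#' scarcest partners (greedy, capped at partner totals); `d_min` is the
#' most opportunistic allocation compatible with the species total --
#' computed exactly over integer unit allocations when `scale = "counts"`
#' (separable-convex greedy, provably optimal), and 0 (proportional use)
#' otherwise. \eqn{d' = (d - d_{min})/(d_{max} - d_{min})}, clamped to
#' \[0, 1\]; a species with a single available partner gets `d' = 0`.
#' Converted values `1 - d` and `1 - d'` are included.
#'
#' @inheritParams degree_indices
#' @return a tibble with columns `species`, `d`, `d_prime`, `d_conv`,
#'   `d_prime_conv`.
#' @export
kl_specialization <- function(matrix, level = "plants") {
  m <- level_matrix(matrix, level)
  M <- sum(m)
  if (M <= 0) stop("grand total must be positive", call. = FALSE)
  q <- colSums(m) / M
  integer_units <- matrix_scale(matrix) == "counts" &&
    all(abs(m - round(m)) < 1e-9)

  one_row <- function(x) {
    A <- sum(x)
    if (A == 0) return(c(d = NA_real_, d_prime = NA_real_))
    p <- x[x > 0] / A
    d <- sum(p * log(p / q[x > 0]))
    d_max <- kl_dmax(A, q, colSums(m))
    d_min <- if (integer_units) kl_dmin_int(round(A), q) else 0
    dp <- if (d_max - d_min < 1e-12) 0 else (d - d_min) / (d_max - d_min)
    c(d = d, d_prime = min(1, max(0, dp)))
  }
  res <- apply(m, 1, one_row)
  d <- unname(res["d", ])
  dp <- unname(res["d_prime", ])
  tibble::tibble(species = rownames(m), d = d, d_prime = dp,
                 d_conv = 1 - d, d_prime_conv = 1 - dp)
}

# maximal divergence: the optimum of this convex objective sits at a
# vertex of {sum x = A, 0 <= x_j <= avail_j}; multi-start greedy -- each
# partner in turn taken as the primary sink, remainder poured into the
# scarcest partners first -- covers the concentration vertices
kl_dmax <- function(A, q, avail) {
  ok <- which(q > 0)
  ord <- ok[order(q[ok])]
  kl_of <- function(x) {
    p <- x[x > 0] / A
    sum(p * log(p / q[x > 0]))
  }
  fill_from <- function(first) {
    x <- numeric(length(q))
    left <- A
    for (j in c(first, setdiff(ord, first))) {
      take <- min(left, avail[j])
      x[j] <- take
      left <- left - take
      if (left <= 0) break
    }
    x
  }
  max(vapply(ok, function(j) kl_of(fill_from(j)), 0))
}

# exact integer minimiser of the KL divergence from availability:
# start at the floor of the continuous optimum A*q, then add the remaining
# units greedily by marginal cost (optimal for separable convex objectives)
kl_dmin_int <- function(A, q) {
  keep <- q > 0
  qq <- q[keep]
  x <- floor(A * qq)
  marg <- function(xj, qj)
    (xj + 1) * log((xj + 1) / (A * qj)) -
      ifelse(xj > 0, xj * log(xj / (A * qj)), 0)
  left <- A - sum(x)
  while (left > 0) {
    costs <- marg(x, qq)
    j <- which.min(costs)
    x[j] <- x[j] + 1
    left <- left - 1
  }
  p <- x[x > 0] / A
  sum(p * log(p / qq[x > 0]))
}

#' Core / periphery classification by standardized degree
#'
#' \eqn{G_c = (k_i - \bar k)/\mathrm{SD}(k)} within the trophic level;
#' species with \eqn{G_c \ge 1} are core, the rest periphery. With zero
#' degree variance every species is periphery (with a warning).
#'
#' @inheritParams degree_indices
#' @return a tibble with columns `species`, `Gc`, `core_flag`.
#' @export
core_periphery <- function(matrix, level = "plants") {
  m <- level_matrix(matrix, level)
  if (nrow(m) < 2) stop("need at least 2 species", call. = FALSE)
  k <- unname(rowSums(m > 0))
  s <- stats::sd(k)
  if (is.na(s) || s == 0) {
    warning("zero degree variance: all species classified periphery",
            call. = FALSE)
    gc <- rep(NA_real_, length(k))
  } else {
    gc <- (k - mean(k)) / s
  }
  tibble::tibble(species = rownames(m), Gc = gc,
                 core_flag = ifelse(!is.na(gc) & gc >= 1, "core", "periphery"))
}

#' All species-level indices for one trophic level
#'
#' Assembles degree (`D`, `ND`), nested rank (`NR`), weighted betweenness
#' and closeness (`WB`, `WC`), species strength (`SS`), effective partners
#' (`EP`, also reported as the per-species generality column `G`), species
#' specificity (`SSP`) and Kullback-Leibler specialization (`d`, `d_prime`),
#' with the conventional `1 - x` conversions for `d`, `d_prime`, `NR` and
#' `SSP`, plus the core/periphery flag.
#'
#' @inheritParams degree_indices
#' @param projection passed to [bipartite_centrality()].
#' @return a tibble, one row per species.
#' @export
species_indices <- function(matrix, level = "plants",
                            projection = "product") {
  tabs <- list(
    degree_indices(matrix, level),
    nested_rank(matrix, level),
    bipartite_centrality(matrix, level, projection),
    species_strength(matrix, level),
    diversity_indices(matrix, level),
    kl_specialization(matrix, level),
    suppressWarnings(core_periphery(matrix, level))
  )
  out <- purrr::reduce(tabs, dplyr::left_join, by = "species")
  dplyr::mutate(out, G = .data$EP, .after = "ND")
}

#' Mean and variance of each index column
#'
#' @param table a species-index tibble (e.g. from [species_indices()]).
#' @return a tibble with one row per numeric index: `index`, `mean`,
#'   `variance` (sample variance), `n`, `n_missing`.
#' @export
summarize_indices <- function(table) {
  num <- dplyr::select(tibble::as_tibble(table), dplyr::where(is.numeric))
  purrr::map_dfr(names(num), function(nm) {
    v <- num[[nm]]
    tibble::tibble(index = nm, mean = mean(v, na.rm = TRUE),
                   variance = stats::var(v, na.rm = TRUE),
                   n = sum(!is.na(v)), n_missing = sum(is.na(v)))
  })
}

#' Pairwise index correlations with redundancy flags
#'
#' Pearson correlations between all numeric index columns
#' (pairwise-complete observations), flagging |r| > 0.6 as redundant.
#' Extra score columns (e.g. a pulp-biomass flow) can be joined in by
#' species label before correlating.
#'
#' @param table a species-index tibble with a `species` column.
#' @param extra_columns optional tibble with `species` plus extra numeric
#'   scores to include.
#' @param threshold |r| above which a pair is flagged (default 0.6).
#' @return a long tibble: `index_x`, `index_y`, `r`, `n`, `high` (flag);
#'   the full correlation matrix is attached as attribute `"matrix"`.
#' @export
correlate_indices <- function(table, extra_columns = NULL, threshold = 0.6) {
  tab <- tibble::as_tibble(table)
  if (!is.null(extra_columns))
    tab <- dplyr::left_join(tab, tibble::as_tibble(extra_columns),
                            by = "species")
  num <- dplyr::select(tab, dplyr::where(is.numeric))
  keep <- vapply(num, function(v) sum(!is.na(v)) >= 3, TRUE)
  num <- num[, keep, drop = FALSE]
  cm <- suppressWarnings(stats::cor(num, use = "pairwise.complete.obs",
                                    method = "pearson"))
  nm <- colnames(cm)
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  out <- tibble::tibble(
    index_x = nm[pairs[, 1]], index_y = nm[pairs[, 2]],
    r = cm[pairs],
    n = apply(pairs, 1, function(ij)
      sum(stats::complete.cases(num[[ij[1]]], num[[ij[2]]]))),
    high = !is.na(cm[pairs]) & abs(cm[pairs]) > threshold
  )
  attr(out, "matrix") <- cm
  out
}
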