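#' Cophenetic (patristic) distance matrix from a tree
#'
#' Pairwise sums of branch lengths along the path between every pair of
#' tips.
#'
#' @param tree newick string, path to a newick file, or an `ape::phylo`
#'   object; branch lengths are required.
#' @return a symmetric numeric matrix with zero diagonal, tip labels as
#'   dimnames.
#' @examples
#' cophenetic_matrix("((A:1,B:1):1,C:2);")
#' @export
cophenetic_matrix <- function(tree) {
  phy <- as_phylo(tree)
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels", call. = FALSE)
  d <- ape::cophenetic.phylo(phy)
  d[phy$tip.label, phy$tip.label]
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1) {
    phy <- if (grepl("\\(", tree)) ape::read.tree(text = tree)
           else ape::read.tree(tree)
    if (is.null(phy)) stop("could not parse newick tree", call. = FALSE)
    return(phy)
  }
  stop("tree must be a phylo object or a newick string/file", call. = FALSE)
}

#' Mean pairwise and nearest-taxon distances of an assemblage
#'
#' Presence-based (unweighted) statistics: `MPD` is the mean cophenetic
#' distance over all unordered pairs of assemblage members; `MNTD` is the
#' mean, over members, of the distance to the nearest other member. Always
#' `MNTD <= MPD`.
#'
#' @param assemblage character vector of >= 2 taxa.
#' @param dist cophenetic distance matrix (see [cophenetic_matrix()]).
#' @return a named list with `MPD` and `MNTD`.
#' @export
distance_stats <- function(assemblage, dist) {
  assemblage <- unique(assemblage)
  if (length(assemblage) < 2)
    stop("assemblage needs at least 2 taxa", call. = FALSE)
  miss <- setdiff(assemblage, rownames(dist))
  if (length(miss))
    stop("taxa absent from distance matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  d <- dist[assemblage, assemblage]
  mpd <- mean(d[lower.tri(d)])
  diag(d) <- Inf
  mntd <- mean(apply(d, 1, min))
  list(MPD = mpd, MNTD = mntd)
}

#' Checkerboard-swap randomization of a binary community matrix
#'
#' Runs a trial-swap Markov chain: at each attempt a random 2 x 2 submatrix
#' is examined and swapped when it is a checkerboard
#' (\eqn{[[1,0],[0,1]] \leftrightarrow [[0,1],[1,0]]}). Row and column
#' totals are preserved exactly, so the null conditions on both species
#' frequencies and assemblage richness ("independent swap"). The default
#' chain length is a burn-in of `10 * fill` successful swaps.
#'
#' @param presence binary matrix (assemblages x taxa).
#' @param n_swaps number of successful swaps to perform; default
#'   `10 * fill`.
#' @param seed optional integer seed.
#' @return a binary matrix with identical marginals; if no checkerboard
#'   exists the input is returned with a warning.
#' @export
swap_randomize <- function(presence, n_swaps = NULL, seed = NULL) {
  b <- as.matrix(presence)
  if (!all(b %in% c(0, 1))) stop("presence matrix must be binary",
                                 call. = FALSE)
  storage.mode(b) <- "integer"
  if (is.null(n_swaps)) n_swaps <- 10L * sum(b)
  if (!has_checkerboard(b)) {
    warning("no checkerboard submatrix: matrix returned unchanged",
            call. = FALSE)
    return(b)
  }
  run <- function() swap_chain(b, n_swaps)
  out <- if (is.null(seed)) run() else
    withr::with_seed(as.integer(seed), run())
  out$m
}

# trial-swap chain running to n successful swaps (attempt-capped)
swap_chain <- function(b, n_swaps) {
  out <- swap_chain_cpp(b, n_swaps, max_attempts = max(1e6, 500 * n_swaps))
  dimnames(out$m) <- dimnames(b)
  out
}

has_checkerboard <- function(b) {
  s <- b %*% t(1L - b)
  any(s > 0 & t(s) > 0)
}

#' NRI/NTI of every assemblage against an independent-swap null
#'
#' For each row of the presence matrix (the assemblage of taxa attached to
#' that focal species), computes observed MPD and MNTD on the cophenetic
#' distances and compares them with `runs` null assemblages obtained by
#' checkerboard-swap randomization of the whole community matrix (thinned
#' chains; marginals preserved). The standardized effect sizes are
#' sign-flipped so that positive values mean phylogenetic aggregation:
#' \deqn{NRI = -\frac{MPD_{obs} - \overline{MPD}_{null}}{SD(MPD_{null})}}
#' and NTI analogously with MNTD. Classification uses the two-tailed null
#' quantiles at `alpha`: `aggregated` when the observed value falls below
#' the \eqn{\alpha/2} quantile, `dispersed` above the \eqn{1-\alpha/2}
#' quantile, `random` otherwise. Assemblages with undefined null SD are
#' classified `random` with a warning.
#'
#' @param presence binary matrix, focal species as rows, taxa as columns.
#' @param dist cophenetic distance matrix covering all column taxa.
#' @param runs number of null replicates (>= 99).
#' @param seed integer master seed.
#' @param alpha two-tailed significance level (default 0.05).
#' @param burnin,thin swap attempts before the first sample and between
#'   samples; default `10 * fill` and `fill`.
#' @return a tibble, one row per focal species: `species`, `n_taxa`, `MPD`,
#'   `MNTD`, `NRI`, `NTI`, `p_mpd`, `p_mntd`, `class_nri`, `class_nti`.
#' @export
ensemble_indices <- function(presence, dist, runs = 999, seed = 1,
                             alpha = 0.05, burnin = NULL, thin = NULL) {
  if (runs < 99) stop("use at least 99 null runs", call. = FALSE)
  b <- as.matrix(presence)
  if (!all(b %in% c(0, 1))) stop("presence matrix must be binary",
                                 call. = FALSE)
  storage.mode(b) <- "integer"
  taxa <- colnames(b) %||% rownames(dist)[seq_len(ncol(b))]
  colnames(b) <- taxa
  miss <- setdiff(taxa, rownames(dist))
  if (length(miss))
    stop("taxa absent from distance matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- dist[taxa, taxa]
  fill <- sum(b)
  burnin <- burnin %||% (10L * fill)
  thin <- thin %||% fill

  obs <- row_phylo_stats(b, d)
  null_mpd <- matrix(NA_real_, runs, nrow(b))
  null_mntd <- matrix(NA_real_, runs, nrow(b))
  if (has_checkerboard(b)) {
    withr::with_seed(as.integer(seed), {
      cur <- swap_chain(b, burnin)$m
      for (rep in seq_len(runs)) {
        cur <- swap_chain(cur, thin)$m
        st <- row_phylo_stats(cur, d)
        null_mpd[rep, ] <- st$MPD
        null_mntd[rep, ] <- st$MNTD
      }
    })
  } else {
    # no checkerboard: the null ensemble is the matrix itself
    null_mpd[] <- rep(obs$MPD, each = runs)
    null_mntd[] <- rep(obs$MNTD, each = runs)
  }

  ses <- function(o, nulls) {
    mu <- colMeans(nulls, na.rm = TRUE)
    sdv <- apply(nulls, 2, stats::sd, na.rm = TRUE)
    -(o - mu) / sdv
  }
  rank_p <- function(o, nulls) {
    # two-tailed rank position of the observed value in the null
    vapply(seq_along(o), function(i) {
      v <- nulls[, i]
      v <- v[!is.na(v)]
      if (!length(v) || is.na(o[i])) return(NA_real_)
      lo <- (1 + sum(v <= o[i])) / (length(v) + 1)
      hi <- (1 + sum(v >= o[i])) / (length(v) + 1)
      2 * min(lo, hi)
    }, 0)
  }
  classify <- function(o, nulls) {
    vapply(seq_along(o), function(i) {
      v <- nulls[, i]
      v <- v[!is.na(v)]
      if (is.na(o[i]) || length(v) < 2 || stats::sd(v) == 0)
        return("random")
      qs <- stats::quantile(v, c(alpha / 2, 1 - alpha / 2), names = FALSE)
      if (o[i] < qs[1]) "aggregated"
      else if (o[i] > qs[2]) "dispersed"
      else "random"
    }, "")
  }
  sd_zero <- apply(null_mpd, 2, function(v) stats::sd(v, na.rm = TRUE)) == 0
  if (any(sd_zero, na.rm = TRUE))
    warning("null SD is zero for some assemblages; indices undefined, ",
            "classified random", call. = FALSE)
  tibble::tibble(
    species = rownames(b) %||% paste0("A", seq_len(nrow(b))),
    n_taxa = rowSums(b),
    MPD = obs$MPD, MNTD = obs$MNTD,
    NRI = ses(obs$MPD, null_mpd), NTI = ses(obs$MNTD, null_mntd),
    p_mpd = rank_p(obs$MPD, null_mpd), p_mntd = rank_p(obs$MNTD, null_mntd),
    class_nri = classify(obs$MPD, null_mpd),
    class_nti = classify(obs$MNTD, null_mntd))
}

# MPD and MNTD for every row of a presence matrix (NA when < 2 taxa)
row_phylo_stats <- function(b, d) {
  k <- unname(rowSums(b))
  quad <- unname(rowSums((b %*% d) * b))    # sum over ordered pairs
  mpd <- ifelse(k >= 2, quad / (k * (k - 1)), NA_real_)
  mntd <- vapply(seq_len(nrow(b)), function(i) {
    idx <- which(b[i, ] == 1)
    if (length(idx) < 2) return(NA_real_)
    ds <- d[idx, idx, drop = FALSE]
    diag(ds) <- Inf
    mean(apply(ds, 1, min))
  }, 0)
  list(MPD = mpd, MNTD = mntd)
}
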