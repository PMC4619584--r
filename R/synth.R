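#' Generate a synthetic consumption matrix with tunable structure
#'
#' Draws a plant x frugivore count matrix whose binary skeleton interpolates
#' between three archetypes: a perfectly nested (strict threshold /
#' triangular) web at `nestedness_level = 1`, a one-to-one (block-diagonal)
#' matching at `specialization_level = 1`, and Bernoulli noise at base
#' connectance when both levels are 0. Each cell independently takes its
#' presence from the nested skeleton with probability `nestedness_level`,
#' from the diagonal matching with probability `specialization_level`, and
#' from a Bernoulli(`base_connectance`) draw otherwise, so the two levels
#' must sum to at most 1. Positive cells receive integer weights from a
#' rounded log-normal with median `mean_weight` (minimum 1), and every row
#' and column is guaranteed at least one interaction.
#'
#' @param n_plants,n_frugivores dimensions, both >= 2.
#' @param nestedness_level,specialization_level reals in \[0, 1\], summing
#'   to <= 1. `specialization_level = 1` requires a square matrix.
#' @param mean_weight median of the log-normal weight distribution (> 0).
#' @param seed integer seed; identical seeds give identical matrices.
#' @param base_connectance fill probability of the noise component.
#' @return a count-scale [consumption_matrix()].
#' @examples
#' gen_matrix(4, 4, nestedness_level = 1, specialization_level = 0, seed = 1)
#' @export
gen_matrix <- function(n_plants = 73, n_frugivores = 82,
                       nestedness_level = 0.5, specialization_level = 0.25,
                       mean_weight = 25, seed = 1,
                       base_connectance = 0.08) {
  if (n_plants < 2 || n_frugivores < 2)
    stop("need at least 2 species per level", call. = FALSE)
  if (nestedness_level < 0 || nestedness_level > 1 ||
      specialization_level < 0 || specialization_level > 1)
    stop("structure levels must lie in [0, 1]", call. = FALSE)
  if (nestedness_level + specialization_level > 1 + 1e-12)
    stop("nestedness_level + specialization_level must not exceed 1",
         call. = FALSE)
  if (specialization_level == 1 && n_plants != n_frugivores)
    stop("a perfect diagonal matching needs equal dimensions", call. = FALSE)
  if (mean_weight <= 0) stop("mean_weight must be positive", call. = FALSE)

  withr::with_seed(as.integer(seed), {
    # strict-threshold (triangular) skeleton: row i uses partners 1..k_i
    k_i <- pmax(1L, round(n_frugivores * (n_plants - seq_len(n_plants) + 1) /
                            n_plants))
    nested <- outer(seq_len(n_plants), seq_len(n_frugivores),
                    function(i, j) j <= k_i[i]) * 1L
    # round-robin (block-)diagonal matching
    diag_sk <- matrix(0L, n_plants, n_frugivores)
    diag_sk[cbind(seq_len(n_plants),
                  (seq_len(n_plants) - 1L) %% n_frugivores + 1L)] <- 1L

    u <- matrix(stats::runif(n_plants * n_frugivores), n_plants)
    noise <- matrix(stats::rbinom(n_plants * n_frugivores, 1,
                                  base_connectance), n_plants)
    skel <- ifelse(u < nestedness_level, nested,
                   ifelse(u < nestedness_level + specialization_level,
                          diag_sk, noise))

    # every row and column must stay in the web
    for (i in which(rowSums(skel) == 0))
      skel[i, sample.int(n_frugivores, 1)] <- 1L
    for (j in which(colSums(skel) == 0))
      skel[sample.int(n_plants, 1), j] <- 1L

    w <- matrix(0, n_plants, n_frugivores)
    npos <- sum(skel)
    w[skel == 1] <- pmax(1, round(stats::rlnorm(npos, log(mean_weight), 0.6)))
    dimnames(w) <- list(sprintf("P%02d", seq_len(n_plants)),
                        sprintf("F%02d", seq_len(n_frugivores)))
    consumption_matrix(w, scale = "counts")
  })
}

#' Simulate a focal-observation visit log realizing a latent matrix
#'
#' Generates per-visit records whose expectation under [fruits_handled()]
#' recovers the latent matrix cell-wise: for each positive cell the number
#' of visits is 1 + Poisson(`mean_visits` - 1), visit durations are
#' exponential with mean `mean_visit_min` minutes, and fruits per focal
#' interval are Poisson with rate chosen so that expected total feeding
#' time times the true feeding rate equals the cell weight. Zero cells
#' produce no records.
#'
#' @param matrix latent count-scale [consumption_matrix()]; weights are the
#'   expected fruits handled per observation block.
#' @param hours_per_plant nominal observation effort (h), carried as
#'   metadata; must be positive.
#' @param seed integer seed.
#' @param mean_visits expected visits per positive pair (>= 1).
#' @param mean_visit_min mean visit duration in minutes.
#' @param primate_fraction leading fraction of frugivore columns treated as
#'   primate-like (30 s focal intervals); the rest get 10 s bird intervals.
#' @return a visit-record tibble (see [fruits_handled()]).
#' @export
gen_visit_log <- function(matrix, hours_per_plant = 46, seed = 1,
                          mean_visits = 4, mean_visit_min = 5,
                          primate_fraction = 1 / 3) {
  if (hours_per_plant <= 0) stop("hours_per_plant must be positive",
                                 call. = FALSE)
  if (mean_visits < 1) stop("mean_visits must be >= 1", call. = FALSE)
  m <- as.matrix(matrix)
  nf <- ncol(m)
  interval_s <- ifelse(seq_len(nf) <= ceiling(nf * primate_fraction), 30L, 10L)

  withr::with_seed(as.integer(seed), {
    cells <- which(m > 0, arr.ind = TRUE)
    recs <- lapply(seq_len(nrow(cells)), function(k) {
      i <- cells[k, 1]; j <- cells[k, 2]
      x <- m[i, j]
      n_vis <- 1L + stats::rpois(1, mean_visits - 1)
      durs <- stats::rexp(n_vis, rate = 1 / mean_visit_min)
      # true rate (fruits / min) making the estimator unbiased
      r <- x / (mean_visits * mean_visit_min)
      iv <- interval_s[j]
      counts <- lapply(durs, function(d) {
        n_foc <- max(1L, round(d * 60 / iv))
        stats::rpois(n_foc, r * iv / 60)
      })
      tibble::tibble(
        plant = rownames(m)[i], frugivore = colnames(m)[j],
        duration_min = durs, focal_counts = counts,
        focal_interval_s = iv)
    })
    log <- dplyr::bind_rows(recs)
    attr(log, "hours_per_plant") <- hours_per_plant
    log
  })
}

#' Write / read a visit log as delimited text
#'
#' Focal counts are serialized as a semicolon-joined field so the log is a
#' plain CSV; the round trip is lossless.
#'
#' @param log visit-record tibble.
#' @param path file path.
#' @export
write_visit_log <- function(log, path) {
  out <- dplyr::mutate(
    tibble::as_tibble(log),
    focal_counts = vapply(.data$focal_counts,
                          function(v) paste(v, collapse = ";"), ""))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_visit_log
#' @export
read_visit_log <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    plant = readr::col_character(), frugivore = readr::col_character(),
    duration_min = readr::col_double(),
    focal_counts = readr::col_character(),
    focal_interval_s = readr::col_integer()))
  df$focal_counts <- lapply(strsplit(
    ifelse(is.na(df$focal_counts), "", df$focal_counts), ";"),
    function(v) as.numeric(v[nzchar(v)]))
  df
}

#' Simulate a Yule (pure-birth) phylogeny
#'
#' @param n_taxa number of tips (>= 2).
#' @param birth_rate speciation rate (> 0).
#' @param seed integer seed.
#' @return a newick string with unique tip labels, positive branch lengths
#'   and a terminal semicolon.
#' @export
gen_phylogeny <- function(n_taxa, birth_rate = 1, seed = 1) {
  if (n_taxa < 2) stop("need at least 2 taxa", call. = FALSE)
  if (birth_rate <= 0) stop("birth_rate must be positive", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    tr <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
    tr$tip.label <- sprintf("t%03d", seq_len(n_taxa))
    ape::write.tree(tr)
  })
}

#' Sample an assemblage with controlled phylogenetic structure
#'
#' `clustered`: a focal tip plus its `k - 1` nearest neighbours by
#' cophenetic distance. `dispersed`: greedy maximin selection (each new tip
#' maximizes its minimum distance to the already-selected set). `random`:
#' uniform sample without replacement. Structure is defined on cophenetic
#' distance, matching how MPD/MNTD measure it.
#'
#' @param tree newick string or `phylo` object.
#' @param k assemblage size, `2 <= k < n_tips`.
#' @param mode `"clustered"`, `"dispersed"` or `"random"`.
#' @param seed integer seed.
#' @param focal optional focal tip label for the clustered / dispersed
#'   start; random tip if `NULL`.
#' @return character vector of `k` tip labels.
#' @export
gen_assemblage <- function(tree, k, mode = c("clustered", "dispersed",
                                             "random"),
                           seed = 1, focal = NULL) {
  mode <- match.arg(mode)
  d <- cophenetic_matrix(tree)
  tips <- rownames(d)
  n <- length(tips)
  if (k < 2 || k >= n)
    stop("k must satisfy 2 <= k < number of tips", call. = FALSE)
  if (!is.null(focal) && !focal %in% tips)
    stop("focal tip not in tree", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    switch(mode,
      random = sample(tips, k),
      clustered = {
        f <- focal %||% sample(tips, 1)
        others <- setdiff(tips, f)
        nearest <- others[order(d[f, others], others)][seq_len(k - 1)]
        c(f, nearest)
      },
      dispersed = {
        sel <- focal %||% sample(tips, 1)
        while (length(sel) < k) {
          rest <- setdiff(tips, sel)
          mind <- apply(d[rest, sel, drop = FALSE], 1, min)
          sel <- c(sel, rest[order(-mind, rest)][1])
        }
        sel
      })
  })
}
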