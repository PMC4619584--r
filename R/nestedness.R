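#' NODF nestedness of a binary matrix
#'
#' Nestedness metric based on Overlap and Decreasing Fill. For every pair of
#' rows (and of columns), the paired nestedness is
#' \eqn{NP = 100 \cdot |\text{shared presences}| / \text{fill(poorer)}} when
#' the richer member has strictly larger fill, and 0 otherwise (including
#' ties). NODF averages NP over all \eqn{n_r(n_r-1)/2 + n_c(n_c-1)/2} pairs,
#' giving a value in \[0, 100\]; 100 is a perfectly nested (strict
#' threshold) matrix.
#'
#' @param binary a 0/1 matrix (use [binarize()] on weighted webs).
#' @return NODF in \[0, 100\].
#' @examples
#' tri <- outer(1:4, 1:4, function(i, j) (j <= 5 - i) * 1)
#' nodf(tri)  # 100
#' @export
nodf <- function(binary) {
  b <- as.matrix(binary)
  if (!all(b %in% c(0, 1)))
    stop("nodf() needs a binary matrix; apply binarize() first",
         call. = FALSE)
  paired_sum <- function(m) {
    if (nrow(m) < 2) return(0)
    f <- rowSums(m)
    shared <- m %*% t(m)
    poor <- outer(f, f, pmin)
    decreasing <- outer(f, f, "!=") & poor > 0
    np <- ifelse(decreasing, 100 * shared / pmax(poor, 1), 0)
    sum(np[upper.tri(np)])
  }
  n_r <- nrow(b); n_c <- ncol(b)
  denom <- n_r * (n_r - 1) / 2 + n_c * (n_c - 1) / 2
  (paired_sum(b) + paired_sum(t(b))) / denom
}

#' ER and CE binary null matrices
#'
#' ER ("equiprobable") fills each cell with probability \eqn{F/(n_r n_c)},
#' the observed connectance. CE ("row-column probability") fills cell
#' \eqn{(i,j)} with probability \eqn{(f_i/n_c + g_j/n_r)/2}, the average of
#' the row and column fill proportions. Dimensions are preserved.
#'
#' @param template binary template matrix.
#' @param model `"ER"` or `"CE"`.
#' @param seed optional integer seed.
#' @return a binary matrix of the template's dimensions.
#' @export
null_matrix <- function(template, model = c("ER", "CE"), seed = NULL) {
  model <- match.arg(toupper(model), c("ER", "CE"))
  b <- as.matrix(template)
  if (!all(b %in% c(0, 1))) stop("template must be binary", call. = FALSE)
  if (length(b) == 0) stop("empty template", call. = FALSE)
  n_r <- nrow(b); n_c <- ncol(b)
  p <- if (model == "ER") {
    matrix(sum(b) / (n_r * n_c), n_r, n_c)
  } else {
    outer(rowSums(b) / n_c, colSums(b) / n_r, function(fi, gj) (fi + gj) / 2)
  }
  draw <- function() {
    out <- matrix(stats::rbinom(n_r * n_c, 1, pmin(1, p)), n_r, n_c)
    dimnames(out) <- dimnames(b)
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Vazquez null matrix conserving total and connectance
#'
#' Draws a weighted null web with the template's grand total \eqn{M} and
#' fill \eqn{F} exactly: the binary skeleton is filled cell by cell with
#' probability proportional to \eqn{(A_i/M)(A_j/M)} (the weighted marginal
#' product), forcing every row and column to retain at least one
#' interaction, until exactly \eqn{F} cells are occupied; the remaining
#' \eqn{M - F} interaction units are then spread multinomially over the
#' occupied cells with the same probabilities.
#'
#' @param template a count-scale [consumption_matrix()] with integer total.
#' @param seed optional integer seed.
#' @return a count-scale [consumption_matrix()] with identical `M` and `F`.
#' @export
vaznull_matrix <- function(template, seed = NULL) {
  m <- as.matrix(template)
  n_r <- nrow(m); n_c <- ncol(m)
  empty_r <- rowSums(m) == 0; empty_c <- colSums(m) == 0
  if (any(empty_r) || any(empty_c)) {
    warning("dropping empty rows/columns for vaznull", call. = FALSE)
    m <- m[!empty_r, !empty_c, drop = FALSE]
    n_r <- nrow(m); n_c <- ncol(m)
  }
  mg <- matrix_marginals(m)
  M <- round(mg$M); F_fill <- mg$F
  if (M < F_fill) stop("grand total below fill: not a count matrix",
                       call. = FALSE)
  if (F_fill < n_r + n_c - 1)
    stop("fill too low to cover every row and column", call. = FALSE)
  p <- outer(mg$A_plant / mg$M, mg$A_frug / mg$M)

  draw <- function() {
    skel <- matrix(0L, n_r, n_c)
    # seed one interaction in every row and column first
    for (i in sample.int(n_r)) {
      j <- sample.int(n_c, 1, prob = p[i, ])
      skel[i, j] <- 1L
    }
    for (j in which(colSums(skel) == 0)) {
      i <- sample.int(n_r, 1, prob = p[, j])
      skel[i, j] <- 1L
    }
    free <- which(skel == 0)
    extra <- F_fill - sum(skel)
    if (extra > 0) {
      pick <- sample(free, extra, prob = p[free])
      skel[pick] <- 1L
    }
    filled <- which(skel == 1)
    spread <- stats::rmultinom(1, M - length(filled), prob = p[filled])[, 1]
    out <- matrix(0, n_r, n_c, dimnames = dimnames(m))
    out[filled] <- 1 + spread
    consumption_matrix(out, scale = "counts")
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Network-level specialization H2'
#'
#' The two-dimensional Shannon entropy of the interaction frequencies,
#' \eqn{H_2 = -\sum_{ij} (X_{ij}/M)\ln(X_{ij}/M)}, standardized between the
#' marginal-constrained extremes: \eqn{H_{2max}} from the entropy-maximizing
#' proportional fill \eqn{p_{ij} = (A_i A_j)/M^2} and \eqn{H_{2min}} from a
#' greedy concentration that repeatedly assigns
#' \eqn{\min(\text{remaining row}, \text{remaining column})} to the cell
#' pairing the largest remaining marginals.
#' \eqn{H_2' = (H_{2max} - H_2)/(H_{2max} - H_{2min})}, clamped to \[0,1\]:
#' 0 for a maximally generalized web, 1 for maximal specialization.
#'
#' @param matrix a [consumption_matrix()] (any non-negative matrix).
#' @return H2' in \[0, 1\], or `NA` when the extremes coincide (single row
#'   or column).
#' @export
h2_prime <- function(matrix) {
  m <- as.matrix(matrix)
  M <- sum(m)
  if (M <= 0) stop("grand total must be positive", call. = FALSE)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  h2 <- ent(m / M)
  r <- rowSums(m) / M
  c_ <- colSums(m) / M
  h2max <- ent(outer(r, c_))
  h2min <- ent(h2min_fill(rowSums(m), colSums(m)) / M)
  if (abs(h2max - h2min) < 1e-12) return(NA_real_)
  min(1, max(0, (h2max - h2) / (h2max - h2min)))
}

# greedy concentration: repeatedly pour min(remaining row, remaining col)
# into the cell pairing the largest remaining marginals
h2min_fill <- function(rt, ct) {
  out <- matrix(0, length(rt), length(ct))
  rt <- as.numeric(rt); ct <- as.numeric(ct)
  while (sum(rt) > 1e-12) {
    i <- which.max(rt); j <- which.max(ct)
    amt <- min(rt[i], ct[j])
    out[i, j] <- out[i, j] + amt
    rt[i] <- rt[i] - amt
    ct[j] <- ct[j] - amt
  }
  out
}

#' Null-model significance test for NODF or H2'
#'
#' Draws `replicates` null matrices (ER or CE binary nulls for NODF;
#' vaznull weighted nulls for H2' or NODF) and reports the observed
#' statistic, the null distribution, its mean and SD, a z-score and the
#' one-tailed empirical p-value with the +1 correction
#' \eqn{p = (1 + \#\{null \ge obs\})/(R + 1)} (or \eqn{\le} with
#' `direction = "less"`), so p is never exactly 0.
#'
#' @param matrix a [consumption_matrix()].
#' @param statistic `"NODF"` or `"H2"`.
#' @param model `"ER"`, `"CE"` or `"vaznull"`. Binary ER/CE nulls destroy
#'   the weights and are rejected for H2'.
#' @param replicates number of null draws (>= 2).
#' @param seed integer master seed; replicate seeds are derived by counter.
#' @param direction tail of the test: `"greater"` (default) counts nulls
#'   >= observed.
#' @return an object of class `null_test` with fields `statistic_name`,
#'   `observed`, `null_values`, `null_mean`, `null_sd`, `z`, `p`, `model`,
#'   `replicates`, `seed`. Methods: [tidy.null_test()],
#'   [glance.null_test()], [autoplot.null_test()].
#' @export
null_test <- function(matrix, statistic = c("NODF", "H2"),
                      model = c("ER", "CE", "vaznull"),
                      replicates = 1000, seed = 1,
                      direction = c("greater", "less")) {
  statistic <- match.arg(statistic)
  model <- match.arg(model)
  direction <- match.arg(direction)
  if (replicates < 2) stop("need at least 2 replicates", call. = FALSE)
  if (statistic == "H2" && model %in% c("ER", "CE"))
    stop("binary ER/CE nulls destroy interaction weights; use vaznull for H2'",
         call. = FALSE)
  if (statistic == "NODF" && model == "vaznull")
    warning("vaznull with NODF compares binary structure of weighted nulls",
            call. = FALSE)

  b <- suppressWarnings(binarize(matrix))
  observed <- if (statistic == "NODF") nodf(b) else h2_prime(matrix)
  stat_fun <- if (statistic == "NODF") {
    function(nm) nodf(suppressWarnings(binarize(nm)))
  } else {
    function(nm) h2_prime(nm)
  }
  seeds <- as.integer(seed) + seq_len(replicates)
  null_values <- vapply(seeds, function(s) {
    nm <- if (model == "vaznull") vaznull_matrix(matrix, seed = s)
          else null_matrix(b, model, seed = s)
    stat_fun(nm)
  }, 0)
  null_mean <- mean(null_values, na.rm = TRUE)
  null_sd <- stats::sd(null_values, na.rm = TRUE)
  n_ok <- sum(!is.na(null_values))
  extreme <- if (direction == "greater")
    sum(null_values >= observed, na.rm = TRUE)
  else sum(null_values <= observed, na.rm = TRUE)
  structure(list(
    statistic_name = statistic, observed = observed,
    null_values = null_values, null_mean = null_mean, null_sd = null_sd,
    z = if (!is.na(null_sd) && null_sd > 0)
      (observed - null_mean) / null_sd else NA_real_,
    p = (1 + extreme) / (n_ok + 1),
    model = model, replicates = replicates, seed = seed,
    direction = direction), class = "null_test")
}

#' @export
print.null_test <- function(x, ...) {
  cat(sprintf("<null_test> %s vs %s null (%d replicates)\n",
              x$statistic_name, x$model, x$replicates))
  cat(sprintf("  observed = %.4g; null mean = %.4g (SD %.4g); z = %.3g; p %s\n",
              x$observed, x$null_mean, x$null_sd, x$z,
              if (x$p <= 1 / (x$replicates + 1))
                sprintf("< %.4g", 1 / x$replicates) else
                sprintf("= %.4g", x$p)))
  invisible(x)
}
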