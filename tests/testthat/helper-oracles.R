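# Independent oracles used across the suite. Everything here is
# deliberately naive (enumeration / direct simulation) and shares no code
# with the package internals it checks.

# all length(caps) vectors of non-negative integers summing to `total`,
# with part j capped at caps[j]
enum_compositions <- function(total, caps) {
  if (length(caps) == 1) {
    if (total <= caps[1]) return(list(total)) else return(list())
  }
  out <- list()
  for (v in 0:min(total, caps[1])) {
    rest <- enum_compositions(total - v, caps[-1])
    out <- c(out, lapply(rest, function(r) c(v, r)))
  }
  out
}

# all non-negative integer matrices with the given row and column totals
enum_int_matrices <- function(rt, ct) {
  if (length(rt) == 1) {
    if (all(rt == sum(ct))) return(list(matrix(ct, 1))) else return(list())
  }
  out <- list()
  for (row in enum_compositions(rt[1], ct)) {
    rest <- enum_int_matrices(rt[-1], ct - row)
    out <- c(out, lapply(rest, function(m) rbind(row, m, deparse.level = 0)))
  }
  out
}

# all binary matrices with the given row and column totals
enum_binary_matrices <- function(rt, ct) {
  if (length(rt) == 1) {
    if (all(ct %in% 0:1) && sum(ct) == rt)
      return(list(matrix(as.integer(ct), 1)))
    return(list())
  }
  out <- list()
  cols <- if (rt[1] == 0) list(integer(0)) else
    utils::combn(length(ct), rt[1], simplify = FALSE)
  for (cc in cols) {
    row <- integer(length(ct))
    row[cc] <- 1L
    if (any(ct - row < 0)) next
    rest <- enum_binary_matrices(rt[-1], ct - row)
    out <- c(out, lapply(rest, function(m) rbind(row, m, deparse.level = 0)))
  }
  out
}

# shannon entropy of a count/probability matrix
shannon <- function(m) {
  p <- m / sum(m)
  p <- p[p > 0]
  -sum(p * log(p))
}

# brute-force secondary-extinction curve: plain set bookkeeping on the
# bipartite edge list, no shared code with the package
brute_curve <- function(bin, order) {
  edges <- which(bin > 0, arr.ind = TRUE)
  n_oth <- ncol(bin)
  alive_frac <- function(removed) {
    keep <- !(edges[, 1] %in% removed)
    length(unique(edges[keep, 2])) / n_oth
  }
  removed <- integer(0)
  ys <- alive_frac(removed)
  for (r in order) {
    removed <- c(removed, r)
    ys <- c(ys, alive_frac(removed))
  }
  data.frame(removed_frac = (0:length(order)) / length(order),
             surviving_frac = ys)
}

# a small reproducible weighted web with no empty rows or columns
random_web <- function(nr, nc, seed, density = 0.5, maxw = 9) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(nr * nc, 1, density) *
                  sample(1:maxw, nr * nc, replace = TRUE), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
  }
  consumption_matrix(m)
}

# hand tree used throughout the phylogenetic tests
HAND_TREE <- "((A:1,B:1):1,C:2);"
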