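test_that("degree and normalized degree count partners", {
  m <- consumption_matrix(rbind(c(1, 2, 3), c(0, 5, 0)))
  d <- degree_indices(m, "plants")
  expect_equal(d$D, c(3L, 1L))
  expect_equal(d$ND, c(1, 1 / 3))
  df <- degree_indices(m, "frugivores")
  expect_equal(df$D, c(1L, 2L, 1L))
})

test_that("nested rank is uniform on [0,1] with documented tie-breaks", {
  m <- consumption_matrix(rbind(c(1, 1, 1, 1, 1), c(1, 1, 1, 0, 0),
                                c(1, 0, 0, 0, 0)))
  nr <- nested_rank(m, "plants")
  expect_equal(nr$NR, c(0, 0.5, 1))
  expect_equal(nr$NR_conv, 1 - nr$NR)
  expect_equal(mean(nested_rank(random_web(9, 7, seed = 2))$NR), 0.5)
  # equal degrees: a and b tie on weight 10 (label breaks), c trails on 4
  tie <- consumption_matrix(rbind(c(1, 9), c(5, 5), c(2, 2)),
                            plant_labels = c("a", "b", "c"))
  expect_equal(nested_rank(tie)$NR, c(0, 0.5, 1))
  expect_error(nested_rank(consumption_matrix(matrix(1, 1, 3))), "at least 2")
})

test_that("betweenness concentrates on hubs and path interiors", {
  # star projection: hub shares a partner with every leaf, leaves share none
  star <- matrix(0, 5, 4)
  star[1, ] <- 1
  star[2:5, ] <- diag(4)
  cb <- bipartite_centrality(consumption_matrix(star), "plants")
  expect_equal(cb$WB, c(1, 0, 0, 0, 0))
  expect_equal(sum(cb$WC), 1)
  # 4-node path projection with equal weights: WB proportional to (0,2,2,0)
  path <- rbind(c(1, 0, 0), c(1, 1, 0), c(0, 1, 1), c(0, 0, 1))
  cp <- bipartite_centrality(consumption_matrix(path), "plants")
  expect_equal(cp$WB, c(0, 2, 2, 0) / 4)
  expect_equal(sum(cp$WC), 1)
})

test_that("centralities handle disconnected projections", {
  # two separate 2-plant components plus the rescale-to-1 invariant
  m <- consumption_matrix(rbind(c(2, 1, 0, 0), c(1, 1, 0, 0),
                                c(0, 0, 3, 1), c(0, 0, 1, 2)))
  cc <- bipartite_centrality(m, "plants")
  expect_equal(sum(cc$WC), 1, tolerance = 1e-9)
  expect_true(all(cc$WC > 0))
})

test_that("species strengths sum to the number of non-empty partners", {
  sole <- consumption_matrix(matrix(c(3, 1, 4), 1))
  expect_equal(species_strength(sole, "plants")$SS, 3)
  for (s in 1:5) {
    w <- random_web(6, 8, seed = s)
    expect_equal(sum(species_strength(w, "plants")$SS),
                 sum(colSums(as.matrix(w)) > 0))
    expect_equal(sum(species_strength(w, "frugivores")$SS),
                 sum(rowSums(as.matrix(w)) > 0))
  }
})

test_that("effective partners and specificity hit their closed forms", {
  m <- consumption_matrix(rbind(c(2, 2), c(4, 0), c(3, 3)))
  di <- diversity_indices(m, "plants")
  expect_equal(di$EP[1], 2)
  expect_equal(di$EP[2], 1)
  expect_equal(di$SSP[2], 1)   # all weight on one of two partners
  expect_equal(di$SSP[1], 0)   # perfectly even
  expect_equal(di$SSP_conv, 1 - di$SSP)
  # zero-total species are missing, not zero
  z <- consumption_matrix(rbind(c(1, 1), c(0, 0)))
  expect_true(is.na(diversity_indices(z)$EP[2]))
  # EP bounded by degree
  w <- random_web(7, 9, seed = 3)
  tab <- dplyr::left_join(diversity_indices(w), degree_indices(w), "species")
  expect_true(all(tab$EP >= 1 - 1e-9 & tab$EP <= tab$D + 1e-9))
})

test_that("d is zero for perfect opportunists and d' maximal on a diagonal", {
  # rows proportional to the availability marginals
  prop <- consumption_matrix(rbind(c(1, 2, 1), c(2, 4, 2)))
  kl <- kl_specialization(prop, "plants")
  expect_equal(kl$d, c(0, 0), tolerance = 1e-12)
  expect_equal(kl$d_prime, c(0, 0))
  dg <- consumption_matrix(diag(c(5, 5)))
  expect_equal(kl_specialization(dg)$d_prime, c(1, 1))
})

test_that("heuristic d bounds bracket the exhaustive enumeration", {
  set.seed(7)
  for (rep in 1:4) {
    repeat {
      m <- matrix(rpois(12, 0.8), 3, 4)
      if (sum(m) >= 4 && sum(m) <= 12 && all(rowSums(m) > 0) &&
          any(colSums(m) > 0)) break
    }
    cm <- consumption_matrix(m)
    q <- colSums(m) / sum(m)
    avail <- colSums(m)
    all_m <- enum_int_matrices(rowSums(m), colSums(m))
    for (i in 1:3) {
      A <- sum(m[i, ])
      dmax <- frugnet:::kl_dmax(A, q, avail)
      dmin <- frugnet:::kl_dmin_int(A, q)
      ds <- vapply(all_m, function(x) {
        p <- x[i, x[i, ] > 0] / A
        sum(p * log(p / q[x[i, ] > 0]))
      }, 0)
      expect_lte(dmin, min(ds) + 1e-9)
      expect_gte(dmax, max(ds) - 1e-9)
    }
    expect_true(all(kl_specialization(cm)$d_prime >= 0 &
                      kl_specialization(cm)$d_prime <= 1))
  }
})

test_that("core species are those at least one degree SD above the mean", {
  m <- matrix(0, 5, 10)
  m[1, 1:10] <- 1
  m[2:5, 1] <- 1
  cp <- core_periphery(consumption_matrix(m), "plants")
  expect_equal(cp$core_flag, c("core", rep("periphery", 4)))
  expect_warning(
    cp2 <- core_periphery(consumption_matrix(diag(3) + 0), "plants"),
    "zero degree variance")
  expect_true(all(cp2$core_flag == "periphery"))
})

test_that("gaining partners never demotes a species from the core", {
  set.seed(11)
  for (rep in 1:50) {
    w <- as.matrix(random_web(6, 8, seed = 100 + rep))
    zeros <- which(w == 0, arr.ind = TRUE)
    if (!nrow(zeros)) next
    pick <- zeros[sample(nrow(zeros), 1), ]
    before <- core_periphery(consumption_matrix(w))$core_flag[pick[1]]
    w2 <- w
    w2[pick[1], pick[2]] <- 1
    after <- core_periphery(consumption_matrix(w2))$core_flag[pick[1]]
    if (before == "core") expect_equal(after, "core")
  }
})

test_that("index summaries report means, variances and missingness", {
  tab <- tibble::tibble(species = letters[1:4], A = c(2, 2, 2, 2),
                        B = c(1, 2, 3, NA))
  s <- summarize_indices(tab)
  expect_equal(s$variance[s$index == "A"], 0)
  expect_equal(s$mean[s$index == "B"], 2)
  expect_equal(s$n_missing[s$index == "B"], 1)
  w <- random_web(8, 6, seed = 9)
  si <- summarize_indices(species_indices(w))
  expect_equal(si$mean[si$index == "NR"], 0.5)
})

test_that("index correlations flag redundancy and tolerate degeneracy", {
  w <- random_web(10, 8, seed = 13)
  tab <- species_indices(w)
  cors <- correlate_indices(tab)
  r_dnd <- cors$r[cors$index_x == "D" & cors$index_y == "ND" |
                    cors$index_x == "ND" & cors$index_y == "D"]
  expect_equal(r_dnd, 1)
  expect_true(cors$high[cors$r == r_dnd][1])
  # zero-variance extra column gives NA r, never a flag
  extra <- tibble::tibble(species = tab$species, const = 1)
  cz <- correlate_indices(tab, extra)
  expect_true(all(is.na(cz$r[cz$index_x == "const" | cz$index_y == "const"])))
})

test_that("indices are invariant to relabeled permutations and row scale", {
  w <- random_web(7, 6, seed = 17)
  orig <- species_indices(w)
  set.seed(4)
  pm <- as.matrix(w)[sample(7), sample(6)]
  perm <- species_indices(consumption_matrix(pm))
  expect_equal(as.data.frame(perm[order(perm$species), ]),
               as.data.frame(orig[order(orig$species), ]),
               tolerance = 1e-9, ignore_attr = TRUE)
  # count vs percent: presence-derived indices unchanged (NR only through
  # its degree ordering -- its weight tie-break legitimately depends on
  # row scale, so compare the degree-sorted ranks, not raw NR)
  pct <- species_indices(normalize_percent(w))
  for (col in c("D", "ND", "EP"))
    expect_equal(pct[[col]], orig[[col]], tolerance = 1e-9, label = col)
  for (dg in unique(orig$D))
    expect_equal(sort(pct$NR[pct$D == dg]), sort(orig$NR[orig$D == dg]))
})
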