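test_that("pulp flow multiplies its four ingredients with clean units", {
  tr <- tibble::tibble(species = "A", consumption_rate = 2,
                       pulp_dry_mass_per_fruit = 5, density = 10)
  expect_equal(pulp_flow(tr)$flow, 2 * 12 * 5 * 10)   # 1200 g/ha/day
  expect_equal(pulp_flow(tr, active_hours = 6)$flow, 600)
  # linearity in each single factor
  tr2 <- dplyr::mutate(tr, density = density * 2)
  expect_equal(pulp_flow(tr2)$flow, 2 * pulp_flow(tr)$flow)
  expect_equal(pulp_flow(dplyr::mutate(tr, density = 0))$flow, 0)
  # annualization by crop duration
  tra <- dplyr::mutate(tr, crop_duration = 3)
  expect_equal(pulp_flow(tra, annualize = TRUE)$flow, 1200 * 3 / 12)
  expect_error(pulp_flow(dplyr::mutate(tr, density = -1)), "negative")
})

test_that("missing ingredients yield missing flows with a reason", {
  tr <- tibble::tibble(species = c("A", "B"), consumption_rate = c(2, 1),
                       pulp_dry_mass_per_fruit = c(5, NA),
                       density = c(10, 3))
  out <- pulp_flow(tr)
  expect_true(is.na(out$flow[2]))
  expect_match(out$reason[2], "pulp_dry_mass_per_fruit")
  expect_equal(out$rank[1], 1L)
})

test_that("keystone ranking is a permutation and stable under relabeling", {
  tr <- tibble::tibble(species = c("c", "a", "b"), consumption_rate = 1,
                       pulp_dry_mass_per_fruit = 1, density = c(2, 9, 2))
  fl <- pulp_flow(tr)
  expect_setequal(fl$rank, 1:3)
  expect_equal(rank_keystones(fl, 3), c("a", "b", "c"))  # tie by label
  expect_equal(rank_keystones(fl, 1), "a")
  expect_error(rank_keystones(fl, 4), "exceeds")
  expect_length(keystone_overlap(fl$species, fl$species), 3)
})

test_that("the two published keystone lists share exactly four species", {
  pulp <- readr::read_csv(
    system.file("extdata", "table4_pulp_flow_top20.csv",
                package = "frugnet"), show_col_types = FALSE)
  scarcity <- readr::read_csv(
    system.file("extdata", "table4_scarcity_keystone_top20.csv",
                package = "frugnet"), show_col_types = FALSE)
  top_pulp <- rank_keystones(
    dplyr::rename(pulp, flow = "pulp_biomass_g_ha_day"), 20)
  shared <- keystone_overlap(top_pulp, scarcity$species)
  expect_length(shared, 4)
  expect_setequal(shared, c("Oenocarpus bataua", "Cecropia membranacea",
                            "Gustavia hexapetala", "Pseudolmedia hirsuta"))
})

test_that("abundance regressions recover proportional visitation exactly", {
  ab <- tibble::tibble(frugivore = paste0("f", 1:6),
                       abundance = c(1, 2, 4, 8, 16, 32))
  vt <- tibble::tibble(plant = "p", frugivore = ab$frugivore,
                       minutes = 3 * ab$abundance)
  # lm warns about the noiseless fit; the exact R^2 = 1 is the point
  res <- suppressWarnings(abundance_r2(vt, ab))
  expect_equal(res$r_squared, 1)
  expect_equal(res$slope_sign, 1)
  expect_equal(attr(res, "summary")$frac_positive, 1)
})

test_that("permuted abundances give the analytic null R-squared", {
  set.seed(6)
  n <- 11
  ab <- tibble::tibble(frugivore = paste0("f", 1:n),
                       abundance = rlnorm(n))
  minutes <- rlnorm(n)
  r2 <- vapply(1:1000, function(i) {
    vt <- tibble::tibble(plant = "p", frugivore = ab$frugivore,
                         minutes = sample(minutes))
    abundance_r2(vt, ab)$r_squared
  }, 0)
  # under independence E[R^2] = 1/(n-1)
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 3 * sd(r2) / sqrt(1000))
})

test_that("abundance-driven synthetic webs are detected as such", {
  set.seed(9)
  n_p <- 30; n_f <- 12
  ab <- tibble::tibble(frugivore = paste0("f", 1:n_f),
                       abundance = rlnorm(n_f, 0, 1))
  vt <- tidyr::expand_grid(plant = paste0("p", 1:n_p),
                           frugivore = ab$frugivore)
  vt <- dplyr::mutate(
    vt, minutes = rep(rlnorm(n_p, 2, 0.5), each = n_f) *
      ab$abundance[match(frugivore, ab$frugivore)] *
      exp(rnorm(nrow(vt), 0, 0.2)))
  res <- abundance_r2(vt, ab)
  expect_gte(attr(res, "summary")$frac_positive, 0.95)
  expect_gt(attr(res, "summary")$mean_r2, 0.5)
})

test_that("degenerate abundance input is skipped with a warning", {
  ab <- tibble::tibble(frugivore = paste0("f", 1:4), abundance = 2)
  vt <- tibble::tibble(plant = "p", frugivore = ab$frugivore,
                       minutes = 1:4)
  expect_warning(res <- abundance_r2(vt, ab), "zero abundance variance")
  expect_true(is.na(res$r_squared))
})

test_that("the seven-prediction battery reports signs and fits", {
  set.seed(3)
  n <- 39
  traits <- tibble::tibble(
    species = paste0("s", 1:n), pct_lipids = runif(n),
    crop_duration = runif(n), seed_width = runif(n),
    frugivore_size = runif(n), crop_size = runif(n),
    visitation_rate = runif(n), richness = runif(n),
    recruit_below_parents = runif(n))
  out <- prediction_battery(traits)
  expect_equal(nrow(out), 7)
  expect_equal(out$expected_sign, c("+", "+", "+", "-", "-", "-", "-"))
  expect_true(all(out$n == n))
  # injected strong association is recovered
  traits2 <- dplyr::mutate(traits,
                           seed_width = pct_lipids * 3 + rnorm(n, 0, 0.15))
  got <- prediction_battery(traits2)
  seed_row <- got[got$predictor == "seed_width", ]
  expect_equal(seed_row$sign, "+")
  expect_gt(seed_row$r_squared, 0.5)
})

test_that("uncorrelated traits rarely produce notable fits", {
  # under independence at n = 39, P(R^2 >= 0.1) is ~5% per regression
  set.seed(14)
  r2 <- vapply(1:100, function(i) {
    n <- 39
    traits <- tibble::tibble(
      species = paste0("s", 1:n), pct_lipids = runif(n),
      crop_duration = runif(n), seed_width = runif(n),
      frugivore_size = runif(n), crop_size = runif(n),
      visitation_rate = runif(n), richness = runif(n),
      recruit_below_parents = runif(n))
    prediction_battery(traits)$r_squared
  }, numeric(7))
  expect_lte(mean(r2 >= 0.1), 0.10)   # per-regression exceedance
  expect_lt(mean(r2), 0.05)           # mean null R^2 ~ 1/(n-1)
})

test_that("constant or absent predictors come back untested", {
  traits <- tibble::tibble(species = letters[1:5], pct_lipids = 0.3,
                           seed_width = 1:5)
  out <- prediction_battery(traits)
  expect_true(all(is.na(out$r_squared)))    # constant response
  traits2 <- tibble::tibble(species = letters[1:5], pct_lipids = runif(5))
  out2 <- prediction_battery(traits2)
  expect_true(all(out2$n == 0))
  expect_error(prediction_battery(tibble::tibble(species = "a")),
               "pct_lipids")
})

test_that("consumption rates divide totals by effort", {
  m <- consumption_matrix(rbind(c(100, 20), c(0, 60)))
  eff <- tibble::tibble(species = c("P1", "P2"), hours = c(10, 20),
                        n_trees = c(2, 3))
  cr <- consumption_rates(m, eff)
  expect_equal(cr$consumption_rate, c(120 / 20, 60 / 60))
})

test_that("flow built from shuffled densities is independent of degree", {
  m <- gen_matrix(25, 20, 0.5, 0.2, seed = 33)
  deg <- degree_indices(m, "plants")
  set.seed(4)
  traits <- tibble::tibble(
    species = deg$species, consumption_rate = rlnorm(25),
    pulp_dry_mass_per_fruit = rlnorm(25),
    density = sample(rlnorm(25, 1)))
  fl <- pulp_flow(traits)
  cors <- correlate_indices(deg, dplyr::select(fl, "species", "flow"))
  r <- cors$r[(cors$index_x == "D" & cors$index_y == "flow") |
                (cors$index_x == "flow" & cors$index_y == "D")]
  expect_lt(abs(r), 0.5)
})
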