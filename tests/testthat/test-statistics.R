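test_that("persistent entropy matches hand-evaluated formula values", {
  expect_equal(persistent_entropy(0, 1), 0)                  # single feature
  expect_equal(persistent_entropy(rep(0, 4), rep(2, 4)), log(4))
  # lifetimes {1, 3}: -(1/4 log 1/4 + 3/4 log 3/4)
  expect_equal(persistent_entropy(c(0, 0), c(1, 3)),
               -(0.25 * log(0.25) + 0.75 * log(0.75)))
  expect_true(is.na(persistent_entropy(numeric(0), numeric(0))))
  expect_error(persistent_entropy(c(0, 2), c(1, 2)), "death > birth")
})

make_diag <- function(dim, birth, death, essential = FALSE) {
  d <- data.frame(dim = dim, birth = birth, death = death,
                  birth_row = 1L, birth_col = 1L,
                  essential = rep_len(essential, length(dim)))
  class(d) <- c("persistence_diagram", class(d))
  d
}

test_that("panel equals hand arithmetic on a two-point diagram", {
  d <- make_diag(c(0, 0, 0), c(-5, -3, -9), c(2, 4, Inf),
                 essential = c(FALSE, FALSE, TRUE))
  p <- compute_panel(d)
  expect_equal(p$H0Q2_n_points, 2)
  expect_equal(p$H0Q2_birth_mean, -4)
  expect_equal(p$H0Q2_death_mean, 3)
  expect_equal(p$H0Q2_birth_median, -4)
  expect_equal(p$H0Q2_birth_iqr, p$H0Q2_birth_q75 - p$H0Q2_birth_q25)
  expect_equal(p$H0Q2_n_radius_ge, 2)
  expect_equal(p$H0Q2_n_radius_lt, 0)
  expect_equal(p$H0Q2_total_persistence, 7 + 7)
  expect_equal(p$H0Q2_entropy, persistent_entropy(c(-5, -3), c(2, 4)))
  # essential excluded from everything
  expect_equal(p$H1Q1_n_points, 0)
  expect_true(is.na(p$H1Q1_birth_mean))
})

test_that("radius-threshold counts partition the points", {
  d <- make_diag(c(0, 0), c(-1.5, -9), c(1, Inf),
                 essential = c(FALSE, TRUE))
  p <- compute_panel(d)
  expect_equal(p$H0Q2_n_radius_lt, 1)
  expect_equal(p$H0Q2_n_radius_ge, 0)
  # threshold is configurable
  p2 <- compute_panel(d, radius_threshold = 1)
  expect_equal(p2$H0Q2_n_radius_ge, 1)
})

test_that("panel columns cover the expected superset and the canonical 28", {
  expect_length(panel_stats(), 32)
  expect_length(canonical_stats(), 28)
  expect_true(all(canonical_stats() %in% panel_stats()))
  expect_length(feature_panel("panel10"), 10)
  expect_length(feature_panel("panel20"), 20)
  expect_true(all(feature_panel("panel20") %in% panel_stats()))
})

test_that("panel is permutation invariant and monotone under point addition", {
  set.seed(21)
  b <- -runif(6, 1, 5); dd <- runif(6, 0.5, 4)
  d1 <- make_diag(rep(0, 7), c(b, -9), c(dd, Inf),
                  essential = c(rep(FALSE, 6), TRUE))
  perm <- sample(7)
  d2 <- d1[perm, ]
  expect_equal(compute_panel(d1), compute_panel(d2), ignore_attr = TRUE)
  # adding one point increments the count and total persistence
  d3 <- rbind(d1, make_diag(0, -2, 1.5))
  p1 <- compute_panel(d1); p3 <- compute_panel(d3)
  expect_equal(p3$H0Q2_n_points, p1$H0Q2_n_points + 1)
  expect_equal(p3$H0Q2_total_persistence,
               p1$H0Q2_total_persistence + (1.5 - (-2)))
})

test_that("scale restriction filters by the window predicates", {
  d <- make_diag(c(0, 0, 0, 1), c(-5, -3, -1, 0.5), c(2, 4, 0.5, 3))
  expect_equal(nrow(restrict_scale(d)), 4)  # unbounded window is identity
  r <- restrict_scale(d, birth_window = c(-Inf, -2))
  expect_equal(nrow(r), 2)
  # birth window [-Inf, -thr] reproduces the n_radius_ge count
  p <- compute_panel(split_quadrants(d, check = FALSE))
  expect_equal(nrow(restrict_scale(d[d$dim == 0, ], c(-Inf, -2))),
               p$H0Q2_n_radius_ge)
  r2 <- restrict_scale(d, death_window = c(1, 3))
  expect_equal(nrow(r2), sum(d$death >= 1 & d$death <= 3))
})

test_that("patch score maps place statistics on the patch grid", {
  panels <- data.frame(patch_row = c(1, 1, 2), patch_col = c(1, 2, 2),
                       H0Q2_n_points = c(4, 7, 1))
  sm <- score_patches(panels, "H0Q2_n_points")
  expect_equal(dim(sm), c(2L, 2L))
  expect_equal(sm[1, 2], 7)
  expect_true(is.na(sm[2, 1]))  # discarded background tile
  expect_error(score_patches(panels, "no_such_stat"), "valid names")
  single <- data.frame(patch_row = 1, patch_col = 1, H0Q2_n_points = 3)
  expect_equal(dim(score_patches(single, "H0Q2_n_points")), c(1L, 1L))
})

test_that("planted disk fields are recovered by the panel within tolerance", {
  fld <- make_disk_field(8, radius_mean = 4, radius_sd = 0, min_gap = 30,
                         side = 300L, seed = 17)
  p <- patch_panel(fld$mask)
  expect_equal(p$H0Q2_n_points, 7)            # essential excluded
  expect_lte(abs(-p$H0Q2_birth_mean - 4), 1)
  # deaths approximate half the planted nearest-hole gaps (merge order is
  # not pinned down, so check against the planted gap range)
  expect_gte(p$H0Q2_death_mean, min(fld$truth$min_gap_to_next) / 2 - 1.5)
  expect_lte(p$H0Q2_death_mean, max(fld$truth$min_gap_to_next) / 2 + 1.5)
})
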