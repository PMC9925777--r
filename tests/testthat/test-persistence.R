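test_that("filtration cell counts and values follow the V-construction", {
  f2 <- matrix(c(1, 3, 2, 4), 2, 2)
  filt <- build_filtration(f2)
  expect_equal(table(filt$dim), table(c(0, 0, 0, 0, 1, 1, 1, 1, 2)),
               ignore_attr = TRUE)
  expect_equal(filt$value[filt$dim == 2], 4)
  # 1xn strip: n vertices, n-1 edges, no squares
  strip <- build_filtration(matrix(c(5, 1, 4, 2), 1, 4))
  expect_equal(as.vector(table(strip$dim)), c(4L, 3L))
  # faces never exceed their cofaces and order is the sorted (value, dim) order
  set.seed(12)
  f3 <- matrix(sample(1:9), 3, 3)
  filt3 <- build_filtration(f3)
  expect_equal(nrow(filt3), 9 + 12 + 4)
  expect_false(is.unsorted(filt3$value))
  ord <- order(filt3$value, filt3$dim, filt3$row, filt3$col)
  expect_equal(ord, seq_len(nrow(filt3)))
})

test_that("a strip with distinct values pairs components by the elder rule", {
  # values 5,1,4,2; edges take the max of their endpoints: (5,1)->5,
  # (1,4)->4, (4,2)->4. Union-find by hand, ascending: edge (1,4) kills the
  # component born at 4 (pair (4,4), zero persistence, dropped); edge (4,2)
  # merges {1,4} with {2}, killing the component born at 2 at value 4 (pair
  # (2,4)); edge (5,1) kills the component born at 5 (pair (5,5), dropped).
  # The essential class is born at the global minimum 1.
  d <- compute_persistence(matrix(c(5, 1, 4, 2), 1, 4))
  h0 <- d[d$dim == 0 & !d$essential, ]
  expect_equal(nrow(h0), 1)
  expect_equal(c(h0$birth, h0$death), c(2, 4))
  expect_equal(d$birth[d$essential], 1)
  expect_equal(sum(d$dim == 1), 0)
})

test_that("a black annulus yields one micro-hole loop crossing zero", {
  m <- matrix(TRUE, 21, 21)
  rows <- row(m); cols <- col(m)
  d2 <- (rows - 11)^2 + (cols - 11)^2
  m[d2 <= 64 & d2 > 16] <- FALSE   # ring: outer radius 8, inner 4
  diag <- split_quadrants(compute_persistence(signed_edt(m)))
  h1 <- diag[diag$dim == 1, ]
  expect_equal(nrow(h1), 1)
  expect_lt(h1$birth, 0)
  expect_gt(h1$death, 0)
  expect_equal(h1$quadrant, 2L)
  # the loop outlives any other H1 feature by construction (it is unique)
  expect_equal(sum(diag$dim == 1 & diag$quadrant == 2L), 1)
})

test_that("diagram alive-counts equal oracle Betti numbers on random fields", {
  set.seed(99)
  for (rep in 1:60) {
    H <- sample(3:12, 1); W <- sample(3:12, 1)
    f <- matrix(sample(-8:8, H * W, replace = TRUE), H, W)
    d <- compute_persistence(f)
    thr <- sort(unique(as.vector(f)))
    oc <- oracle_betti_curve(f, thr)
    expect_equal(vapply(thr, alive_at, numeric(1), diag = d, dim = 0), oc$beta0)
    expect_equal(vapply(thr, alive_at, numeric(1), diag = d, dim = 1), oc$beta1)
  }
})

test_that("the diagram is invariant to tie order in equal-valued cells", {
  # many ties: binary-valued field; compare against oracle (order-free)
  set.seed(5)
  f <- matrix(sample(c(-1, 1), 64, replace = TRUE), 8, 8)
  d <- compute_persistence(f)
  oc <- oracle_betti_curve(f, c(-1, 0, 1))
  expect_equal(vapply(c(-1, 0, 1), alive_at, numeric(1), diag = d, dim = 0),
               oc$beta0)
  expect_equal(vapply(c(-1, 0, 1), alive_at, numeric(1), diag = d, dim = 1),
               oc$beta1)
})

test_that("quadrant split obeys the SEDT quadrant laws", {
  m <- disk_mask(rbind(c(20, 20), c(20, 60), c(60, 40)), c(4, 6, 5), side = 80L)
  diag <- split_quadrants(compute_persistence(signed_edt(m)))
  expect_false(any(diag$dim == 0 & diag$quadrant == 1L))
  expect_false(any(diag$dim == 1 & diag$quadrant == 3L))
  expect_false(any(diag$quadrant == 4L))
  expect_equal(sum(diag$essential), 1)
  expect_equal(diag$quadrant[diag$essential], 2L)
  # two separated disks: H0-Q2 = 1 finite + essential, H0-Q3 empty
  m2 <- disk_mask(rbind(c(25, 25), c(55, 55)), c(4, 4), side = 80L)
  d2 <- split_quadrants(compute_persistence(signed_edt(m2)))
  expect_equal(sum(d2$dim == 0 & d2$quadrant == 2L & !d2$essential), 1)
  expect_equal(sum(d2$dim == 0 & d2$quadrant == 3L), 0)
})

test_that("an irregular dumbbell hole produces a quadrant-3 merge point", {
  m <- matrix(TRUE, 40, 60)
  rows <- row(m); cols <- col(m)
  # two overlapping lobes joined by a thin neck: one hole, two SEDT minima
  m[(rows - 20)^2 + (cols - 20)^2 <= 36] <- FALSE
  m[(rows - 20)^2 + (cols - 40)^2 <= 36] <- FALSE
  m[19:21, 20:40] <- FALSE
  diag <- split_quadrants(compute_persistence(signed_edt(m)))
  expect_gte(sum(diag$dim == 0 & diag$quadrant == 3L), 1)
})

test_that("bone loops between close disks land in H1 quadrant 1", {
  m <- disk_mask(rbind(c(30, 30), c(30, 50), c(50, 30), c(50, 50)),
                 rep(6, 4), side = 80L)
  diag <- split_quadrants(compute_persistence(signed_edt(m)))
  expect_equal(sum(diag$dim == 1 & diag$quadrant == 1L), 1)
})

test_that("inscribed-radius and crowding laws hold on planted disks", {
  radii <- c(3, 5, 8, 12, 20)
  m <- disk_mask(rbind(c(50, 50), c(50, 230), c(150, 60), c(230, 230),
                       c(150, 160)), radii, side = 300L)
  diag <- split_quadrants(compute_persistence(signed_edt(m)))
  h0q2 <- diag[diag$dim == 0 & diag$quadrant == 2L, ]
  expect_equal(nrow(h0q2), 5)
  expect_true(all(abs(sort(-h0q2$birth) - sort(radii)) <= 1))
  for (g in c(10, 20, 40)) {
    m2 <- disk_mask(rbind(c(150, 80), c(150, 80 + 5 + 5 + g)), c(5, 5),
                    side = 300L)
    d2 <- split_quadrants(compute_persistence(signed_edt(m2)))
    fin <- d2[d2$dim == 0 & d2$quadrant == 2L & !d2$essential, ]
    expect_equal(nrow(fin), 1)
    expect_gte(fin$death, g / 2 - 1)
    expect_lte(fin$death, g / 2 + 1)
  }
})

test_that("flipping one far-from-feature pixel perturbs the diagram by at most one pixel unit", {
  m <- disk_mask(rbind(c(30, 30), c(70, 70)), c(5, 5), side = 100L)
  m[5, 95] <- FALSE   # speck far from both disks
  d0 <- compute_persistence(signed_edt(disk_mask(rbind(c(30, 30), c(70, 70)),
                                                 c(5, 5), side = 100L)))
  d1 <- compute_persistence(signed_edt(m))
  # original finite points must each have a match within 1.5 px sup-norm
  f0 <- d0[!d0$essential, ]
  f1 <- d1[!d1$essential, ]
  for (i in seq_len(nrow(f0))) {
    dist <- pmax(abs(f1$birth - f0$birth[i]), abs(f1$death - f0$death[i]))
    expect_lte(min(dist), 1.5)
  }
})

test_that("degenerate fields give an empty flagged diagram and filtration", {
  f <- signed_edt(matrix(TRUE, 5, 5))
  expect_true(attr(build_filtration(f), "degenerate"))
  d <- compute_persistence(f)
  expect_equal(nrow(d), 0)
  expect_true(attr(d, "degenerate"))
})

test_that("diagram CSV IO round-trips including the infinite death", {
  m <- disk_mask(rbind(c(10, 10), c(25, 25)), c(3, 3), side = 40L)
  d <- compute_persistence(signed_edt(m))
  path <- withr::local_tempfile(fileext = ".csv")
  write_diagram_csv(d, path)
  back <- read_diagram_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(d), ignore_attr = TRUE)
})
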