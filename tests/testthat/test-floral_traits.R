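test_that("Gower distance mixes range-normalized and categorical components", {
  rg <- c(height = 20, diameter = 10)
  a <- list(height = 10, diameter = 5, colour = "white")
  b <- list(height = 20, diameter = 5, colour = "white")
  expect_equal(gower_distance(a, b, rg), (0.5 + 0 + 0) / 3)
  expect_equal(gower_distance(a, a, rg), 0)
  b2 <- list(height = 30, diameter = 15, colour = "purple")
  expect_equal(gower_distance(a, b2, rg), 1)
  # zero-range and missing traits are excluded from the mean
  expect_equal(gower_distance(list(h = 1, k = 5), list(h = 3, k = 5),
                              c(h = 4, k = 0)), 0.5)
  expect_error(gower_distance(list(h = 1), list(h = 2), c(h = 0)),
               class = "invanet_no_usable_trait")
})

test_that("Gower matrix agrees with the cluster::daisy oracle on numeric tables", {
  skip_if_not_installed("cluster")
  set.seed(5)
  tab <- data.frame(species_id = paste0("sp", 1:7),
                    a = runif(7, 0, 10), b = rnorm(7), c = rexp(7))
  D <- gower_matrix(tab)
  D_oracle <- as.matrix(cluster::daisy(tab[-1], metric = "gower"))
  expect_equal(unname(D), unname(D_oracle), tolerance = 1e-9)
})

test_that("similarity index is 1 minus mean pairwise distance", {
  same <- data.frame(species_id = c("a", "b", "c"), t1 = 1, t2 = 2)
  expect_equal(unname(similarity_index(same, ranges = c(t1 = 1, t2 = 1))),
               rep(1, 3))
  # two species at full distance
  two <- data.frame(species_id = c("a", "b"), t1 = c(0, 1))
  expect_equal(unname(similarity_index(two)), c(0, 0))
  # collinear trio with pairwise distances {0.2, 0.4, 0.6}
  trio <- data.frame(species_id = c("a", "b", "c"), t1 = c(0, 0.2, 0.6))
  s <- similarity_index(trio, ranges = c(t1 = 1))
  expect_equal(sort(unname(s)), c(0.5, 0.6, 0.7))
  expect_error(similarity_index(two[1, , drop = FALSE]),
               class = "invanet_too_small")
  # averaging over traits (not summing): duplicating the whole trait schema
  # leaves every similarity unchanged
  set.seed(8)
  tab <- data.frame(species_id = paste0("s", 1:6), a = runif(6), b = runif(6))
  tab2 <- tab; tab2$a2 <- tab$a; tab2$b2 <- tab$b
  expect_equal(unname(similarity_index(tab)), unname(similarity_index(tab2)),
               tolerance = 1e-9)
})

test_that("group summaries handle missing groups and degenerate communities", {
  tab <- data.frame(species_id = paste0("s", 1:4), t1 = c(1, 2, 3, 4))
  res <- group_similarity_summary(tab, rep("native", 4))
  expect_true(is.na(res$alien_mean))
  expect_equal(res$alien_n, 0)
  same <- data.frame(species_id = paste0("s", 1:3), t1 = 1, t2 = 0)
  res2 <- group_similarity_summary(same, c("native", "native", "alien"),
                                   ranges = c(t1 = 1, t2 = 1))
  expect_equal(res2$mean, 1)
  expect_equal(res2$sd, 0)
})

test_that("with no alien trait shift, native and alien similarity means coincide", {
  cfg <- generator_config(seed = 21, delta = 0)
  gaps <- vapply(1:50, function(i) {
    g <- generate_site(cfg, i)
    r <- group_similarity_summary(g$traits, g$traits$origin)
    r$native_mean - r$alien_mean
  }, numeric(1))
  expect_lt(abs(mean(gaps, na.rm = TRUE)), 0.05)
})

test_that("hexagon coordinates behave like background-adapted excitations", {
  wl <- seq(300, 700, by = 10)
  n <- length(wl)
  sens <- cbind(uv = dnorm(wl, 350, 30), blue = dnorm(wl, 440, 30),
                green = dnorm(wl, 540, 40))
  illum <- rep(1, n)
  bg <- rep(0.1, n)
  # stimulus identical to the background sits at the achromatic centre
  expect_equal(unname(hexagon_coordinates(bg, sens, illum, bg, wl)),
               c(0, 0), tolerance = 1e-12)
  # exciting only the green channel pushes X positive
  green_stim <- bg + 0.5 * (wl > 500 & wl < 600)
  xy <- hexagon_coordinates(green_stim, sens, illum, bg, wl)
  expect_gt(xy["x"], 0)
  # doubling the illuminant leaves background-relative coordinates unchanged
  stim <- 0.1 + 0.4 * dnorm(wl, 450, 40) / max(dnorm(wl, 450, 40))
  expect_equal(hexagon_coordinates(stim, sens, illum, bg, wl),
               hexagon_coordinates(stim, sens, 2 * illum, bg, wl),
               tolerance = 1e-12)
  # coordinates stay inside the unit hexagon's bounding box
  for (s in 1:5) {
    set.seed(s)
    stim_r <- runif(n, 0, 1)
    xy_r <- hexagon_coordinates(stim_r, sens, illum, bg, wl)
    expect_lte(abs(xy_r["x"]), sqrt(3) / 2)
    expect_lte(abs(xy_r["y"]), 1)
  }
  expect_error(hexagon_coordinates(bg[-1], sens, illum, bg, wl),
               class = "invanet_grid_mismatch")
})
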