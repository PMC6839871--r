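test_that("generated sites respect configured ranges and are seed-reproducible", {
  cfg <- generator_config(seed = 1)
  s <- generate_site(cfg, 1)
  expect_s3_class(s$community, "site_community")
  expect_gte(nrow(s$community$plants), 8)
  expect_lte(nrow(s$community$plants), 17)
  expect_gte(nrow(s$community$visitors), 22)
  expect_lte(nrow(s$community$visitors), 38)
  expect_gte(sum(s$community$counts), 504)
  expect_lte(sum(s$community$counts), 3335)
  expect_length(validate_community(s$community), 0)

  s2 <- generate_site(cfg, 1)
  expect_identical(s$community$counts, s2$community$counts)
  expect_identical(s$traits, s2$traits)
})

test_that("studies span a strictly increasing alien-flower gradient", {
  cfg <- generator_config(seed = 2)
  study <- generate_study(cfg, 9)
  expect_length(study, 9)
  shares <- vapply(study, function(s) {
    fc <- s$community$plants$flower_count
    sum(fc[s$community$plants$origin == "alien"]) / sum(fc)
  }, numeric(1))
  expect_true(all(diff(shares) > 0))
  expect_equal(shares[1], 0.11, tolerance = 0.05)
  expect_equal(shares[9], 0.99, tolerance = 0.05)

  one <- generate_study(cfg, 1)
  fc <- one[[1]]$community$plants$flower_count
  expect_equal(sum(fc[one[[1]]$community$plants$origin == "alien"]) / sum(fc),
               mean(cfg$alien_flower_share), tolerance = 0.05)

  study2 <- generate_study(cfg, 9)
  expect_identical(lapply(study, function(s) s$community$counts),
                   lapply(study2, function(s) s$community$counts))
})

test_that("alien flower share and super-generalist share are recovered on average", {
  cfg <- generator_config(seed = 3)
  stats <- vapply(1:200, function(i) {
    g <- generate_site(cfg, i, alien_flower_target = 0.90)
    fc <- g$community$plants$flower_count
    c(share = sum(fc[g$community$plants$origin == "alien"]) / sum(fc),
      sg = sum(g$community$counts[, 1]) / sum(g$community$counts))
  }, numeric(2))
  expect_equal(mean(stats["share", ]), 0.90, tolerance = 0.02)
  expect_equal(mean(stats["sg", ]), 0.575, tolerance = 0.05)
})

test_that("the trait-matching decay tunes nestedness down from the abundance regime", {
  n0 <- vapply(1:50, function(i) {
    m <- generate_site(generator_config(seed = 5, gamma = 0), i)$community$counts
    nodf(drop_empty(m, warn = FALSE))
  }, numeric(1))
  n_hi <- vapply(1:50, function(i) {
    m <- generate_site(generator_config(seed = 5, gamma = 150), i)$community$counts
    nodf(drop_empty(m, warn = FALSE))
  }, numeric(1))
  expect_gt(mean(n0), mean(n_hi))
})

test_that("per-flower visitation rate declines with flower abundance", {
  study <- generate_study(generator_config(seed = 11), 9)
  dat <- do.call(rbind, lapply(study, function(s) {
    pe <- pollination_environment(s$community)$per_plant
    pe[pe$visits > 0 & !is.na(pe$rate) & pe$rate > 0,
       c("flower_count", "rate")]
  }))
  slope <- coef(lm(log(rate) ~ log(flower_count), dat))[2]
  expect_lt(slope, 0)
})

test_that("all study-level metrics compute on every default synthetic site", {
  study <- generate_study(generator_config(seed = 23), 9)
  for (s in study) {
    m <- drop_empty(s$community$counts, warn = FALSE)
    nm <- network_metrics(m, n_orders = 30,
                          sa = sa_config(moves_per_temp_factor = 10,
                                         patience = 5), seed = 1)
    expect_true(all(is.finite(c(nm$nodf, nm$h2prime, nm$modularity_q,
                                nm$robustness, nm$connectance))))
    expect_gte(nm$nodf, 0); expect_lte(nm$nodf, 100)
    expect_gte(nm$h2prime, 0); expect_lte(nm$h2prime, 1)
    expect_gte(nm$modularity_q, 0)
    expect_gte(nm$robustness, 0); expect_lte(nm$robustness, 1)
  }
})

test_that("zero-visit species stay in metadata but carry no interactions", {
  # force many zero-visit visitors with a tiny visit total
  cfg <- generator_config(seed = 6, total_visits = c(30L, 40L))
  s <- generate_site(cfg, 1)
  expect_gte(nrow(s$community$visitors), 22)      # metadata retained
  expect_true(any(colSums(s$community$counts) == 0))
  m <- suppressWarnings(drop_empty(s$community$counts))
  expect_true(all(colSums(m) > 0))
  # survey records agree with the count matrix cell for cell
  sv <- s$community$surveys
  agg <- tapply(sv$n_visits, list(sv$plant_id, sv$visitor_id), sum)
  for (k in which(s$community$counts > 0)) {
    idx <- arrayInd(k, dim(s$community$counts))
    expect_equal(agg[rownames(s$community$counts)[idx[1]],
                     colnames(s$community$counts)[idx[2]]],
                 s$community$counts[k])
  }
})
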