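test_that("a community written to the CSV contract round-trips bit-exactly", {
  comm <- make_invaded_community()
  d <- withr::local_tempdir()
  write_community(comm, d)
  back <- load_community(file.path(d, "interactions.csv"),
                         file.path(d, "species.csv"), site_id = comm$site_id)
  expect_identical(unname(back$counts), unname(comm$counts))
  expect_identical(back$plants$species_id, comm$plants$species_id)
  expect_identical(back$plants$origin, comm$plants$origin)
  expect_identical(back$visitors$species_id, comm$visitors$species_id)
  expect_equal(sum(back$counts), sum(comm$counts))
})

test_that("loader raises distinct named errors for malformed inputs", {
  d <- withr::local_tempdir()
  sp <- make_species_df(c("p1", "p2"), c("v1", "v2"))
  write.csv(sp, file.path(d, "species.csv"), row.names = FALSE)

  ok <- data.frame(plant_id = c("p1", "p2"), v1 = c(3L, 1L), v2 = c(1L, 1L))
  write.csv(ok, file.path(d, "interactions.csv"), row.names = FALSE)
  comm <- load_community(file.path(d, "interactions.csv"),
                         file.path(d, "species.csv"))
  expect_equal(sum(comm$counts), 6)

  bad_col <- ok; names(bad_col)[3] <- "ghost"
  write.csv(bad_col, file.path(d, "interactions.csv"), row.names = FALSE)
  expect_error(load_community(file.path(d, "interactions.csv"),
                              file.path(d, "species.csv")),
               class = "invanet_unknown_species")

  write.csv(ok[0, ], file.path(d, "interactions.csv"), row.names = FALSE)
  expect_error(load_community(file.path(d, "interactions.csv"),
                              file.path(d, "species.csv")),
               class = "invanet_dimension_mismatch")

  neg <- ok; neg$v1[1] <- -1L
  write.csv(neg, file.path(d, "interactions.csv"), row.names = FALSE)
  expect_error(load_community(file.path(d, "interactions.csv"),
                              file.path(d, "species.csv")),
               class = "invanet_negative_count")

  write.csv(ok, file.path(d, "interactions.csv"), row.names = FALSE)
  write.csv(rbind(sp, sp[1, ]), file.path(d, "species.csv"), row.names = FALSE)
  expect_error(load_community(file.path(d, "interactions.csv"),
                              file.path(d, "species.csv")),
               class = "invanet_duplicate_species")
})

test_that("validate_community reports (not raises) violations naming the culprit", {
  comm <- make_invaded_community()
  expect_length(validate_community(comm), 0)

  bad <- unclass(comm)
  bad$plants$origin[2] <- "not_applicable"
  v <- validate_community(bad)
  expect_length(v, 1)
  expect_match(as.character(v[[1]]), bad$plants$species_id[2], fixed = TRUE)

  bad2 <- unclass(comm)
  bad2$counts[1, 1] <- -1
  v2 <- validate_community(bad2)
  expect_length(v2, 1)
  expect_match(as.character(v2[[1]]), "pl01")
})

test_that("inflorescence flower estimates follow the product rule with half-up rounding", {
  expect_equal(estimate_inflorescence_flowers(12, 10), 120)
  expect_equal(estimate_inflorescence_flowers(0, 50), 0)
  expect_equal(estimate_inflorescence_flowers(2.5, 3), 8)
  expect_error(estimate_inflorescence_flowers(-1, 3),
               class = "invanet_negative_input")
})

test_that("pollination environment: richness counts partners, rates scale with flowers", {
  comm <- make_community(rbind(c(3, 0, 2), c(0, 0, 0)),
                         flower_counts = c(10, 20))
  pe <- pollination_environment(comm)$per_plant
  expect_equal(pe$richness, c(2L, 0L))
  expect_equal(pe$rate, c(0.5, 0))

  # equal visits, 10x flowers -> 10x lower rate
  comm2 <- make_community(rbind(c(4, 4), c(4, 4)), flower_counts = c(10, 100))
  pe2 <- pollination_environment(comm2)$per_plant
  expect_equal(pe2$rate[1] / pe2$rate[2], 10)

  # zero flower count reported missing, never infinite
  comm3 <- make_community(rbind(c(3, 1), c(1, 1)), flower_counts = c(0, 10))
  pe3 <- pollination_environment(comm3)$per_plant
  expect_true(is.na(pe3$rate[1]))
})

test_that("Bray-Curtis matrix matches the 2*min formula and its invariants", {
  expect_equal(bray_curtis_matrix(rbind(c(5, 2), c(5, 2)))[1, 2], 0)
  expect_equal(bray_curtis_matrix(rbind(c(3, 0), c(0, 4)))[1, 2], 1)
  expect_equal(bray_curtis_matrix(rbind(c(3, 1), c(1, 1)))[1, 2], 1 - 4 / 6,
               tolerance = 1e-12)
  expect_error(bray_curtis_matrix(rbind(c(0, 0), c(1, 2))),
               class = "invanet_all_zero_vector")

  set.seed(42)
  for (k in 1:5) {
    m <- matrix(rpois(24, 3), 4, 6) + 1
    D <- bray_curtis_matrix(m)
    expect_equal(D, t(D))
    expect_equal(diag(D), rep(0, 4), ignore_attr = TRUE)
    expect_true(all(D >= 0 & D <= 1))
  }
})
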