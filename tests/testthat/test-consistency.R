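test_that("template draws are uniform without replacement", {
  pool <- sprintf("S%d", 1:5)
  full <- draw_template_subjects(pool, 5)
  expect_setequal(full, pool)

  set.seed(4); d1 <- draw_template_subjects(pool, 3)
  set.seed(4); d2 <- draw_template_subjects(pool, 3)
  expect_identical(d1, d2)

  expect_error(draw_template_subjects(pool, 6),
               class = "atrophynorm_error_pool_too_small")

  # Monte-Carlo uniformity: all 10 unordered pairs at frequency 0.1 +/- 0.01
  set.seed(12)
  draws <- replicate(10000, paste(sort(draw_template_subjects(pool, 2)),
                                  collapse = "+"))
  freq <- table(draws) / 10000
  expect_length(freq, 10)
  expect_true(all(abs(freq - 0.1) <= 0.01))
})

test_that("across-repeat SD is a per-voxel sample SD on the validity intersection", {
  vols <- random_volumes(5, seed = 31)
  tpl <- build_template(vols)
  pat <- random_volumes(1, seed = 32)[[1]]
  zm <- compute_zmap(pat, tpl)

  same <- sd_across_repeats(list(zm, zm, zm))
  expect_true(all(same$sd == 0))
  expect_identical(same$valid, zm$valid)

  z1 <- zm; z1$z <- array(1, dim(zm$z)); z1$valid <- array(TRUE, dim(zm$z))
  z3 <- z1; z3$z <- array(3, dim(zm$z))
  two <- sd_across_repeats(list(z1, z3))
  expect_equal(unique(as.vector(two$sd)), sqrt(2))

  # random stack versus an explicit per-voxel loop oracle
  set.seed(33)
  zs <- lapply(1:6, function(i) {
    z <- z1; z$z <- array(rnorm(64), c(4, 4, 4))
    z$valid <- array(runif(64) > 0.2, c(4, 4, 4)); z
  })
  got <- sd_across_repeats(zs)
  stack <- simplify2array(lapply(zs, function(z) z$z))
  vstack <- simplify2array(lapply(zs, function(z) z$valid))
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    if (all(vstack[i, j, k, ])) {
      expect_equal(got$sd[i, j, k], sd(stack[i, j, k, ]), tolerance = 1e-12)
      expect_true(got$valid[i, j, k])
    } else {
      expect_false(got$valid[i, j, k])
    }
  }
  expect_error(sd_across_repeats(zs[1]), class = "atrophynorm_error_too_few")
})

test_that("the spatial mean is an arithmetic mean over mask voxels", {
  f <- array(7, c(3, 3, 3))
  m <- array(TRUE, c(3, 3, 3))
  expect_equal(spatial_mean(f, m), 7)

  f2 <- array(0, c(2, 2, 2)); f2[1, 1, 1] <- 0; f2[2, 2, 2] <- 2
  m2 <- array(FALSE, c(2, 2, 2)); m2[1, 1, 1] <- m2[2, 2, 2] <- TRUE
  expect_equal(spatial_mean(f2, m2), 1)

  set.seed(5)
  fr <- array(rnorm(27), c(3, 3, 3)); mr <- array(runif(27) > 0.5, c(3, 3, 3))
  expect_equal(spatial_mean(fr, mr), sum(fr[mr]) / sum(mr))
  expect_error(spatial_mean(fr, array(FALSE, c(3, 3, 3))),
               class = "atrophynorm_error_empty_mask")
})

test_that("consistency at one size composes draw/template/z-map and is seeded", {
  spec <- synthetic_cohort_spec(shape = c(6, 6, 6), n_subjects = 8,
                                age_range = c(69, 71), sex_ratio = 1, seed = 41)
  co <- generate_cohort(spec)
  pat <- generate_subject(spec, 70, "female", "P")
  pool <- co$volumes
  mask <- default_brain_ellipsoid(spec$shape)

  v1 <- consistency_at_n(pat, pool, n = 4, repeats = 5, mask = mask, seed = 9)
  v2 <- consistency_at_n(pat, pool, n = 4, repeats = 5, mask = mask, seed = 9)
  expect_identical(v1, v2)

  # two-repeat composition oracle built from the public pieces
  set.seed(17)
  got <- consistency_at_n(pat, pool, n = 3, repeats = 2, mask = mask)
  set.seed(17)
  zmaps <- lapply(1:2, function(r)
    compute_zmap(pat, build_template(draw_template_subjects(pool, 3))))
  sdr <- sd_across_repeats(zmaps)
  want <- spatial_mean(sdr$sd, sdr$valid & mask$include)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("drawing the whole pool every repeat yields exactly zero", {
  spec <- synthetic_cohort_spec(shape = c(6, 6, 6), n_subjects = 6,
                                age_range = c(69, 71), sex_ratio = 1, seed = 43)
  co <- generate_cohort(spec)
  pat <- generate_subject(spec, 70, "female", "P")
  v <- consistency_at_n(pat, co$volumes, n = 6, repeats = 10, seed = 1)
  expect_identical(v, 0)
})

test_that("consistency curves are reproducible, eligible-pool-guarded and serializable", {
  spec <- synthetic_cohort_spec(shape = c(6, 6, 6), n_subjects = 30,
                                age_range = c(69, 71), sex_ratio = 1, seed = 45)
  co <- generate_cohort(spec)
  pat <- patient_case(generate_subject(spec, 70, "female", "P"), 70, "female")
  cfg <- experiment_config(n_min = 3, n_max = 8, repeats = 5, min_pool = 20,
                           seed = 6)
  c1 <- consistency_curve(pat, co, cfg)
  c2 <- consistency_curve(pat, co, cfg)
  expect_identical(c1, c2)
  expect_equal(c1$n, 3:8)
  expect_true(all(c1$value >= 0))

  # byte-identical CSV serialization across runs
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_curve(c1, p1); write_curve(c2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(read_curve(p1)$value, c1$value)

  strict <- experiment_config(n_min = 3, n_max = 8, repeats = 5, min_pool = 100)
  expect_error(consistency_curve(pat, co, strict),
               class = "atrophynorm_error_ineligible")
  err <- tryCatch(consistency_curve(pat, co, strict), error = identity)
  expect_match(conditionMessage(err), "shortfall")
})

test_that("a single-point curve at the full pool size is exactly zero", {
  spec <- synthetic_cohort_spec(shape = c(6, 6, 6), n_subjects = 10,
                                age_range = c(69, 71), sex_ratio = 1, seed = 47)
  co <- generate_cohort(spec)
  pat <- patient_case(generate_subject(spec, 70, "female", "P"), 70, "female")
  npool <- nrow(match_subjects(co$table, 70, "female"))
  cfg <- experiment_config(n_min = npool, n_max = npool, repeats = 5,
                           min_pool = npool, seed = 2)
  cv <- consistency_curve(pat, co, cfg)
  expect_length(cv$value, 1)
  expect_identical(cv$value, 0)
})

test_that("experiment config validates its bounds", {
  expect_error(experiment_config(n_min = 1), class = "atrophynorm_error_config")
  expect_error(experiment_config(repeats = 1), class = "atrophynorm_error_config")
  expect_error(experiment_config(n_max = 50, min_pool = 40),
               class = "atrophynorm_error_config")
})
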