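test_that("default box-size ladder follows the powers-of-two rule", {
  expect_equal(default_box_sizes(c(64, 64, 64)), c(1L, 2L, 4L, 8L, 16L))
  expect_equal(default_box_sizes(c(32, 32, 32)), c(1L, 2L, 4L, 8L))
  expect_equal(default_box_sizes(c(64, 32, 64)), c(1L, 2L, 4L, 8L))
  expect_error(default_box_sizes(c(8, 8, 8)), ">= 4")
  expect_error(default_box_sizes(c(4, 64, 64)), "too small")
})

test_that("box counts on exact tilings and singletons", {
  cube <- array(1L, c(8, 8, 8))
  p <- box_counts(cube, c(1, 2, 4))
  expect_equal(p$counts, c(512L, 64L, 8L))
  expect_equal(p$mass_mean, c(1, 8, 64))
  expect_equal(p$mass_var, c(0, 0, 0))

  single <- array(0L, c(16, 16, 16)); single[5, 7, 3] <- 1L
  ps <- box_counts(single, c(1, 2, 4, 8))
  expect_equal(ps$counts, rep(1L, 4))
  expect_equal(ps$mass_mean, rep(1, 4))
  expect_equal(ps$mass_var, rep(0, 4))

  expect_error(box_counts(array(0L, c(8, 8, 8)), c(1, 2)), "empty mask")
})

test_that("box counting matches the explicit-loop oracle exactly", {
  m <- random_mask(c(16, 16, 16), 0.3, seed = 101)
  sizes <- c(1, 2, 4)
  p <- box_counts(m, sizes)
  orc <- oracle_box_counts(m, sizes)
  for (s in seq_along(sizes)) {
    expect_identical(p$counts[s], length(orc[[s]]))
    expect_equal(p$mass_mean[s], mean(orc[[s]]))
    expect_equal(p$mass_var[s], mean((orc[[s]] - mean(orc[[s]]))^2))
  }
  # lacunarity and multifractal range from the oracle's mass lists
  lam_oracle <- mean(vapply(orc, function(ms)
    mean((ms - mean(ms))^2) / mean(ms)^2, numeric(1)))
  expect_equal(lacunarity(p), lam_oracle, tolerance = 1e-12)
})

test_that("profile invariants hold on random masks", {
  for (seed in 1:5) {
    dims <- c(24, 20, 28)
    m <- random_mask(dims, runif(1, 0.05, 0.6), seed = seed)
    if (sum(m) == 0) next
    sizes <- c(1, 2, 4, 8)
    p <- box_counts(m, sizes)
    expect_true(all(diff(p$counts) <= 0))             # non-increasing in eps
    expect_true(all(p$counts >= p$total_fg / sizes^3))
    expect_true(all(p$counts <= prod(ceiling(dims / 1)) / 1)) # trivial cap
    for (s in seq_along(sizes))
      expect_true(p$counts[s] <= prod(ceiling(dims / sizes[s])))
    expect_equal(p$counts * p$mass_mean, rep(p$total_fg, length(sizes)))
    expect_true(all(p$mass_var >= 0))
  }
})

test_that("counts and indices are invariant to grid-aligned translation", {
  blob <- random_mask(c(8, 8, 8), 0.4, seed = 7)
  a <- array(0L, c(32, 32, 32)); a[1:8, 1:8, 1:8] <- blob
  b <- array(0L, c(32, 32, 32)); b[9:16, 17:24, 25:32] <- blob  # shifts 8/16/24
  sizes <- c(1, 2, 4, 8)
  pa <- box_counts(a, sizes); pb <- box_counts(b, sizes)
  expect_identical(pa$counts, pb$counts)
  expect_equal(pa$mass_mean, pb$mass_mean)
  expect_equal(pa$mass_var, pb$mass_var)
  expect_equal(lacunarity(pa), lacunarity(pb))
  expect_equal(multifractal_range(pa), multifractal_range(pb))
})

test_that("fractal dimension recovers exact power laws", {
  cube <- box_counts(array(1L, c(8, 8, 8)), c(1, 2, 4))
  expect_equal(fractal_dimension(cube)$fd, 3, tolerance = 1e-12)

  single <- array(0L, c(16, 16, 16)); single[1, 1, 1] <- 1L
  fd0 <- fractal_dimension(box_counts(single, c(1, 2, 4, 8)))
  expect_identical(fd0$fd, 0)
  expect_true(is.na(fd0$r_squared))

  sponge <- box_counts(menger_sponge(3), c(1, 3, 9, 27))
  fit <- fractal_dimension(sponge)
  expect_equal(fit$fd, log(20) / log(3), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("lacunarity follows the variance-over-squared-mean definition", {
  # homogeneous tiling: every occupied box has identical mass
  cube <- box_counts(array(1L, c(16, 16, 16)), c(1, 2, 4, 8))
  expect_equal(lacunarity(cube), 0)

  # one scale, two occupied boxes with masses 1 and 3: var 1, mean 2
  m <- array(0L, c(4, 2, 2))
  m[1, 1, 1] <- 1L                      # box 1: mass 1
  m[3, 1, 1] <- 1L; m[4, 1, 1] <- 1L; m[3, 2, 1] <- 1L  # box 2: mass 3
  p <- box_counts(m, 2)
  expect_equal(p$counts, 2L)
  expect_equal(lacunarity(p), 0.25)
})

test_that("multifractal range separates the two half-fits", {
  # Menger sponge at aligned scales is exactly linear in log-log
  expect_equal(multifractal_range(box_counts(menger_sponge(3), c(1, 3, 9, 27))),
               0, tolerance = 1e-9)

  # constructed profile: slope 3 on the lower half, slope 2 on the upper
  prof <- structure(list(box_sizes = c(1L, 2L, 4L, 8L),
                         counts = c(512L, 64L, 32L, 8L),
                         mass_mean = c(1, 8, 16, 64),
                         mass_var = rep(0, 4), total_fg = 512L),
                    class = "box_count_profile")
  expect_equal(multifractal_range(prof), 1.0, tolerance = 1e-12)

  # random mask: match an independent two-regression recomputation
  m <- random_mask(c(32, 32, 32), 0.2, seed = 55)
  p <- box_counts(m, c(1, 2, 4, 8))
  expect_equal(multifractal_range(p),
               oracle_multifractal_range(p$box_sizes, p$counts),
               tolerance = 1e-12)
  expect_error(multifractal_range(box_counts(m, c(1, 2, 4))), ">= 4 scales")
})

test_that("composed tissue indices behave on analytic solids", {
  solid <- tissue_fractal_indices(array(1L, c(32, 32, 32)))
  expect_equal(solid$fd, 3, tolerance = 1e-12)
  expect_equal(solid$lacunarity, 0)
  expect_equal(solid$multifractal_range, 0, tolerance = 1e-12)

  sponge <- tissue_fractal_indices(menger_sponge(3), box_sizes = c(1, 3, 9, 27))
  expect_equal(sponge$fd, log(20) / log(3), tolerance = 1e-9)
  expect_equal(sponge$lacunarity, 0)  # self-similar: constant mass per scale
  expect_equal(sponge$n_scales, 4L)
})

test_that("fitted FD stays in [0, 3] on generated fixtures", {
  for (seed in 1:10) {
    m <- random_mask(c(32, 32, 32), runif(1, 0.02, 0.9), seed = 200 + seed)
    if (sum(m) == 0) next
    fi <- tissue_fractal_indices(m)
    expect_gte(fi$fd, 0)
    expect_lte(fi$fd, 3)
    expect_gte(fi$multifractal_range, 0)
    expect_gte(fi$lacunarity, 0)
  }
})

test_that("estimated FD grows with Cantor retention probability", {
  set.seed(1)
  mean_fd <- vapply(c(0.45, 0.65, 0.85, 1.0), function(p) {
    mean(vapply(1:20, function(s) {
      m <- random_cantor_3d(p, 3, seed = 1000 * p + s)
      if (sum(m) == 0) return(NA_real_)
      fractal_dimension(box_counts(m, c(1, 3, 9, 27)))$fd
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_fd) > 0))
})

test_that("bilateral averaging and missing-tissue flagging", {
  phL <- leg_phantom(hu_noise_sd = 0, seed = 11)
  legs <- split_legs(phL$masks)
  # identical legs: averaged equals single-leg
  f1 <- tissue_fractal_indices(legs$left$sm)
  same <- subject_fractal_features(legs$left, legs$left)
  expect_equal(same$sm_fd, f1$fd)
  expect_equal(same$sm_lacunarity, f1$lacunarity)

  # left/right arithmetic mean
  both <- subject_fractal_features(legs$left, legs$right)
  fr <- tissue_fractal_indices(legs$right$sm)
  expect_equal(both$sm_fd, (f1$fd + fr$fd) / 2)

  # tissue empty in one leg -> NA for that tissue only
  noimat <- tissue_mask_set(legs$left$sm, legs$left$sat,
                            array(0L, dim(legs$left$sm)),
                            spacing = legs$left$spacing)
  part <- subject_fractal_features(noimat, legs$right)
  expect_true(is.na(part$imat_fd))
  expect_false(is.na(part$sm_fd))
  expect_false(is.na(part$sat_fd))
})
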