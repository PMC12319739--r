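test_that("identity, pure shift, and pure affine compression decompose exactly", {
  tt <- c(1.0, 2.3, 4.1, 7.0, 10.5)
  d <- decompose_pattern(tt, tt)
  expect_equal(d$translation, 0)
  expect_equal(d$scaling, 1)
  expect_equal(d$pattern_score, 0)
  expect_equal(d$scaling_compr, 0)
  expect_equal(d$scaling_exp, 0)

  d2 <- decompose_pattern(tt, tt + 1.2)
  expect_equal(abs(d2$translation), 1.2)
  expect_equal(d2$scaling, 1)
  expect_equal(d2$pattern_score, 0)

  d3 <- decompose_pattern(tt, mean(tt) + 0.5 * (tt - mean(tt)))
  expect_equal(d3$scaling, 0.5)
  expect_equal(d3$scaling_compr, 0.5)
  expect_equal(d3$pattern_score, 0)
})

test_that("scale law holds across compression and expansion factors", {
  tt <- c(0.8, 2.0, 3.1, 6.4, 9.9)
  for (b in c(0.25, 0.5, 0.8, 1, 1.6, 2.5, 4)) {
    rec <- mean(tt) + b * (tt - mean(tt)) + 0.7
    d <- decompose_pattern(tt, rec)
    expect_equal(d$scaling, b, tolerance = 1e-10)
    expect_equal(d$translation, 0.7, tolerance = 1e-10)
    expect_equal(d$pattern_score, 0, tolerance = 1e-8)
  }
})

test_that("decomposition is shift-equivariant", {
  set.seed(31)
  tt <- random_pattern()
  rec <- tt + rnorm(5, 0, 0.5)
  d0 <- decompose_pattern(tt, rec)
  for (shift in c(-20, 3.7, 111)) {
    d <- decompose_pattern(tt + shift, rec + shift)
    expect_equal(d$translation, d0$translation, tolerance = 1e-9)
    expect_equal(d$scaling, d0$scaling, tolerance = 1e-9)
    expect_equal(d$pattern_score, d0$pattern_score, tolerance = 1e-9)
  }
})

test_that("decomposition matches the grid-search alignment oracle", {
  set.seed(99)
  for (i in 1:50) {
    tt <- random_pattern()
    rec <- mean(tt) + runif(1, 0.5, 2) * (tt - mean(tt)) + rnorm(5, 0, 0.6)
    d <- decompose_pattern(tt, rec)
    o <- grid_fit_oracle(tt, rec)
    expect_equal(1 / d$scaling, o$slope, tolerance = 1e-3)
    achieved <- sqrt(mean((d$aligned - tt)^2))
    expect_lte(achieved, o$rmsd + 1e-6)
  }
  # the worked 5-point case
  tt <- c(1.0, 2.0, 4.0, 7.0, 11.0)
  rec <- c(1.1, 2.3, 3.6, 7.4, 10.6)
  d <- decompose_pattern(tt, rec)
  o <- grid_fit_oracle(tt, rec)
  expect_equal(1 / d$scaling, o$slope, tolerance = 1e-3)
  expect_equal(d$translation, mean(rec) - mean(tt))
})

test_that("nearest-position residual never exceeds identity-matching residual", {
  set.seed(17)
  for (i in 1:200) {
    tt <- random_pattern()
    rec <- tt + rnorm(5, 0, runif(1, 0.1, 3))
    d <- decompose_pattern(tt, rec)
    identity_sse <- sum((d$aligned - tt)^2)
    expect_lte(-d$pattern_score, identity_sse + 1e-9)
  }
})

test_that("added noise weakly decreases the expected pattern score", {
  set.seed(23)
  tt <- random_pattern()
  mean_scores <- vapply(c(0, 0.3, 0.8), function(sd) {
    mean(replicate(300, decompose_pattern(tt, tt + rnorm(5, 0, sd))$pattern_score))
  }, numeric(1))
  expect_true(all(diff(mean_scores) < 0))
})

test_that("degenerate recalled patterns are flagged with NA scaling", {
  tt <- c(1, 3, 5, 8, 10)
  d <- decompose_pattern(tt, rep(4, 5))
  expect_true(d$degenerate)
  expect_true(is.na(d$scaling))
  expect_true(d$pattern_score <= 0)
  # fully reversed pattern gives a non-positive fitted slope
  d2 <- decompose_pattern(tt, rev(tt))
  expect_true(d2$degenerate)
  expect_error(decompose_pattern(tt, tt[1:4]), "equal length")
  expect_error(decompose_pattern(1, 1), "two items")
})

test_that("item measures recover identity and local gap ratios", {
  tt <- c(1, 3, 5, 8, 10)
  im <- item_measures(tt, tt)
  expect_equal(im$item_translation, rep(0, 5))
  expect_equal(im$item_scaling, rep(1, 5))

  # halve the smallest adjacent gap around item 5 (gap 8->10 becomes 1)
  rec <- c(1, 3, 5, 8, 9)
  im2 <- item_measures(tt, rec)
  expect_equal(im2$item_scaling[5], 0.5)
  expect_equal(im2$item_scaling_compr[5], 0.5)
  expect_error(item_measures(1, 1), "two items")
})

test_that("item measures agree with a hand enumeration on a 5-item case", {
  tt <- c(1.0, 2.0, 4.5, 7.0, 11.0)
  rec <- c(1.5, 2.2, 4.0, 8.0, 10.0)
  im <- item_measures(tt, rec)
  # true adjacent gaps: 1, 2.5, 2.5, 4 -> min gaps per item 1,1,2.5,2.5,4
  # recalled order is unchanged; gaps: 0.7, 1.8, 4, 2 -> mins 0.7,0.7,1.8,2,2
  expect_equal(im$item_translation, abs(rec - tt))
  expect_equal(im$item_scaling, c(0.7 / 1, 0.7 / 1, 1.8 / 2.5, 2 / 2.5, 2 / 4))
})

test_that("order scores count rank deviations", {
  expect_equal(order_score(1:5, c(1.1, 2.2, 3.0, 4.4, 5.5))$deviations, rep(0L, 5))
  # an episode presented third but placed first deviates by 2
  placed <- c(2, 3, 0.5, 4, 5)
  expect_equal(order_score(1:5, placed)$deviations[3], 2L)
  expect_equal(order_score(1:5, 5:1)$mean_deviation, 2.4)
  expect_error(order_score(1:3, 3:1, ids = c(1, 1, 2)), "duplicate")
})

test_that("windowed between-episode measures slice consistently", {
  set.seed(5)
  pos <- sort(runif(16, 0, 1500))
  w_id <- windowed_between_measures(pos, pos, "fours")
  expect_equal(nrow(w_id), 4L)
  expect_equal(w_id$translation, rep(0, 4))
  expect_equal(w_id$scaling, rep(1, 4))
  expect_equal(w_id$pattern_score, rep(0, 4))

  rec <- pos + rnorm(16, 0, 30)
  rec <- sort(rec)
  w_exp <- windowed_between_measures(pos, rec, "expanding")
  expect_equal(nrow(w_exp), 12L)
  expect_equal(w_exp$first, rep(1L, 12))
  expect_equal(w_exp$last, 5:16)
  manual <- decompose_pattern(pos[1:7], rec[1:7])
  expect_equal(w_exp$pattern_score[w_exp$last == 7], manual$pattern_score)
  expect_equal(w_exp$scaling[w_exp$last == 7], manual$scaling)

  w5 <- windowed_between_measures(pos, rec, "fives")
  expect_equal(nrow(w5), 3L)
  expect_error(windowed_between_measures(pos[1:8], rec[1:8], list(1:9)), "window index")
})
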