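test_that("rotation matches the hand index-map oracle and forms a group", {
  # single filled corner: top-left -> top-right under 90 degrees clockwise
  p <- pattern3x3(c(1,0,0, 0,0,0, 0,0,0))
  expect_true(unclass(rotate_pattern(p, 90))[1, 3])
  expect_equal(sum(rotate_pattern(p, 90)), 1)

  # exhaustive over all 512 grids: r^4 = identity, oracle agreement,
  # cell count preserved
  for (code in seq(0, 511, by = 7)) {
    p <- cogbattery:::pattern_from_code(code)
    m <- unclass(p)
    expect_identical(unclass(rotate_pattern(p, 90)) * 1L,
                     oracle_rotate_cw(m) * 1L)
    r4 <- rotate_pattern(rotate_pattern(rotate_pattern(
      rotate_pattern(p, 90), 90), 90), 90)
    expect_identical(unclass(r4) * 1L, m * 1L)
    expect_identical(unclass(rotate_pattern(p, 0)) * 1L, m * 1L)
    expect_equal(sum(rotate_pattern(p, 180)), sum(p))
  }
  expect_error(rotate_pattern(p, 45), "90")
})

test_that("reflection is an involution and maps cells as expected", {
  p <- pattern3x3(c(1,0,0, 0,1,0, 0,0,0))
  expect_true(unclass(reflect_pattern(p, "vertical"))[1, 3])
  for (axis in c("vertical", "horizontal")) {
    for (code in c(3L, 57L, 170L, 341L, 509L)) {
      q <- cogbattery:::pattern_from_code(code)
      twice <- reflect_pattern(reflect_pattern(q, axis), axis)
      expect_identical(unclass(twice) * 1L, unclass(q) * 1L)
      expect_equal(sum(reflect_pattern(q, axis)), sum(q))
    }
  }
  sym <- pattern3x3(c(0,1,0, 0,1,0, 0,0,0))  # symmetric about vertical axis
  expect_identical(unclass(reflect_pattern(sym, "vertical")) * 1L,
                   unclass(sym) * 1L)
  expect_error(reflect_pattern(p, "diagonal"))
})

test_that("group counting agrees with hand-worked configurations", {
  expect_equal(pattern_groups(pattern3x3(c(1,1,0, 0,0,0, 0,0,0))), 1)
  expect_equal(pattern_groups(pattern3x3(c(1,0,1, 0,0,0, 1,0,1))), 4)
  expect_equal(pattern_groups(pattern3x3(c(1,0,0, 0,1,0, 0,0,1))), 3)
  expect_equal(pattern_groups(pattern3x3(c(1,1,1, 0,1,0, 1,1,1))), 1)
  expect_equal(pattern_groups(pattern3x3(rep(0, 9))), 0)
})

test_that("the packaged stimulus set has 18 valid, rotation-distinct patterns", {
  set <- load_pattern_set()
  expect_length(set, 18)
  for (p in set) {
    expect_true(pattern_is_valid(p))
    expect_gte(sum(p), 2)
    expect_lte(sum(p), 6)
    expect_true(pattern_groups(p) %in% 1:3)
    for (d in c(90, 180, 270))
      expect_false(cogbattery:::pattern_equal(rotate_pattern(p, d), p))
  }
  for (i in 1:17) for (j in (i + 1):18) for (d in c(0, 90, 180, 270))
    expect_false(cogbattery:::pattern_equal(
      rotate_pattern(set[[i]], d), set[[j]]))
  # fixture matches the deterministic derivation exactly, in order
  derived <- derive_pattern_set()
  for (i in 1:18)
    expect_identical(unclass(set[[i]]) * 1L, unclass(derived[[i]]) * 1L)
})

test_that("foils never coincide with the rotated target (full brute force)", {
  set <- load_pattern_set()
  for (p in set) {
    foils <- list(reflect_pattern(p, "vertical"),
                  reflect_pattern(p, "horizontal"))
    for (d in c(90, 180, 270)) {
      correct <- rotate_pattern(p, d)
      for (f in foils)
        expect_false(cogbattery:::pattern_equal(f, correct))
    }
  }
})

test_that("rotation trials satisfy their invariants and are seed-reproducible", {
  set <- load_pattern_set()
  set.seed(99)
  for (rep in 1:50) {
    p <- set[[sample.int(18, 1)]]
    tr <- make_spin_trial(p)
    expect_true(tr$rotation_deg %in% c(90, 180, 270))
    expect_identical(
      unclass(tr$options[[tr$correct_index]]) * 1L,
      unclass(rotate_pattern(p, tr$rotation_deg)) * 1L)
    others <- tr$options[-tr$correct_index]
    refl <- list(reflect_pattern(p, "vertical"),
                 reflect_pattern(p, "horizontal"))
    for (o in others) {
      expect_true(any(vapply(refl, cogbattery:::pattern_equal,
                             logical(1), b = o)))
      expect_false(cogbattery:::pattern_equal(o, tr$options[[tr$correct_index]]))
    }
  }
  set.seed(5); t1 <- make_spin_trial(set[[3]])
  set.seed(5); t2 <- make_spin_trial(set[[3]])
  expect_identical(t1, t2)
})

test_that("the correct option position is uniform over the three slots", {
  set <- load_pattern_set()
  set.seed(123)
  idx <- replicate(6000, make_spin_trial(set[[1]])$correct_index)
  chi <- suppressWarnings(chisq.test(table(factor(idx, levels = 1:3))))
  expect_gt(chi$p.value, 0.001)
})
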