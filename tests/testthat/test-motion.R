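lt <- 200 # nm, convenient target for profile checks

test_that("Standard (linear converging) profile immobilises agents at or above target", {
  pr <- displacement_profile("linear_converging", d_max = 3.5, l_target = lt)
  expect_equal(displacement_rate(pr, lt), 0)
  expect_equal(displacement_rate(pr, lt + 150), 0)
  expect_equal(displacement_rate(pr, 0), 3.5)       # anchor
  expect_equal(displacement_rate(pr, lt / 2), 1.75) # halfway down the ramp
})

test_that("floored profile keeps the minimum rate at and beyond the target", {
  pr <- displacement_profile("linear_floor", d_max = 3.5, d_min = 0.52,
                             l_target = lt)
  expect_equal(displacement_rate(pr, lt), 0.52)
  expect_equal(displacement_rate(pr, 10 * lt), 0.52)
  expect_equal(displacement_rate(pr, 0), 3.5)
  # the floor takes over exactly where the ramp would drop below it
  l_cross <- lt * (1 - 0.52 / 3.5)
  expect_equal(displacement_rate(pr, l_cross), 0.52)
  expect_gt(displacement_rate(pr, l_cross - 1), 0.52)
})

test_that("tent profile is zero only at exact equality and rises on both sides", {
  pr <- displacement_profile("tent_nonconverging", d_max = 3.5, l_target = lt)
  expect_equal(displacement_rate(pr, lt), 0)
  expect_gt(displacement_rate(pr, lt + 1e-6), 0)
  expect_gt(displacement_rate(pr, lt - 1e-6), 0)
  expect_equal(displacement_rate(pr, 2 * lt), 3.5)  # clamped beyond the mirror
  # non-decreasing beyond the target
  l <- seq(lt, 3 * lt, length.out = 50)
  expect_true(all(diff(displacement_rate(pr, l)) >= 0))
})

test_that("quadratic profile squares the linear ramp", {
  pr <- displacement_profile("quadratic", d_max = 3.5, l_target = lt)
  expect_equal(displacement_rate(pr, lt / 2), 3.5 / 4)
  expect_equal(displacement_rate(pr, 0), 3.5)
  expect_equal(displacement_rate(pr, lt), 0)
})

test_that("all profile families decrease monotonically from anchor to target", {
  l <- seq(0, lt, length.out = 100)
  for (fam in c("linear_converging", "linear_floor", "tent_nonconverging",
                "quadratic")) {
    pr <- displacement_profile(fam, d_max = 3.5, d_min = 0.3, l_target = lt)
    r <- displacement_rate(pr, l)
    expect_true(all(diff(r) <= 1e-12), info = fam)
    expect_true(all(r >= 0 & r <= 3.5), info = fam)
  }
  expect_error(displacement_profile("linear_converging", d_max = 3.5,
                                    l_target = 50, l_anchor = 80), "exceed")
  expect_error(displacement_profile("linear_floor", d_max = 1, d_min = 2,
                                    l_target = lt))
})

test_that("fixed-mode steps have exact length rate*dt; zero rate leaves position unchanged", {
  set.seed(11)
  p <- matrix(runif(400) * 1000, ncol = 2)
  out <- propose_step(p, rate = 3.5, dt = 10, mode = "fixed")
  expect_equal(sqrt(rowSums((out - p)^2)), rep(35, 200), tolerance = 1e-12)
  expect_equal(propose_step(p, rate = 0, dt = 10, mode = "fixed"), p)
})

test_that("gaussian-mode RMS step length matches the fixed-mode step", {
  set.seed(12)
  p <- matrix(0, nrow = 1e5, ncol = 2)
  out <- propose_step(p, rate = 3.5, dt = 10, mode = "gaussian")
  rms <- sqrt(mean(rowSums(out^2)))
  expect_equal(rms, 35, tolerance = 0.01)
})

test_that("mesh reflection mirrors about crossed lines", {
  m <- actin_mesh(500)
  # no crossing: unchanged
  expect_equal(reflect_off_mesh(c(100, 100), c(140, 120), m), c(140, 120))
  # single vertical line at x = 500
  expect_equal(reflect_off_mesh(c(490, 100), c(510, 100), m), c(490, 100))
  # corner: two sequential mirrors about x = 500 and y = 500
  expect_equal(reflect_off_mesh(c(495, 495), c(510, 510), m), c(490, 490))
  expect_error(reflect_off_mesh(c(10, 10), c(600, 10), m), "smaller than the mesh")
})

test_that("reflected steps never change mesh cell", {
  set.seed(13)
  m <- actin_mesh(250)
  n <- 1e6
  old <- cbind(runif(n) * 3000, runif(n) * 3000)
  theta <- runif(n) * 2 * pi
  len <- runif(n) * 249
  prop <- old + cbind(len * cos(theta), len * sin(theta))
  refl <- reflect_off_mesh(old, prop, m)
  expect_true(all(floor(refl / 250) == floor(old / 250)))
})
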