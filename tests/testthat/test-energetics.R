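test_that("zero distance costs nothing and cost is linear in distance", {
  fox <- animal_profile(4.5, "mammal")
  out0 <- energy_cost(fox, 0)
  expect_identical(out0$energy_cost, 0)
  expect_identical(out0$energy_remaining, energy_storage(fox))
  for (a in profiles_at(2)) {
    d <- 12345
    expect_equal(energy_cost(a, 2 * d)$energy_cost,
                 2 * energy_cost(a, d)$energy_cost)
  }
  expect_error(energy_cost(fox, -1), ">= 0")
})

test_that("the published 100 km cost for a 4.5 kg running mammal is
           reproduced", {
  fox <- animal_profile(4.5, "mammal")
  # 58.82 J/m x 1e5 m
  expect_equal(energy_cost(fox, 1e5)$energy_cost, 5.882e6, tolerance = 1e-2)
  expect_equal(cost_per_metre(fox) * 1e5, energy_cost(fox, 1e5)$energy_cost)
})

test_that("energy is conserved and depletion is exactly linear", {
  set.seed(11)
  for (i in 1:25) {
    g <- sample(c("bird", "mammal", "fish"), 1)
    a <- animal_profile(exp(runif(1, log(1e-3), log(1e3))), g)
    d <- runif(1, 0, 1e7)
    out <- energy_cost(a, d)
    expect_equal(out$energy_remaining + out$energy_cost, energy_storage(a),
                 tolerance = 1e-9)
  }
  # second differences of Er over an arithmetic distance grid vanish
  er <- energy_cost(animal_profile(2, "fish"), seq(0, 1e6, by = 1e5))
  expect_equal(diff(er$energy_remaining, differences = 2),
               rep(0, length(er$distance) - 2),
               tolerance = 1e-9 * energy_storage(animal_profile(2, "fish")))
})

test_that("beyond the maximum distance the outcome is flagged, not an
           error", {
  fox <- animal_profile(4.5, "mammal")
  dmax <- max_dispersal_distance(fox)$d_max
  out <- energy_cost(fox, 2 * dmax)
  expect_false(out$feasible)
  expect_lt(out$energy_remaining, 0)
  expect_true(energy_cost(fox, 0.5 * dmax)$feasible)
})

test_that("relative depletion runs from 0 at the origin to 1 at Dmax", {
  for (a in profiles_at(0.7)) {
    expect_identical(relative_depletion(a, 0), 0)
    dmax <- max_dispersal_distance(a)$d_max
    expect_equal(relative_depletion(a, dmax), 1, tolerance = 1e-12)
  }
  expect_error(relative_depletion(fish_1kg, 100, lambda = 1), "lambda = 1")
  # published example: 4000 kg running mammal uses ~7% over 100 km
  expect_identical(
    round(100 * relative_depletion(animal_profile(4000, "mammal"), 1e5)), 7)
})

test_that("larger runners are relatively more efficient despite higher
           absolute cost", {
  small <- animal_profile(4.5, "mammal")
  large <- animal_profile(4000, "mammal")
  expect_gt(cost_per_metre(large), cost_per_metre(small))
  expect_lt(relative_depletion(large, 1e5), relative_depletion(small, 1e5))
})

test_that("maximum distance is linear in (1 - lambda)", {
  a <- animal_profile(0.5, "bird")
  expect_identical(max_dispersal_distance(a, lambda = 1)$d_max, 0)
  sw <- lambda_sweep(a, c(0, 0.5, 1))
  expect_equal(sw$d_max_m / sw$d_max_m[1], c(1, 0.5, 0))
  expect_equal(lambda_sweep(a, 0.1)$d_max_m,
               max_dispersal_distance(a)$d_max)
  # any two rows: Dmax(l1)/Dmax(l2) = (1-l1)/(1-l2)
  set.seed(4)
  l <- runif(6, 0, 0.95)
  d <- lambda_sweep(a, l)$d_max_m
  for (i in 2:6)
    expect_equal(d[1] / d[i], (1 - l[1]) / (1 - l[i]), tolerance = 1e-12)
  expect_error(lambda_sweep(a, numeric(0)), "at least one")
  expect_error(lambda_sweep(a, c(0.2, 1.5)), "\\[0, 1\\]")
})

test_that("resting extension reduces to the non-resting result and
           shrinks distance monotonically", {
  for (a in profiles_at(3.3)) {
    base <- max_dispersal_distance(a)
    expect_identical(max_dispersal_distance_resting(a, beta = 0)$d_max,
                     base$d_max)
    expect_identical(max_dispersal_distance_resting(a, beta = 1)$d_max, 0)
    betas <- seq(0, 1, by = 0.1)
    d <- vapply(betas, function(b)
      max_dispersal_distance_resting(a, beta = b)$d_max, numeric(1))
    expect_true(all(diff(d) < 0))
    # independent closed form: Dmax_beta = v*Ea / (FMR + beta/(1-beta)*BMR)
    v <- travel_speed(a); Ea <- 0.9 * energy_storage(a)
    fmr <- field_metabolic_rate(a); bmr <- basal_metabolic_rate(a)
    b <- 0.5
    expect_equal(max_dispersal_distance_resting(a, beta = b)$d_max,
                 v * Ea / (fmr + b / (1 - b) * bmr), tolerance = 1e-12)
    expect_lt(max_dispersal_distance_resting(a, beta = b)$d_max, base$d_max)
  }
  expect_error(max_dispersal_distance_resting(fish_1kg, beta = -0.1),
               "\\[0, 1\\]")
  expect_error(max_dispersal_distance_resting(fish_1kg, beta = 1.2),
               "\\[0, 1\\]")
})

test_that("at 2 kg swimmers out-range fliers out-range runners", {
  d <- vapply(profiles_at(2), function(a)
    max_dispersal_distance(a)$d_max, numeric(1))
  expect_gt(d[["fish"]], d[["bird"]])
  expect_gt(d[["bird"]], d[["mammal"]])
})

test_that("maximum distance increases with mass across each empirical
           mass range", {
  ranges <- list(bird = c(0.0031, 8.44), mammal = c(0.0076, 3940),
                 fish = c(0.22, 550))
  for (g in names(ranges)) {
    a <- animal_profile(mass_grid(ranges[[g]][1], ranges[[g]][2], 30), g)
    expect_true(all(diff(max_dispersal_distance(a)$d_max) > 0), label = g)
  }
})
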