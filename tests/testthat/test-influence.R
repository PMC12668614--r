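# Taylor influence decompositions and their finite-difference oracles.

test_that("closed-form partials match central finite differences (both modes)", {
  fluid <- fluid_environment()
  states <- rand_density_radius(100, seed = 101)
  for (i in seq_len(nrow(states))) {
    b <- c(density = states$density[i], radius = states$radius[i])
    exact <- taylor_partials("density_volume", b, fluid)
    fd <- fd_partials_density_volume(b, fluid)
    expect_equal(exact, fd, tolerance = 1e-6)
  }
  wd <- rand_water_dry(100, seed = 202)
  for (i in seq_len(nrow(wd))) {
    b <- c(water_volume = wd$water_volume[i], dry_volume = wd$dry_volume[i],
           dry_density = wd$dry_density[i])
    exact <- taylor_partials("water_dry", b, fluid)
    fd <- fd_partials_water_dry(as.list(b), fluid)
    expect_equal(exact, fd, tolerance = 1e-6)
  }
})

test_that("density partial has the hand-evaluated closed form", {
  # dv/drho = 2 g r^2 / (9 mu), converted to um/s per g/mL
  p <- taylor_partials("density_volume", c(density = 1.10, radius = 2))
  expect_equal(p[["density"]], 8.1495, tolerance = 1e-4)
  # dv/dr vanishes at neutral buoyancy
  p0 <- taylor_partials("density_volume", c(density = 1.026, radius = 2))
  expect_equal(p0[["radius"]], 0)
})

test_that("density/volume influence: trivial axes and hand-derived case", {
  b <- c(density = 1.08, radius = 2.0)
  # only density changes
  i1 <- influence_density_volume(b, c(density = 1.12, radius = 2.0))
  expect_equal(unname(i1$influences[c("density", "volume")]), c(1, 0))
  # only radius changes
  i2 <- influence_density_volume(b, c(density = 1.08, radius = 2.3))
  expect_equal(unname(i2$influences[c("density", "volume")]), c(0, 1))
  # hand-derived mixed case: term_rho ~ r0^2 drho, term_r ~ 2 r0 (rho0-rf) dr
  i3 <- influence_density_volume(b, c(density = 1.10, radius = 2.1))
  expect_equal(i3$influences[["density"]], 0.08 / (0.08 + 0.0216),
               tolerance = 1e-9)
  expect_equal(i3$influences[["volume"]],
               1 - i3$influences[["density"]])  # exact identity
})

test_that("water/dry influence: trivial axes and finite-difference case", {
  b <- c(water_volume = 60, dry_volume = 40, dry_density = 1.30)
  i1 <- influence_water_dry(b, c(water_volume = 75, dry_volume = 40,
                                 dry_density = 1.30))
  expect_equal(unname(i1$influences[c("water", "dry_volume",
                                      "dry_density")]), c(1, 0, 0))
  i2 <- influence_water_dry(b, c(water_volume = 60, dry_volume = 40,
                                 dry_density = 1.42))
  expect_equal(unname(i2$influences[c("water", "dry_volume",
                                      "dry_density")]), c(0, 0, 1))

  # both volumes scale 10%, dry density fixed: matches the
  # central-difference attribution and sums to one
  p <- c(water_volume = 66, dry_volume = 44, dry_density = 1.30)
  res <- influence_water_dry(b, p)
  fd <- fd_partials_water_dry(as.list(b))
  terms_fd <- fd * (p - b)
  expect_equal(res$influences[["dry_density"]], 0)
  expect_equal(unname(res$influences[c("water", "dry_volume")]),
               unname(terms_fd[c("water_volume", "dry_volume")] /
                        sum(terms_fd)), tolerance = 1e-6)
  expect_equal(sum(res$influences[c("water", "dry_volume",
                                    "dry_density")]), 1, tolerance = 1e-9)
  # I_dry aggregates its two factors exactly
  expect_equal(res$influences[["dry"]],
               res$influences[["dry_volume"]] +
                 res$influences[["dry_density"]])
})

test_that("influences sum to one on randomized valid state pairs", {
  set.seed(303)
  st <- rand_density_radius(100, seed = 303)
  for (i in seq_len(nrow(st))) {
    b <- c(density = st$density[i], radius = st$radius[i])
    p <- b * (1 + runif(2, -0.1, 0.1))
    res <- tryCatch(influence_density_volume(b, p),
                    psk_error = function(e) NULL)
    if (is.null(res)) next  # degenerate pair excluded by contract
    expect_equal(sum(res$influences[c("density", "volume")]), 1,
                 tolerance = 1e-9)
  }
  wd <- rand_water_dry(100, seed = 404)
  for (i in seq_len(nrow(wd))) {
    b <- c(water_volume = wd$water_volume[i], dry_volume = wd$dry_volume[i],
           dry_density = wd$dry_density[i])
    p <- b * (1 + runif(3, -0.1, 0.1))
    res <- tryCatch(influence_water_dry(b, p),
                    psk_error = function(e) NULL)
    if (is.null(res)) next
    expect_equal(sum(res$influences[c("water", "dry_volume",
                                      "dry_density")]), 1, tolerance = 1e-9)
  }
})

test_that("first-order sum approaches the exact change for small perturbations", {
  fluid <- fluid_environment()
  states <- rand_density_radius(20, seed = 505)
  for (i in seq_len(nrow(states))) {
    b <- c(density = states$density[i], radius = states$radius[i])
    # 1% perturbation of the sinking-relevant factors: the density excess
    # over the fluid (v is linear in it) and the radius
    p <- c(density = fluid$density +
             1.01 * (b[["density"]] - fluid$density),
           radius = 1.01 * b[["radius"]])
    res <- influence_density_volume(b, p, fluid)
    exact_dv <- sinking_velocity(p[["density"]], fluid,
                                 radius = p[["radius"]]) -
      sinking_velocity(b[["density"]], fluid, radius = b[["radius"]])
    expect_equal(res$first_order_delta_v / exact_dv, 1, tolerance = 0.01)
  }
})

test_that("influence fractions are invariant to the direction of the change", {
  # swapping states while keeping the expansion point fixed flips every
  # term's sign, leaving the fractions untouched
  b <- c(density = 1.09, radius = 2.5)
  p <- c(density = 1.13, radius = 2.8)
  fwd <- influence_density_volume(b, p)
  partials <- taylor_partials("density_volume", b)
  rev_terms <- partials * (b - p)
  expect_equal(unname(fwd$influences[c("density", "volume")]),
               unname(rev_terms / sum(rev_terms)), tolerance = 1e-12)
})

test_that("degenerate decompositions raise typed errors", {
  b <- c(density = 1.08, radius = 2.0)
  expect_error(influence_density_volume(b, b), class = "psk_no_change")
  # construct cancelling terms: term_rho = -term_r
  partials <- taylor_partials("density_volume", b)
  drho <- 0.01
  dr <- -partials[["density"]] * drho / partials[["radius"]]
  expect_error(
    influence_density_volume(b, c(density = 1.08 + drho,
                                  radius = 2.0 + dr)),
    class = "psk_decomposition_undefined")
  expect_error(
    influence_water_dry(c(water_volume = 0, dry_volume = 0,
                          dry_density = 1.3),
                        c(water_volume = 1, dry_volume = 1,
                          dry_density = 1.3)),
    class = "psk_domain")
})
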