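# double-well landscape theory: fixed points, Hopf threshold, barriers,
# extremal barrier F and the admissible noise window

test_that("Hopf threshold matches the analytic anchors", {
  expect_equal(round(hopf_beta(5e-4, 0.5), 4), 0.7497)
  expect_equal(hopf_beta(1e-8, 0.5), 0.75, tolerance = 1e-5)
  # monotone decreasing in epsilon near the study value
  expect_lt(hopf_beta(6e-4, 0.5), hopf_beta(4e-4, 0.5))
})

test_that("uncoupled fixed point is the exact cubic root (-1, -2/3)", {
  fp <- fixed_point(elec_layer(kappa = 0))
  expect_equal(fp$v, -1, tolerance = 1e-10)
  expect_equal(fp$w, -2 / 3, tolerance = 1e-10)
  expect_true(fp$excitable)
  expect_lt(abs(fp$residual), 1e-10)
})

test_that("electrical coupling leaves the homogeneous fixed point unchanged; chemical shifts it left", {
  fp0 <- fixed_point(elec_layer(kappa = 0))
  fp1 <- fixed_point(elec_layer(kappa = 1, tau = 3))
  expect_equal(fp1$v, fp0$v, tolerance = 1e-12)
  fpc <- fixed_point(chem_layer(kappa = 0.16))
  expect_lt(fpc$v, -1)
  expect_lt(abs(fpc$residual), 1e-10)
})

test_that("uncoupled potential has the textbook symmetric double well", {
  lay <- elec_layer(kappa = 0)
  expect_equal(potential(lay, 0, 0), 0)
  expect_equal(potential(lay, sqrt(3), 0), -3 / 4)
  expect_equal(potential(lay, -sqrt(3), 0), -3 / 4)
  r <- cubic_roots(lay, w = 0)
  expect_equal(as.numeric(r), c(-sqrt(3), 0, sqrt(3)), tolerance = 1e-10)
  expect_true(attr(r, "three_roots"))
  expect_equal(unname(barriers(lay, 0)), c(3 / 4, 3 / 4), tolerance = 1e-10)
  # outside the fold region only one root survives
  expect_false(attr(cubic_roots(lay, 0.9), "three_roots"))
  expect_false(attr(cubic_roots(lay, -0.9), "three_roots"))
})

test_that("critical points are true roots and match a brute-force grid scan", {
  cfgs <- list(
    list(lay = elec_layer(kappa = 0.3), vbar = -1, w = -0.2),
    list(lay = elec_layer(kappa = 0.6), vbar = 0, w = 0.1),
    list(lay = chem_layer(kappa = 0.4), vbar = 0, w = -0.1),
    list(lay = chem_layer(kappa = 0.5), vbar = "self", w = -0.3))
  for (cf in cfgs) {
    r <- cubic_roots(cf$lay, cf$w, cf$vbar)
    resid <- abs(cf$lay$kappa) # placeholder overwritten below
    u_grad <- sisrmux:::potential_grad(cf$lay, as.numeric(r), cf$w, cf$vbar)
    expect_true(all(abs(u_grad) < 1e-10))
    # brute force: local extrema of U on a fine grid bracket the roots
    v <- seq(-3, 3, length.out = 20001)
    u <- potential(cf$lay, v, cf$w, cf$vbar)
    du <- diff(u)
    flips <- which(du[-1] * du[-length(du)] < 0)
    expect_equal(length(flips), length(r))
    expect_equal(v[flips + 1], as.numeric(r), tolerance = 1e-3)
  }
})

test_that("asymmetry of the wells follows the slow variable", {
  lay <- elec_layer(kappa = 0)
  b <- barriers(lay, w = -0.3)
  expect_lt(b["dU_l"], b["dU_r"])  # shallower left well before a spike
  b2 <- barriers(lay, w = 0.3)
  expect_gt(b2["dU_l"], b2["dU_r"])
})

test_that("stronger coupling deepens the synchronized-landscape barriers", {
  # electrical: symmetric at w = 0 for every kappa, depth grows with kappa
  b25 <- barriers(elec_layer(kappa = 0.25), 0, vbar = "self")
  b100 <- barriers(elec_layer(kappa = 1), 0, vbar = "self")
  expect_equal(unname(b25["dU_l"]), unname(b25["dU_r"]), tolerance = 1e-9)
  expect_equal(unname(b100["dU_l"]), unname(b100["dU_r"]), tolerance = 1e-9)
  expect_gt(b100["dU_l"], b25["dU_l"])
  expect_equal(unname(b100["dU_l"]), 3 / 4 * 4, tolerance = 1e-8)  # (1+k)^2
})

test_that("frozen-neighbour barriers grow with kappa while wells persist", {
  ks <- c(0.05, 0.1, 0.2, 0.3)
  bl <- vapply(ks, function(k)
    barriers(elec_layer(kappa = k), w = 0, vbar = -1)["dU_l"], 0)
  expect_true(all(diff(bl) > 0))
  # chemical: the spike barrier (left) deepens with kappa at a fixed gate
  blc <- vapply(c(0.03, 0.08, 0.14), function(k)
    barriers(chem_layer(kappa = k), w = 0, vbar = 0)["dU_l"], 0)
  expect_true(all(diff(blc) > 0))
})

test_that("electrical landscape stays left-right symmetric for a symmetric neighbour value", {
  for (k in c(0.1, 0.4, 0.8)) {
    b <- barriers(elec_layer(kappa = k), w = 0, vbar = 0)
    expect_equal(unname(b["dU_l"]), unname(b["dU_r"]), tolerance = 1e-9)
  }
  # chemical potential at w = 0 is asymmetric wherever the double well exists
  for (k in c(0.05, 0.1, 0.15)) {
    b <- barriers(chem_layer(kappa = k), w = 0, vbar = 0)
    expect_gt(abs(b["dU_l"] - b["dU_r"]), 1e-4)
  }
})

test_that("extremal barrier F: uncoupled value 3/4, continuity, chemical symmetric point", {
  fe <- f_extremal(elec_layer(kappa = 0))
  expect_equal(fe$F, 0.75, tolerance = 1e-6)
  expect_equal(fe$w_s, 0, tolerance = 1e-6)
  expect_equal(f_extremal(elec_layer(kappa = 1e-6))$F, 0.75, tolerance = 1e-4)
  # inhibitory chemical layer at kappa = 0.16: a symmetric double well exists
  # at some negative slow value (equal barriers at the optimum)
  fc <- f_extremal(chem_layer(kappa = 0.16), vbar = 0)
  expect_lt(fc$w_s, 0)
  expect_equal(unname(fc$dU_l), unname(fc$dU_r), tolerance = 1e-4)
})

test_that("noise window follows the Kramers scaling of the barriers", {
  lay0 <- elec_layer(kappa = 0)
  nw0 <- noise_window(lay0)
  expect_equal(nw0$sigma_max, sqrt(1.5 / log(2000)), tolerance = 1e-10)
  expect_equal(nw0$sigma_max, 0.4442, tolerance = 1e-3)
  expect_equal(nw0$sigma_min, 0, tolerance = 1e-6)  # fixed point at the fold
  expect_false(nw0$empty)
  # sigma_min grows with electrical coupling at a fixed neighbour value
  sm <- vapply(c(0.1, 0.3, 0.6),
               function(k) noise_window(elec_layer(kappa = k))$sigma_min, 0)
  expect_true(all(diff(sm) > 0))
  expect_true(all(sm < vapply(c(0.1, 0.3, 0.6), function(k)
    noise_window(elec_layer(kappa = k))$sigma_max, 0)))
})

test_that("admissibility is exactly the interior of the noise window", {
  lay <- elec_layer(kappa = 0.2)
  nw <- noise_window(lay)
  sig <- c(nw$sigma_min, sqrt(nw$sigma_min * nw$sigma_max), nw$sigma_max)
  adm <- sisr_admissible(sig, lay, nw)
  expect_equal(adm$admissible, c(FALSE, TRUE, FALSE))
  expect_equal(adm$margin_lower[1], 0, tolerance = 1e-12)
  expect_equal(adm$margin_upper[3], 0, tolerance = 1e-12)
  # random sigmas: flag == strict interior
  set.seed(5)
  s <- stats::runif(50, 0, 0.6)
  a <- sisr_admissible(s, lay, nw)
  expect_equal(a$admissible,
               s > nw$sigma_min & s < nw$sigma_max)
  # below the Hopf threshold nothing is admissible
  osc <- layer_spec(kappa = 0.2, neuron = neuron_params(beta = 0.7))
  expect_warning(nwo <- noise_window(osc), "not excitable")
  expect_false(any(sisr_admissible(sig, osc, nwo)$admissible))
})
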