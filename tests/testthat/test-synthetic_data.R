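test_that("noise-free generator reproduces the exact golden-angle spiral", {
  cfg <- synth_config(n_leaves = 4, divergence_sd_deg = 0,
                      big_deviation_prob = 0, internode_sd_mm = 0, seed = 1)
  st <- generate_stem(cfg)
  lv <- st$organs[st$organs$kind == "leaf", ]
  expect_equal(nrow(lv), 4)
  divs <- diff(unwrap_leaf_angles(lv$theta_deg))
  expect_equal(divs, rep(137.5, 3), tolerance = 1e-9)
  expect_equal(diff(lv$H_mm), rep(35, 3))
})

test_that("generation is deterministic per seed and validates its config", {
  cfg <- synth_config(n_leaves = 8, seed = 123)
  s1 <- generate_stem(cfg)
  s2 <- generate_stem(cfg)
  expect_identical(s1$organs, s2$organs)
  p1 <- sample_prickles(s1, cfg)
  p2 <- sample_prickles(s2, cfg)
  expect_identical(p1$organs, p2$organs)
  expect_error(synth_config(n_leaves = 1), "n_leaves")
  expect_error(synth_config(big_deviation_prob = 2), "big_deviation_prob")
})

test_that("divergence noise structure matches its stated distribution", {
  # mixture expectation: (1 - p) * 137.5 + p * 300 for extreme draws
  # uniform on (270, 330)
  divs <- unlist(lapply(1:200, function(s) {
    st <- generate_stem(synth_config(n_leaves = 8, seed = s))
    diff(unwrap_leaf_angles(st$organs$theta_deg[st$organs$kind == "leaf"]))
  }))
  extreme <- divs > 240
  expect_equal(mean(extreme), 0.05, tolerance = 0.5)
  expect_equal(mean(divs[!extreme]), 137.5, tolerance = 2 / 137.5)
  expect_equal(mean(divs), 0.95 * 137.5 + 0.05 * 300,
               tolerance = 3 / 145.6)
  expect_true(any(divs > 270))
})

test_that("prickle sampler respects the hard core and the target density", {
  cfg <- synth_config(n_leaves = 10, seed = 7)
  st <- sample_prickles(generate_stem(cfg), cfg)
  pk <- st$organs[st$organs$kind == "prickle", ]
  expect_gt(nrow(pk), 5)
  d <- nearest_prickle_distances(pk$theta_deg, pk$H_mm, cfg$stem_radius_mm)
  expect_true(all(d >= cfg$min_spacing_mm))

  # uniform density regime: phi of sampled prickles is uniform on the
  # circle (chi-square goodness of fit)
  ucfg <- synth_config(
    n_leaves = 60, prickles_per_internode_mean = 12, min_spacing_mm = 0,
    params = model_params(1e-9, 0, -0.909, 0.071, 1.661), seed = 21
  )
  ust <- sample_prickles(generate_stem(ucfg), ucfg)
  out <- process_stem(ust)
  expect_gt(nrow(out), 400)
  counts <- table(cut(out$phi_deg, breaks = seq(-90, 270, by = 30)))
  expect_gt(suppressWarnings(chisq.test(counts)$p.value), 0.01)
})

test_that("sampled patterns reproduce the generating density profile", {
  grid <- model_density_grid(
    redqueen_params(),
    phi_axis = (-90 + 360 * (0:99) / 100) * pi / 180,
    t_axis = (0:99) / 100
  )
  p_marg <- rowSums(grid$values) / sum(grid$values)
  # goodness of fit of the sampled phi marginal against the generating
  # density (the marginal is nearly flat, CV ~ 8%, so a chi-square GOF is
  # the powerful check; the correlation needs n large enough for the
  # Poisson noise to drop below that signal)
  pts <- redqueen_fixture(seed = 11, n = 4000)
  hist100 <- tabulate(findInterval(pts$phi_deg, -90 + 360 * (0:100) / 100),
                      nbins = 100)
  stat <- sum((hist100 - 4000 * p_marg)^2 / (4000 * p_marg))
  expect_gt(pchisq(stat, df = 99, lower.tail = FALSE), 0.01)
  # increasing-n correlation against the 20-bin coarse marginal
  coarse <- function(x) colSums(matrix(x, nrow = 5))
  cors <- vapply(c(4000, 40000), function(n) {
    p <- redqueen_fixture(seed = 11, n = n)
    hh <- tabulate(findInterval(p$phi_deg, -90 + 360 * (0:100) / 100),
                   nbins = 100)
    cor(coarse(hh), coarse(p_marg))
  }, numeric(1))
  expect_gt(cors[2], cors[1])
  expect_gt(cors[2], 0.9)
  # band concentration: 90-135 degrees holds more than the uniform share
  expect_gt(mean(pts$phi_deg >= 90 & pts$phi_deg <= 135), 0.125)
  expect_error(redqueen_fixture(seed = 1, n = 0), "n must be")
})

test_that("measurement round-trip recovers sampled prickle coordinates", {
  # zero divergence noise and constant internodes make the spline exact,
  # so (phi, h) -> (theta, H) -> (phi, h) is the identity
  cfg <- synth_config(n_leaves = 8, divergence_sd_deg = 0,
                      big_deviation_prob = 0, internode_sd_mm = 0, seed = 31)
  st <- sample_prickles(generate_stem(cfg), cfg)
  lv <- st$organs[st$organs$kind == "leaf", ]
  frame <- fit_phyllotaxis_spline(lv$H_mm, unwrap_leaf_angles(lv$theta_deg))
  pk <- st$organs[st$organs$kind == "prickle", ]
  out <- process_stem(st, stem_radius_mm = cfg$stem_radius_mm)
  expect_equal(nrow(out), nrow(pk))
  # recomputed phi agrees with direct back-conversion of each prickle
  phi_direct <- compute_phi(pk$theta_deg, pk$H_mm, frame)
  expect_equal(sort(out$phi_deg), sort(phi_direct), tolerance = 1e-9)
  expect_true(all(out$phi_deg >= -90 & out$phi_deg < 270))
  expect_true(all(out$h >= 0 & out$h <= 1))
  expect_true(all(out$d_pp_mm >= cfg$min_spacing_mm))

  # full loop at scale: sample from the model density, convert to
  # (theta, H), re-measure, and compare the recovered phi histogram with
  # the generating density's phi marginal
  big <- synth_config(n_leaves = 60, prickles_per_internode_mean = 12,
                      min_spacing_mm = 0, divergence_sd_deg = 0,
                      big_deviation_prob = 0, internode_sd_mm = 0, seed = 41)
  bst <- sample_prickles(generate_stem(big), big)
  bout <- process_stem(bst)
  expect_gt(nrow(bout), 400)
  grid <- model_density_grid(
    big$params,
    phi_axis = (-90 + 360 * (0:99) / 100) * pi / 180, t_axis = (0:99) / 100
  )
  # chi-square GOF of the re-measured phi marginal against the density
  # marginal binned the same way: a wrong inverse transform would shift
  # the histogram and blow this statistic up
  hist12 <- tabulate(
    findInterval(bout$phi_deg, -90 + 360 * (0:12) / 12), nbins = 12)
  p_marg <- rowSums(grid$values) / sum(grid$values)
  p12 <- as.vector(tapply(
    p_marg, findInterval(grid$phi_axis * 180 / pi, -90 + 360 * (0:12) / 12),
    sum))
  n <- nrow(bout)
  stat <- sum((hist12 - n * p12)^2 / (n * p12))
  expect_gt(pchisq(stat, df = 11, lower.tail = FALSE), 0.01)
})

test_that("the paired-prickle fixture is the two symmetric points", {
  fx <- aseyal_pair_fixture()
  expect_equal(nrow(fx), 2)
  expect_equal(fx$h, c(0.95, 0.95))
  expect_equal(sort(fx$phi_deg), c(-60, 60))
})
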