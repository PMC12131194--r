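test_that("Hill block fraction matches its closed forms and monotonicity", {
  expect_equal(hill_fraction_blocked(10, 10, h = 3), 0.5)
  expect_equal(hill_fraction_blocked(0, 5), 0)
  expect_equal(hill_fraction_blocked(9 * 5, 5, h = 1), 0.9)
  cs <- sort(runif(50, 0, 1000))
  f <- hill_fraction_blocked(cs, 21.18, 1.3)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0 & f < 1))
  expect_error(hill_fraction_blocked(-1, 10), "non-negative")
})

test_that("packaged 6f block profiles scale conductances exactly", {
  p <- crn_params("AF")
  for (row in list(c(100, 0.50, 0.35, 0.15),
                   c(10, 0.975, 0.70, 0.25),
                   c(1, 1.00, 0.84, 0.42))) {
    pb <- apply_block(p, block_profile_6f(row[1]))
    expect_equal(pb[["g_kur"]], p[["g_kur"]] * row[2], tolerance = 1e-14)
    expect_equal(pb[["g_na"]], p[["g_na"]] * row[3], tolerance = 1e-14)
    expect_equal(pb[["g_k2p"]], p[["g_k2p"]] * row[4], tolerance = 1e-14)
    untouched <- setdiff(names(p), c("g_kur", "g_na", "g_k2p"))
    expect_identical(pb[untouched], p[untouched])
  }
})

test_that("apply_block is identity at zero, zeroing at one, and composes multiplicatively", {
  p <- crn_params("SR")
  expect_identical(apply_block(p, block_profile(0)), p)
  p1 <- apply_block(p, block_profile(1, 1, 1, 1))
  expect_identical(unname(p1[c("g_kur", "g_na", "g_k2p")]), c(0, 0, 0))
  b1 <- block_profile(1, 0.2, 0.3, 0.4)
  b2 <- block_profile(1, 0.5, 0.1, 0.25)
  seq2 <- apply_block(apply_block(p, b1), b2)
  combo <- block_profile(1, 1 - 0.8 * 0.5, 1 - 0.7 * 0.9, 1 - 0.6 * 0.75)
  expect_equal(seq2, apply_block(p, combo), tolerance = 1e-12)
  expect_error(apply_block(p, block_profile_6f(7)), "available")
})

test_that("percent inhibition algebra, including activation sign", {
  expect_equal(percent_inhibition(5, 5), 0)
  expect_equal(percent_inhibition(5, 0), 100)
  expect_equal(percent_inhibition(2, 2.8), -40)  # TASK-4-type activation
  # invariance under common current rescaling
  expect_equal(percent_inhibition(3 * 2, 3 * 0.5),
               percent_inhibition(2, 0.5))
  expect_error(percent_inhibition(0, 1), "non-zero")
})

test_that("hemolysis percentage reproduces the control anchors", {
  expect_equal(hemolysis_percent(0.9, 0.1, 0.9), 100)
  expect_equal(hemolysis_percent(0.1, 0.1, 0.9), 0)
  expect_equal(hemolysis_percent(0.5, 0.1, 0.9), 50)
  expect_error(hemolysis_percent(0.5, 0.2, 0.2), "dynamic range")
})

test_that("noiseless Hill fits are an exact inverse over random parameters", {
  cs <- c(0.01, 0.1, 1, 10, 100, 1000)
  set.seed(1)
  for (k in 1:10) {
    ic50 <- 10^runif(1, -2, 3)
    h <- runif(1, 0.3, 3)
    grid <- 10^seq(log10(ic50) - 2, log10(ic50) + 2, length.out = 7)
    fit <- fit_hill(grid, hill_fraction_blocked(grid, ic50, h))
    expect_equal(fit$ic50, ic50, tolerance = 1e-6)
    expect_equal(fit$h, h, tolerance = 1e-6)
  }
  # and on the default assay grid
  fit <- fit_hill(cs, hill_fraction_blocked(cs, 10, 1))
  expect_equal(fit$ic50, 10, tolerance = 1e-6)
  expect_false(fit$activation)
})

test_that("Hill CI covers the generating IC50 in >= 90% of noisy repeats", {
  cs <- c(0.01, 0.1, 1, 10, 100, 1000)
  covered <- 0
  for (k in 1:200) {
    d <- gen_dose_response(10, 1, cs, sigma = 0.05, n_reps = 6, seed = k)
    fit <- fit_hill(d$concentration_uM, d$response_fraction)
    if (fit$ic50_ci[1] <= 10 && 10 <= fit$ic50_ci[2]) covered <- covered + 1
  }
  expect_gte(covered / 200, 0.90)
})

test_that("monotone-decreasing responses are flagged as activation", {
  cs <- c(0.1, 1, 10, 100, 1000)
  resp <- 1 - hill_fraction_blocked(cs, 10, 1)   # falls with concentration
  fit <- fit_hill(cs, resp)
  expect_true(fit$activation)
  expect_lt(fit$h, 0)
})

test_that("Boltzmann G-V fits recover generating parameters", {
  v <- seq(-80, 20, by = 10)
  g <- 1 / (1 + exp((-40 - v) / 7))
  fit <- fit_boltzmann(v, g)
  expect_equal(fit$v_half, -40, tolerance = 1e-6)
  expect_equal(fit$k, 7, tolerance = 1e-6)
  # G at the fitted v_half is one half by construction
  expect_equal(1 / (1 + exp((fit$v_half - fit$v_half) / fit$k)), 0.5)
  set.seed(7)
  gn <- g + rnorm(length(g), 0, 0.02)
  fitn <- fit_boltzmann(v, gn)
  expect_lt(abs(fitn$v_half - (-40)), 2)
  expect_error(fit_boltzmann(c(-40, 0), c(0.4, 0.9)), ">= 5")
})

test_that("4PL viability fits recover the cytotoxic IC50", {
  cs <- c(1, 5, 10, 25, 50, 100, 250, 500)
  y <- 0 + (100 - 0) / (1 + (cs / 129.7)^1)
  fit <- fit_4pl(cs, y)
  expect_equal(fit$ic50, 129.7, tolerance = 1e-5)
  expect_equal(fit$bottom, 0, tolerance = 1e-4)
  expect_equal(fit$top, 100, tolerance = 1e-4)
  # viability at the fitted midpoint is (top+bottom)/2
  mid <- fit$bottom + (fit$top - fit$bottom) / (1 + (fit$ic50 / fit$ic50)^fit$slope)
  expect_equal(mid, (fit$top + fit$bottom) / 2)
  # Monte-Carlo recovery: the median error over noisy repeats (sigma = 5%,
  # 5 experiments) stays within 15% relative of the generating midpoint
  errs <- sapply(1:20, function(k) {
    set.seed(k)
    yn <- rep(y, 5) + rnorm(5 * length(y), 0, 5)
    abs(fit_4pl(rep(cs, 5), yn)$ic50 - 129.7) / 129.7
  })
  expect_lt(median(errs), 0.15)
})
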