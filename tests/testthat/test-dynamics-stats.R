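test_that("baseline normalization returns ones for a flat trace and the fold at the end", {
  time <- seq(0, 10, by = 0.5)
  tr <- matrix(rep(7, length(time)), 1)
  expect_equal(as.numeric(normalizeToBaseline(tr, time, 0)),
               rep(1, length(time)))
  tr2 <- matrix(seq(5, 10, length.out = length(time)), 1)
  n2 <- normalizeToBaseline(tr2, time, 0)
  expect_equal(n2[1, length(time)], 2)
  # non-positive baseline excluded with a message
  tr3 <- rbind(tr2, 0 * tr2)
  expect_message(n3 <- normalizeToBaseline(tr3, time, 0), "non-positive")
  expect_equal(nrow(n3), 1L)
})

test_that("generator mean nuclear fold is recovered from normalized traces", {
  sc <- sceneParams(n_cells = 200L, field_size = c(1800L, 1800L),
                    n_frames = 56L, frame_interval = 30, drug_frame = 6L,
                    rng_seed = 33)
  truth <- simulateDynamics(generatePopulation(sc),
                            responseParams(fold_nuclear_25h = c(1.9, 1.9)))
  tk <- linkTracks(truthMeasurements(truth), max_displacement = 13,
                   pixel_size = 0.8)
  tr <- traceMatrix(tk, "nuclear", "cyan")
  time <- (as.numeric(colnames(tr)) - 6) * 0.5   # hours relative to drug
  norm <- normalizeToBaseline(tr, time, 0)
  at25 <- which(abs(time - 25) < 1e-9)
  expect_lt(abs(mean(norm[, at25], na.rm = TRUE) - 1.9) / 1.9, 0.10)
})

test_that("population CV matches hand arithmetic and the lognormal closed form", {
  expect_equal(populationCV(c(1, 2, 3)), 0.5)
  expect_equal(populationCV(rep(4, 10)), 0)
  expect_warning(v <- populationCV(c(5)), "n < 2")
  expect_true(is.na(v))
  expect_warning(v2 <- populationCV(c(-1, 1)), "zero mean")
  expect_true(is.na(v2))
  # lognormal: CV -> sqrt(exp(sigma^2) - 1)
  set.seed(101)
  sigma <- 0.4
  x <- rlnorm(2e5, meanlog = 1, sdlog = sigma)
  expect_lt(abs(populationCV(x) - sqrt(exp(sigma^2) - 1)), 0.01)
})

test_that("90:10 ratio follows the interpolated-percentile oracle", {
  expect_equal(ratio9010(rep(3, 20)), 1)
  # brute-force type-7 oracle for 1..100: h = (n-1)p + 1
  x <- 1:100
  h10 <- 99 * 0.1 + 1; h90 <- 99 * 0.9 + 1
  q10 <- x[floor(h10)] + (h10 - floor(h10)) * (x[floor(h10) + 1] - x[floor(h10)])
  q90 <- x[floor(h90)] + (h90 - floor(h90)) * (x[floor(h90) + 1] - x[floor(h90)])
  expect_equal(q10, 10.9)
  expect_equal(q90, 90.1)
  expect_equal(ratio9010(x), q90 / q10)
  expect_equal(ratio9010(x), 8.266055, tolerance = 1e-6)
  # lognormal: ratio -> exp(2 * z_0.9 * sigma)
  set.seed(102)
  sigma <- 0.5
  x <- rlnorm(2e5, meanlog = 2, sdlog = sigma)
  expect_lt(abs(ratio9010(x) / exp(2 * qnorm(0.9) * sigma) - 1), 0.02)
  expect_warning(v <- ratio9010(1:5), "n < 10")
  expect_true(is.na(v))
  expect_warning(v2 <- ratio9010(c(rep(0, 5), 1:10)), "non-positive")
  expect_true(is.na(v2))
})

test_that("CV and 90:10 ratio are invariant under positive rescaling", {
  set.seed(103)
  for (i in 1:20) {
    x <- rlnorm(50, 1, 0.5)
    a <- runif(1, 0.01, 100)
    expect_equal(populationCV(a * x), populationCV(x), tolerance = 1e-12)
    expect_equal(ratio9010(a * x), ratio9010(x), tolerance = 1e-12)
  }
})

test_that("rank correlation is 1 for monotone pairs and ~0 for independent ones", {
  set.seed(104)
  x <- rlnorm(100, 1, 0.4)
  r <- correlateChannels(x, exp(x) + x^3, n_boot = 100)
  expect_equal(r$estimate, 1)
  n <- 2000
  r0 <- correlateChannels(rnorm(n), rnorm(n), n_boot = 0)
  expect_lt(abs(r0$estimate), 2 / sqrt(n))
  expect_error(correlateChannels(rep(1, 20), rnorm(20)), "constant")
})

test_that("bootstrap CI covers the generator rank correlation", {
  # simulation calibration: copula draws at n = 300, nominal rho_s = 0.6
  set.seed(105)
  rho <- 2 * sin(pi * 0.6 / 6)
  cover <- vapply(1:25, function(i) {
    z1 <- rnorm(300); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(300)
    x <- qlnorm(pnorm(z1), 0, 0.4); y <- qlnorm(pnorm(z2), 0, 0.43)
    r <- correlateChannels(x, y, n_boot = 200)
    r$ci[1] <= 0.6 && 0.6 <= r$ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("response metrics reproduce linear, flat and exponential closed forms", {
  time <- seq(0, 25, by = 0.5)
  lin <- matrix(time / 25 * 8, 1)          # linear rise 0 -> 8 over 25 h
  rm <- responseMetrics(lin, time, drug_time = 0, window = 25)
  expect_equal(rm$T50, 12.5)
  expect_equal(rm$Fmax, 8)
  flat <- matrix(rep(3, length(time)), 1)
  rf <- responseMetrics(flat, time, 0, 25)
  expect_equal(rf$fold, 1)
  expect_equal(rf$T50, 0)
  expect_true(rf$degenerate)
  # saturating exponential: analytic crossing of the half level
  lam <- 5; N0 <- 2; Tg <- 6
  y <- matrix(Tg + (N0 - Tg) * exp(-time / lam), 1)
  re <- responseMetrics(y, time, 0, 25)
  Fend <- Tg + (N0 - Tg) * exp(-25 / lam)
  half <- (N0 + Fend) / 2
  t_analytic <- -lam * log((Tg - half) / (Tg - N0))
  expect_lt(abs(re$T50 - t_analytic), 0.5)   # within one frame interval
  # a trace that never reaches the half level is censored
  cens <- matrix(c(2, rep(2.001, length(time) - 2), 10), 1)
  rc <- responseMetrics(cens, time, 0, 25)
  expect_equal(rc$T50, 24.75, tolerance = 0.5)  # reaches only at the last step
})

test_that("cross-correlation is 1 at lag 0 for duplicated channels and bounded", {
  set.seed(106)
  n <- 40; nT <- 60
  C <- matrix(rnorm(n * nT), n) + outer(rlnorm(n, 0, 0.3), rep(1, nT))
  cc <- crossCorrelation(C, C, time = (1:nT) / 3, max_lag = 6)
  i0 <- which(cc@lag == 0)
  expect_equal(cc@R[i0], 1)
  expect_true(all(abs(cc@R[!is.na(cc@R)]) <= 1 + 1e-12))
  # independent channels: near zero everywhere
  Y <- matrix(rnorm(n * nT), n)
  cc0 <- crossCorrelation(C, Y, (1:nT) / 3, max_lag = 6)
  expect_lt(max(abs(cc0@R), na.rm = TRUE), 0.15)
})

test_that("a lag-shifted copy peaks at the shift, matching a brute-force scan", {
  set.seed(107)
  n <- 30; nT <- 80; shift <- 4
  base <- matrix(0, n, nT + shift)
  for (i in 1:n) base[i, ] <- as.numeric(arima.sim(list(ar = 0.9), nT + shift))
  C <- base[, (shift + 1):(nT + shift)]
  Y <- base[, 1:nT]                        # y(t) = c(t - shift)
  time <- (1:nT) * 0.5
  cc <- crossCorrelation(C, Y, time, max_lag = 5)
  expect_equal(cc@lag[which.max(cc@R)], shift * 0.5)
  # brute-force oracle: per-lag Pearson over pooled deviations
  cbar <- colMeans(C); ybar <- colMeans(Y)
  brute <- vapply(seq_along(cc@lag), function(j) {
    k <- as.integer(round(cc@lag[j] / 0.5))
    ts <- seq_len(nT); keep <- ts + k >= 1 & ts + k <= nT
    a <- as.numeric(sweep(C, 2, cbar)[, ts[keep]])
    b <- as.numeric(sweep(Y, 2, ybar)[, ts[keep] + k])
    mean(a * b) / sqrt(mean(a^2) * mean(b^2))
  }, numeric(1))
  expect_equal(cc@R, brute, tolerance = 1e-12)
})

test_that("R for (c, y) at lag tau equals R for (y, c) at -tau", {
  set.seed(108)
  C <- matrix(rnorm(600), 20)
  Y <- matrix(rnorm(600), 20) + 0.5 * C
  time <- (1:30) * 0.5
  ab <- crossCorrelation(C, Y, time, max_lag = 4)
  ba <- crossCorrelation(Y, C, time, max_lag = 4)
  expect_equal(ab@R, rev(ba@R), tolerance = 1e-12)
})

test_that("tau50 matches the closed form for an exponential decay", {
  lam <- 2
  lag <- seq(-10, 10, by = 0.1)
  R <- exp(-abs(lag) / lam)
  cc <- new("CrossCorrResult", lag = lag, R = R, cov = R,
            nPairs = rep(100L, length(lag)), nCells = 10L, measure = "total")
  expect_lt(abs(tau50(cc) - lam * log(2)), 0.1)
  expect_lt(abs(tau50(cc, symmetric = TRUE) - lam * log(2)), 0.1)
  # constant R never decays: censored
  ccflat <- new("CrossCorrResult", lag = lag, R = rep(1, length(lag)),
                cov = rep(1, length(lag)), nPairs = rep(100L, length(lag)),
                nCells = 10L, measure = "total")
  v <- tau50(ccflat)
  expect_true(is.infinite(v))
  expect_equal(attr(v, "censored_at"), 10)
})

test_that("slow common-mode dynamics decorrelate more slowly than fast ones", {
  set.seed(109)
  n <- 60; nT <- 90; time <- (1:nT) * (1 / 3)
  mk <- function(ar) {
    # per-cell latent dynamics shared by both channels (the statistic works
    # on deviations from the cross-sectional mean, so a population-common
    # mode would cancel out)
    C <- matrix(0, n, nT); Y <- matrix(0, n, nT)
    for (i in 1:n) {
      s <- as.numeric(arima.sim(list(ar = ar), nT))
      C[i, ] <- s + as.numeric(arima.sim(list(ar = ar), nT))
      Y[i, ] <- s + as.numeric(arima.sim(list(ar = ar), nT))
    }
    crossCorrelation(C, Y, time, max_lag = 8)
  }
  slow <- tau50(mk(0.95)); fast <- tau50(mk(0.3))
  expect_gt(slow, fast)
})

test_that("population report flags tiny samples and nails identical channels", {
  one <- data.frame(frame = 1L, track_id = 1L, cell_id = 1L,
                    centroid_row = 1, centroid_col = 1, area = 10,
                    border = FALSE, total_cyan = 5, nuclear_cyan = 2,
                    cyto_cyan = 3, enrich_cyan = 0.4, total_yellow = 5,
                    nuclear_yellow = 2, cyto_yellow = 3, enrich_yellow = 0.4)
  rep1 <- populationReport(one, measures = "total")
  expect_equal(rep1$n_cells, 1L)
  expect_true(is.na(rep1$cv_cyan))
  expect_true(is.na(rep1$spearman_R))

  sc <- smallScene(n_cells = 15L, n_frames = 2L, seed = 51)
  tk <- linkTracks(truthMeasurements(simulateDynamics(generatePopulation(sc))))
  tk$total_yellow <- tk$total_cyan
  tk$nuclear_yellow <- tk$nuclear_cyan
  tk$cyto_yellow <- tk$cyto_cyan
  tk$enrich_yellow <- tk$enrich_cyan
  rep2 <- populationReport(tk)
  expect_equal(rep2$spearman_R, rep(1, nrow(rep2)))
})
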