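fam_dl <- growth_family("double_logistic")
times24 <- 1:24

make_curves <- function(theta_list, n_per, times = times24, sd = 0, fam = fam_dl,
                        rw = FALSE) {
  rows <- lapply(theta_list, function(th) {
    mu <- growth_mean(fam, times, th)
    t(vapply(seq_len(n_per), function(i) {
      noise <- if (sd == 0) 0 else if (rw) cumsum(rnorm(length(times), 0, sd))
               else rnorm(length(times), 0, sd)
      mu + noise
    }, numeric(length(times))))
  })
  do.call(rbind, rows)
}

test_that("mean functions evaluate their closed forms", {
  lg <- growth_family("logistic")
  expect_equal(growth_mean(lg, 5, c(a = 2, r = 1.3, c = 5)), 1)  # t = c -> a/2
  expect_equal(growth_mean(lg, 1e4, c(2, 1, 3)), 2, tolerance = 1e-8)  # asymptote
  gz <- growth_family("gompertz")
  expect_equal(growth_mean(gz, 1e4, c(3, 2, 0.5)), 3, tolerance = 1e-6)
  expect_equal(growth_mean(gz, 2, c(3, 2, 0.5)), 3 * exp(-2 * exp(-1)))
  rich <- growth_family("richards")
  expect_equal(growth_mean(rich, 2, c(2, 1, 0.5, 3)), 2 / (1 + exp(-1))^3)
  hoss <- growth_family("hossfeld")
  expect_equal(growth_mean(hoss, 2, c(2, 2, 4)), 2 * 4 / (4 + 4))
  # double-logistic with a vanishing second term reduces to the logistic
  th <- c(1.7, 0.9, 6, 0, 1, 0)
  expect_equal(growth_mean(fam_dl, times24, th),
               growth_mean(lg, times24, c(1.7, 0.9, 6)))
  expect_error(growth_mean(lg, 1, c(1, 2)), "length 3")
})

test_that("analytic jacobians match finite differences", {
  thetas <- list(logistic = c(2, 0.8, 7), gompertz = c(2, 3, 0.4),
                 richards = c(2, 4, 0.5, 1.5), hossfeld = c(2, 2.5, 30),
                 double_logistic = c(1, .8, 7, 1.2, .6, 16))
  for (nm in names(thetas)) {
    fam <- growth_family(nm)
    th <- thetas[[nm]]
    j <- fam$jac(times24, th)
    for (k in seq_along(th)) {
      tp <- th; tp[k] <- tp[k] + 1e-6
      num <- (growth_mean(fam, times24, tp) - growth_mean(fam, times24, th)) / 1e-6
      expect_equal(j[, k], num, tolerance = 1e-3)
    }
  }
})

test_that("noiseless grouped fits recover the generating parameters", {
  th1 <- c(1, .8, 7, 1.2, .6, 16)
  th2 <- c(1.4, .9, 9, .8, .5, 14)
  y <- make_curves(list(th1, th2), n_per = 3)
  tg <- functional_target(y, times24)
  fit <- fit_curve(tg, fam_dl, rep(c("g1", "g2"), each = 3))
  expect_lt(fit$rss, 1e-6)
  mu1 <- growth_mean(fam_dl, times24, fit$theta_by_group$g1)
  expect_equal(mu1, growth_mean(fam_dl, times24, th1), tolerance = 1e-4)
  mu2 <- growth_mean(fam_dl, times24, fit$theta_by_group$g2)
  expect_equal(mu2, growth_mean(fam_dl, times24, th2), tolerance = 1e-4)
  # parameter count: 2 groups x 6 + pooled variance = 13
  expect_identical(fit$n_params, 13L)
})

test_that("the NLS optimum matches a coarse-to-fine grid-search oracle", {
  set.seed(4)
  lg <- growth_family("logistic")
  th <- c(2, 0.7, 10)
  y <- make_curves(list(th), n_per = 4, sd = 0.1, fam = lg)
  tg <- functional_target(y, times24)
  fit <- fit_curve(tg, lg)
  ybar <- colMeans(y)
  obj <- function(p) sum((ybar - growth_mean(lg, times24, p))^2)
  # coarse-to-fine grid search around the data-driven box
  lo <- c(0.5, 0.1, 2); hi <- c(4, 2, 20)
  best <- NULL
  for (pass in 1:3) {
    gr <- expand.grid(a = seq(lo[1], hi[1], length.out = 12),
                      r = seq(lo[2], hi[2], length.out = 12),
                      c = seq(lo[3], hi[3], length.out = 12))
    vals <- apply(gr, 1, obj)
    best <- as.numeric(gr[which.min(vals), ])
    w <- (hi - lo) / 6
    lo <- best - w; hi <- best + w
  }
  expect_lt(sum((ybar - predict(fit, "all")[1, ])^2), obj(best) + 1e-6)
})

test_that("parameter recovery tightens as noise shrinks (iid and random walk)", {
  set.seed(9)
  th <- c(1, .8, 7, 1.2, .6, 16)
  mu <- growth_mean(fam_dl, times24, th)
  for (em in c("iid", "random_walk")) {
    ctl <- growth_control(error_model = em)
    errs <- vapply(c(0, 0.02, 0.1), function(sd) {
      y <- make_curves(list(th), n_per = 30, sd = sd, rw = em == "random_walk")
      fit <- fit_curve(functional_target(y, times24), fam_dl, control = ctl)
      sqrt(mean((predict(fit, "all")[1, ] - mu)^2))
    }, 0)
    expect_lt(errs[1], 1e-6)
    expect_lt(errs[2], 0.05)
    expect_true(errs[2] <= errs[3] + 0.02)
  }
})

test_that("the fitted solution is a local maximum of the Gaussian likelihood", {
  set.seed(21)
  th <- c(1, .8, 7, 1.2, .6, 16)
  y <- make_curves(list(th), n_per = 10, sd = 0.05)
  tg <- functional_target(y, times24)
  fit <- fit_curve(tg, fam_dl)
  rss_hat <- fit$rss
  for (i in 1:20) {
    pert <- fit$theta_by_group$all * (1 + runif(6, -0.05, 0.05))
    rss_p <- sum(sweep(y, 2, growth_mean(fam_dl, times24, pert))^2)
    expect_gte(rss_p, rss_hat - 1e-8)
  }
})

test_that("AIC selection prefers the generating family and penalises arity on ties", {
  set.seed(31)
  gz <- growth_family("gompertz")
  hits <- 0
  for (r in 1:10) {
    y <- make_curves(list(c(2, 6, 0.35)), n_per = 5, sd = 0.02, fam = gz)
    tg <- functional_target(y, times24)
    sel <- select_family(tg, list("logistic", "gompertz"))
    hits <- hits + (sel$name == "gompertz")
  }
  expect_gte(hits, 8)  # far above the 50% chance level
  # single candidate returns that candidate
  y <- make_curves(list(c(2, 6, 0.35)), n_per = 2, sd = 0.01, fam = gz)
  sel1 <- select_family(functional_target(y, times24), list("richards"))
  expect_equal(sel1$name, "richards")
  # equal RSS: the smaller-arity family must win the AIC tie-break
  rss <- 1.0
  aic3 <- curvecause:::growth_aic(rss, 10, 24, 3 + 1)
  aic4 <- curvecause:::growth_aic(rss, 10, 24, 4 + 1)
  expect_lt(aic3, aic4)
})

test_that("AIC variants use RSS/q (printed) and RSS/(nq) respectively", {
  n <- 7; q <- 24; rss <- 2.3; k <- 13
  expect_equal(curvecause:::growth_aic(rss, n, q, k, "printed"),
               n * q + n * q * log(2 * pi) + n * q * log(rss / q) + 2 * k)
  expect_equal(curvecause:::growth_aic(rss, n, q, k, "per_observation"),
               n * q + n * q * log(2 * pi) + n * q * log(rss / (n * q)) + 2 * k)
})

test_that("tidy/glance accessors and target IO round-trip", {
  set.seed(2)
  y <- make_curves(list(c(1, .8, 7, 1.2, .6, 16)), n_per = 3, sd = 0.01)
  tg <- functional_target(y, times24)
  fit <- fit_curve(tg, fam_dl)
  td <- tidy(fit)
  expect_equal(nrow(td), 6L)
  expect_named(td, c("group", "term", "estimate"))
  gl <- glance(fit)
  expect_equal(gl$n_params, 13L - 6L)  # one group: 6 + variance = 7
  tmpj <- tempfile(fileext = ".json")
  write_growth_fit_json(fit, tmpj)
  back <- jsonlite::read_json(tmpj, simplifyVector = TRUE)
  expect_equal(back$family, "double_logistic")
  expect_equal(back$rss, fit$rss, tolerance = 1e-12)
  tmp <- tempfile(fileext = ".csv")
  write_functional_target(tg, tmp)
  back <- read_functional_target(tmp)
  expect_equal(back$times, tg$times)
  expect_equal(back$curves, tg$curves, tolerance = 1e-12)
  expect_error(functional_target(y, rep(1, 24)), "strictly increasing")
  expect_error(functional_target(y, 1:23), "must equal")
})
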