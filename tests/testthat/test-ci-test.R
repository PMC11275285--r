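fam_dl <- growth_family("double_logistic")
times24 <- 1:24

sim_curves <- function(mu_by_level, levels, sd = 0.02, rw = TRUE) {
  t(vapply(levels, function(l) {
    noise <- if (rw) cumsum(rnorm(24, 0, sd)) else rnorm(24, 0, sd)
    mu_by_level[[l]] + noise
  }, numeric(24)))
}

test_that("a constant factor gives lr = 0, df = 0, p = 1", {
  set.seed(1)
  mu <- growth_mean(fam_dl, times24, c(1, .8, 7, 1.2, .6, 16))
  y <- sim_curves(list(mu), rep(1L, 30))
  res <- lr_independence_test(data.frame(X = rep(1L, 30)), "X",
                              functional_target(y, times24), fam_dl)
  expect_equal(res$lr, 0)
  expect_identical(res$df, 0L)
  expect_equal(res$p_value, 1)
  expect_false(res$insufficient)
})

test_that("degrees of freedom count free mean parameters per extra configuration", {
  set.seed(2)
  mu <- growth_mean(fam_dl, times24, c(1, .8, 7, 1.2, .6, 16))
  n <- 60
  x <- data.frame(X = rep(1:2, each = n / 2), A = rep(1:2, times = n / 2))
  y <- sim_curves(list(mu, mu), x$X)
  tg <- functional_target(y, times24)
  res <- lr_independence_test(x, "X", tg, fam_dl)
  expect_identical(res$df, 6L)                 # binary factor: 13 - 7
  expect_identical(res$n_params_alt, 13L)      # 2 x 6 + variance
  expect_identical(res$n_params_null, 7L)
  resc <- lr_conditional_test(x, "X", "A", tg, fam_dl)
  # configs: A has 2, (A, X) has 4 -> df = 6 * 2
  expect_identical(resc$df, 12L)
  expect_identical(resc$n_params_alt - resc$n_params_null, 12L)
  expect_error(lr_conditional_test(x, "X", c("X", "A"), tg, fam_dl), "conditioning")
})

test_that("df additivity over nested groupings holds on random factor tables", {
  set.seed(14)
  n <- 120
  mu <- growth_mean(fam_dl, times24, c(1, .8, 7, 1.2, .6, 16))
  fac <- data.frame(X = sample(1:3, n, TRUE), A = sample(1:2, n, TRUE),
                    B = sample(1:2, n, TRUE))
  y <- sim_curves(list(mu, mu, mu), fac$X)
  tg <- functional_target(y, times24)
  for (a in list(character(0), "A", c("A", "B"))) {
    res <- lr_conditional_test(fac, "X", a, tg, fam_dl, min_cell = 1)
    n_cfg_null <- length(unique(curvecause:::config_labels(fac, a)))
    n_cfg_alt <- length(unique(curvecause:::config_labels(fac, c(a, "X"))))
    expect_identical(res$df, 6L * (n_cfg_alt - n_cfg_null))
  }
})

test_that("marginal null rejection rate is near alpha and power reaches 1", {
  set.seed(3)
  mu0 <- growth_mean(fam_dl, times24, c(1, .8, 7, 1.2, .6, 16))
  mu1 <- growth_mean(fam_dl, times24, c(1.25, .8, 7, 1.45, .6, 16))
  R <- 40
  rej0 <- rej1 <- 0
  for (r in 1:R) {
    n <- 100
    x <- data.frame(X = sample(1:2, n, TRUE))
    # null: curves ignore X
    y0 <- sim_curves(list(mu0, mu0), x$X)
    p0 <- suppressWarnings(
      lr_independence_test(x, "X", functional_target(y0, times24), fam_dl,
                           growth_control(error_model = "random_walk")))$p_value
    rej0 <- rej0 + (p0 < 0.05)
    # alternative: X shifts the curve
    y1 <- sim_curves(list(mu0, mu1), x$X)
    p1 <- suppressWarnings(
      lr_independence_test(x, "X", functional_target(y1, times24), fam_dl,
                           growth_control(error_model = "random_walk")))$p_value
    rej1 <- rej1 + (p1 < 0.05)
  }
  expect_lte(rej0 / R, 0.15)   # near alpha at modest rep count
  expect_gte(rej1 / R, 0.95)   # strong effect: power ~ 1
})

test_that("conditioning on a mediator removes the association", {
  set.seed(5)
  mu_a <- list(growth_mean(fam_dl, times24, c(1, .8, 7, 1.2, .6, 16)),
               growth_mean(fam_dl, times24, c(1.3, .8, 7, 1.5, .6, 16)))
  ctl <- growth_control(error_model = "random_walk")
  R <- 15
  rej_uncond <- rej_cond <- 0
  for (r in 1:R) {
    n <- 200
    x <- sample(1:2, n, TRUE)                       # X -> A -> curve
    a <- ifelse(runif(n) < 0.85, x, 3 - x)
    y <- sim_curves(mu_a, a)
    fac <- data.frame(X = x, A = a)
    tg <- functional_target(y, times24)
    pu <- suppressWarnings(lr_independence_test(fac, "X", tg, fam_dl, ctl))$p_value
    pc <- suppressWarnings(lr_conditional_test(fac, "X", "A", tg, fam_dl, ctl))$p_value
    rej_uncond <- rej_uncond + (pu < 0.05)
    rej_cond <- rej_cond + (pc < 0.05)
  }
  expect_gte(rej_uncond / R, 0.9)  # marginal dependence through the mediator
  expect_lte(rej_cond / R, 0.3)    # conditional independence given the mediator
})

test_that("sparse configuration cells are dropped symmetrically, not fatal", {
  set.seed(6)
  n <- 200
  mu <- list(growth_mean(fam_dl, times24, c(1, .8, 7, 1.2, .6, 16)),
             growth_mean(fam_dl, times24, c(1.4, .8, 7, 1.6, .6, 16)))
  # level 3 is rare (2 samples): it must be dropped, not sink the test
  x <- c(rep(1L, 120), rep(2L, 78), rep(3L, 2))
  y <- sim_curves(c(mu, mu[2]), pmin(x, 2))
  res <- lr_independence_test(data.frame(X = x), "X",
                              functional_target(y, times24), fam_dl,
                              growth_control(error_model = "random_walk"))
  expect_false(res$insufficient)
  expect_identical(res$n_dropped, 2L)
  expect_lt(res$p_value, 1e-6)
  expect_identical(res$df, 6L)  # only two usable levels remain
  # every extra cell sparse -> degenerate flagged non-rejection
  x2 <- c(rep(1L, 198), rep(2L, 2))
  y2 <- sim_curves(c(mu, mu[2]), pmin(x2, 2))
  res2 <- lr_independence_test(data.frame(X = x2), "X",
                               functional_target(y2, times24), fam_dl)
  expect_true(res2$insufficient)
  expect_equal(res2$p_value, 1)
})

test_that("the discrete G-squared CI test detects copies and calibrates on noise", {
  set.seed(8)
  n <- 1000
  x <- sample(1:2, n, TRUE)
  cp <- discrete_ci_test(data.frame(A = x, B = x), "A", "B")
  expect_lt(cp$p_value, 1e-10)
  # independent fair coins: rejection rate near alpha
  rej <- 0
  for (r in 1:200) {
    d <- data.frame(A = sample(1:2, 300, TRUE), B = sample(1:2, 300, TRUE))
    rej <- rej + (discrete_ci_test(d, "A", "B")$p_value < 0.05)
  }
  expect_gt(rej / 200, 0.01)
  expect_lt(rej / 200, 0.10)
  # collider: marginally independent, dependent given the common child
  rej_m <- rej_c <- 0
  for (r in 1:40) {
    a <- sample(0:1, 500, TRUE); b <- sample(0:1, 500, TRUE)
    k <- ifelse(runif(500) < 0.9, as.integer(xor(a, b)), sample(0:1, 500, TRUE))
    d <- data.frame(A = a, B = b, K = k)
    rej_m <- rej_m + (discrete_ci_test(d, "A", "B")$p_value < 0.05)
    rej_c <- rej_c + (discrete_ci_test(d, "A", "B", "K")$p_value < 0.05)
  }
  expect_lte(rej_m / 40, 0.2)
  expect_gte(rej_c / 40, 0.95)
  # stratified df: two strata of a 2x2 table
  d <- data.frame(A = sample(1:2, 400, TRUE), B = sample(1:2, 400, TRUE),
                  Z = sample(1:2, 400, TRUE))
  expect_identical(discrete_ci_test(d, "A", "B", "Z")$df, 2L)
})

test_that("the d-separation oracle answers queries exactly and logs them", {
  chain <- mixed_graph(c("X1", "X2", "Y"),
                       data.frame(tail = c("X1", "X2"), head = c("X2", "Y")))
  ot <- oracle_tester(chain, "Y")
  expect_equal(ot$target_pvalue("X1", "X2"), 1)   # cause but not direct
  expect_equal(ot$target_pvalue("X1", character(0)), 0)
  expect_equal(ot$target_pvalue("X2", "X1"), 0)   # direct edge cannot be blocked
  expect_equal(ot$factor_pvalue("X1", "X2"), 0)
  log <- audit_log(ot)
  expect_equal(nrow(log), 4L)
  expect_equal(log$kind, c(rep("target", 3), "factor"))
  # a target with children is rejected
  bad <- mixed_graph(c("X1", "Y", "Z"),
                     data.frame(tail = c("X1", "Y"), head = c("Y", "Z")))
  expect_error(oracle_tester(bad, "Y"), "no children")
  # randomized agreement with d_separated
  set.seed(30)
  for (r in 1:10) {
    g <- random_test_dag(6, 0.3)
    sinks <- g$vertices[vapply(g$vertices, function(v) length(children_of(g, v)) == 0, TRUE)]
    y <- sinks[1]
    ot <- oracle_tester(g, y)
    others <- setdiff(g$vertices, y)
    for (x in others[1:3]) {
      a <- setdiff(others, x)[1:2]
      expect_equal(ot$target_pvalue(x, a) == 1, d_separated(g, x, y, a))
    }
  }
})
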