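test_that("topology validation and parameter counting", {
  topo <- ann_topology(c(15, 14), c("tansig", "logsig", "purelin"))
  expect_identical(topo$layer_sizes, c(2L, 15L, 14L, 1L))
  # (2*15+15) + (15*14+14) + (14*1+1) = 45 + 224 + 15 = 284
  expect_identical(rwdry:::ann_n_par(topo), 284L)

  expect_error(ann_topology(c(15, 14), c("tansig", "relu", "purelin")),
               "unknown activation")
  expect_error(ann_topology(16, c("tansig", "purelin")), "\\[2, 15\\]")
  expect_error(ann_topology(c(5, 5, 5), rep("tansig", 4)), "two hidden")
  expect_error(ann_topology(5, "tansig"), "activation names")
})

test_that("initialization is seed-deterministic", {
  topo <- ann_topology(7, c("tansig", "purelin"))
  n1 <- build_network(topo, seed = 31)
  n2 <- build_network(topo, seed = 31)
  expect_identical(n1$par, n2$par)
  expect_false(identical(n1$par, build_network(topo, seed = 32)$par))
})

test_that("forward pass reduces to explicit matrix arithmetic", {
  topo <- ann_topology(2, c("purelin", "purelin"))
  net <- build_network(topo, seed = 1)
  # layout: W1 (2x2 col-major), b1 (2), W2 (1x2), b2 (1)
  par <- c(1, 0, 0, 1, 0.5, -0.5, 2, 3, 0.25)
  X <- matrix(c(0.2, -0.3, 0.7, 0.1), 2, 2)
  W1 <- matrix(par[1:4], 2, 2); b1 <- par[5:6]
  W2 <- matrix(par[7:8], 1, 2); b2 <- par[9]
  manual <- as.numeric(W2 %*% (W1 %*% t(X) + b1) + b2)
  expect_equal(ann_forward(net, X, par), manual)

  # all-zero parameters: output is purelin(0) = 0 for any input
  expect_equal(ann_forward(net, X, rep(0, 9)), c(0, 0))

  # activation anchors through a zeroed logsig hidden layer:
  # logsig(0) = 0.5 so the output is W2 %*% (0.5, 0.5) = 0 with zero W2
  tl <- build_network(ann_topology(2, c("logsig", "purelin")), seed = 1)
  p0 <- rep(0, length(tl$par))
  p0[7:8] <- c(1, 1)   # output weights only
  expect_equal(ann_forward(tl, X, p0), c(1, 1))  # 0.5 + 0.5

  expect_error(ann_forward(net, matrix(1, 2, 3)), "expects 2")
})

test_that("analytic Jacobian matches finite differences", {
  for (spec in list(list(h = c(4, 3), a = c("tansig", "logsig", "purelin")),
                    list(h = 5, a = c("logsig", "tansig")),
                    list(h = 3, a = c("purelin", "purelin")))) {
    net <- build_network(ann_topology(spec$h, spec$a), seed = 17)
    set.seed(17)
    X <- matrix(rnorm(12), 6, 2)
    J <- ann_jacobian(net, X)
    h <- 1e-6
    Jfd <- vapply(seq_along(net$par), function(i) {
      p1 <- net$par; p2 <- net$par
      p1[i] <- p1[i] + h; p2[i] <- p2[i] - h
      (ann_forward(net, X, p1) - ann_forward(net, X, p2)) / (2 * h)
    }, numeric(nrow(X)))
    expect_lt(max(abs(J - Jfd)), 1e-6)
  }
})

test_that("LM drives a purelin network to the least-squares optimum", {
  # noiseless linear target: y = 0.3 T' + 0.5 t'
  grid <- expand.grid(temperature_C = c(50, 60, 70, 80, 90),
                      time_min = seq(0, 90, 15))
  Ts <- 2 * (grid$temperature_C - 50) / 40 - 1
  ts <- 2 * grid$time_min / 90 - 1
  d <- data.frame(grid, mr = 0.3 * Ts + 0.5 * ts)
  net <- build_network(ann_topology(3, c("purelin", "purelin")), seed = 5)
  ann <- train_lm(net, d, train_config(seed = 8))
  expect_lt(ann$train_mse, 1e-10)

  # noisy linear data: the purelin network equals OLS on the same design
  set.seed(99)
  d$mr <- d$mr + rnorm(nrow(d), 0, 0.02)
  ann2 <- train_lm(net, d, train_config(seed = 8, patience = 100))
  tr <- ann2$split$train
  ols <- lm(d$mr[tr] ~ Ts[tr] + ts[tr])
  expect_lt(ann2$train_mse - mean(residuals(ols)^2), 1e-8)
})

test_that("a degenerate dataset of identical points fits immediately", {
  d <- data.frame(temperature_C = rep(70, 12), time_min = rep(10, 12),
                  mr = rep(0.4, 12))
  net <- build_network(ann_topology(3, c("tansig", "purelin")), seed = 2)
  ann <- train_lm(net, d, train_config(seed = 3))
  expect_lt(ann$train_mse, 1e-10)
  expect_lte(ann$epoch, 10)
})

test_that("accepted LM steps never increase the training MSE", {
  cfg <- synthetic_config(noise_sd_mr = 0.01, replicates = 1)
  pooled <- rwdry:::pool_moisture_data(generate_experiment(cfg)$drying_runs)
  net <- build_network(ann_topology(6, c("tansig", "purelin")), seed = 12)
  ann <- train_lm(net, pooled, train_config(seed = 4))
  expect_true(all(diff(ann$history$train_mse) <= 0))
  expect_lte(nrow(ann$history), 1200)
})

test_that("training is bitwise deterministic for fixed seed and data", {
  cfg <- quiet_config()
  pooled <- rwdry:::pool_moisture_data(generate_experiment(cfg)$drying_runs)
  net <- build_network(ann_topology(5, c("tansig", "purelin")), seed = 6)
  a1 <- train_lm(net, pooled, train_config(seed = 10))
  a2 <- train_lm(net, pooled, train_config(seed = 10))
  expect_identical(a1$weights, a2$weights)
  expect_identical(a1$history, a2$history)
  expect_identical(a1$mse, a2$mse)
})

test_that("split is stratified over temperatures and respects fractions", {
  cfg <- quiet_config()
  pooled <- rwdry:::pool_moisture_data(generate_experiment(cfg)$drying_runs)
  parts <- rwdry:::.split_indices(pooled$temperature_C,
                                  c(train = 0.7, validation = 0.15,
                                    test = 0.15), seed = 1)
  n <- nrow(pooled)
  expect_identical(sort(as.integer(unlist(parts))), seq_len(n))
  expect_gt(length(parts$train) / n, 0.6)
  for (p in parts)
    expect_setequal(unique(pooled$temperature_C[p]),
                    unique(pooled$temperature_C))
})

test_that("topology search ranks candidates and keeps the linear optimum", {
  grid <- expand.grid(temperature_C = c(50, 70, 90),
                      time_min = seq(0, 60, 10))
  d <- data.frame(grid,
                  mr = 0.5 - 0.002 * grid$time_min +
                       0.001 * (grid$temperature_C - 70))
  one <- topology_search(d, hidden_range = 4,
                         activation_sets = list(c("tansig", "purelin")),
                         config = train_config(seed = 2, max_epochs = 60))
  expect_identical(nrow(one$table), 1L)
  expect_identical(one$table$topology, "2-4-1")

  # linear data: a purelin-only candidate is at least as good as any
  both <- topology_search(
    d, hidden_range = 3,
    activation_sets = list(c("purelin", "purelin"), c("tansig", "purelin")),
    config = train_config(seed = 2, max_epochs = 200, patience = 50)
  )
  pure <- both$table$mse[both$table$activations == "purelin-purelin"]
  expect_lt(pure, min(both$table$mse) + 1e-8)
})

test_that("model comparison flags the lower-MSE side and checks the series", {
  cfg <- quiet_config(temperatures_C = c(50, 70, 90))
  ex <- generate_experiment(cfg)
  pooled <- rwdry:::pool_moisture_data(ex$drying_runs)
  net <- build_network(ann_topology(8, c("tansig", "purelin")), seed = 3)
  ann <- train_lm(net, pooled, train_config(seed = 5))

  s <- moisture_ratio(ex$drying_runs[["T70_r1"]])
  fit <- fit_thin_layer_model(s, "page")
  d70 <- data.frame(temperature_C = 70, time_min = s$time_min, mr = s$mr)
  cmp <- compare_models(ann, fit, d70)
  expect_identical(
    cmp$winner,
    c("ann", "kinetic")[which.min(cmp$table$mse)]
  )
  # Page on its own noiseless curve is essentially exact, so it wins
  expect_identical(cmp$winner, "kinetic")

  d50 <- data.frame(temperature_C = 50, time_min = s$time_min, mr = s$mr)
  expect_error(compare_models(ann, fit, d50), "do not match")
})

test_that("a trained network round-trips through JSON", {
  cfg <- quiet_config(temperatures_C = c(50, 70, 90))
  pooled <- rwdry:::pool_moisture_data(generate_experiment(cfg)$drying_runs)
  net <- build_network(ann_topology(4, c("tansig", "purelin")), seed = 3)
  ann <- train_lm(net, pooled, train_config(seed = 5, max_epochs = 60))
  f <- tempfile(fileext = ".json")
  write_ann_json(ann, f)
  back <- read_ann_json(f)
  expect_equal(predict(back, pooled), predict(ann, pooled),
               tolerance = 1e-12)
})

test_that("train config validates split and damping", {
  expect_error(train_config(split = c(train = 0.6, validation = 0.15,
                                      test = 0.15)), "sum to 1")
  expect_error(train_config(lambda_up = 0.5), "> 1")
  expect_error(train_config(max_epochs = 0), "max_epochs")
})
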