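#' Feedforward network topology for moisture-ratio prediction
#'
#' Two inputs (water temperature, drying time), one or two hidden layers
#' of 2--15 neurons, one output.  Activations are named per non-input
#' layer: `tansig` (hyperbolic tangent), `logsig` (logistic), `purelin`
#' (identity).
#'
#' @param hidden Integer vector of hidden-layer sizes (length 1 or 2,
#'   sizes in `[2, 15]`).
#' @param activations Character vector, one name per non-input layer
#'   (`length(hidden) + 1`).
#' @return Object of class `rw_ann_topology`.
#' @export
ann_topology <- function(hidden, activations) {
  hidden <- as.integer(hidden)
  if (length(hidden) < 1 || length(hidden) > 2)
    stopf("one or two hidden layers supported")
  if (any(hidden < 2 | hidden > 15))
    stopf("hidden sizes must be in [2, 15]")
  if (length(activations) != length(hidden) + 1)
    stopf("need %d activation names", length(hidden) + 1)
  bad <- setdiff(activations, c("tansig", "logsig", "purelin"))
  if (length(bad)) stopf("unknown activation(s): %s", paste(bad, collapse = ", "))
  structure(list(layer_sizes = c(2L, hidden, 1L), activations = activations),
            class = "rw_ann_topology")
}

#' @export
format.rw_ann_topology <- function(x, ...)
  paste(x$layer_sizes, collapse = "-")

.act <- list(
  tansig = list(f = tanh, df = function(z, a) 1 - a^2),
  logsig = list(f = function(z) 1 / (1 + exp(-z)),
                df = function(z, a) a * (1 - a)),
  purelin = list(f = identity, df = function(z, a) rep(1, length(z)))
)

# number of weights + biases
ann_n_par <- function(topology) {
  s <- topology$layer_sizes
  sum(s[-1] * s[-length(s)] + s[-1])
}

#' Initialize a network
#'
#' Seeded small-uniform (-0.5, 0.5) initialization of all weights and
#' biases; the same seed always yields the identical parameter vector.
#'
#' @param topology An [ann_topology()].
#' @param seed Integer seed.
#' @return Object of class `rw_ann_network` with the flat parameter
#'   vector in `par`.
#' @export
build_network <- function(topology, seed = 1) {
  stopifnot(inherits(topology, "rw_ann_topology"))
  P <- ann_n_par(topology)
  par <- with_seed(seed, runif(P, -0.5, 0.5))
  structure(list(topology = topology, par = par, scaling = NULL),
            class = "rw_ann_network")
}

# unpack flat par into per-layer weight matrices and bias vectors
.unpack <- function(topology, par) {
  s <- topology$layer_sizes
  W <- vector("list", length(s) - 1); b <- W
  off <- 0L
  for (l in seq_len(length(s) - 1)) {
    nw <- s[l + 1] * s[l]
    W[[l]] <- matrix(par[off + seq_len(nw)], nrow = s[l + 1], ncol = s[l])
    off <- off + nw
    b[[l]] <- par[off + seq_len(s[l + 1])]
    off <- off + s[l + 1]
  }
  list(W = W, b = b)
}

# forward pass on an N x 2 standardized matrix, keeping activations
.forward_pass <- function(topology, par, X) {
  wb <- .unpack(topology, par)
  L <- length(wb$W)
  A <- vector("list", L + 1); Z <- vector("list", L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% t(wb$W[[l]]), 2, wb$b[[l]], `+`)
    A[[l + 1]] <- .act[[topology$activations[l]]]$f(Z[[l]])
  }
  list(A = A, Z = Z, W = wb$W, out = A[[L + 1]][, 1])
}

#' Evaluate a network on standardized inputs
#'
#' Layer-wise affine map plus activation.  `X` must already be on the
#' scale the network was trained on (see [predict.rw_ann()] for
#' raw-unit prediction).
#'
#' @param network An `rw_ann_network` or trained `rw_ann`.
#' @param X Numeric matrix (N x 2) of standardized inputs.
#' @param par Optional parameter vector overriding `network$par`.
#' @return Numeric vector of predictions.
#' @export
ann_forward <- function(network, X, par = network$par) {
  X <- as.matrix(X)
  if (ncol(X) != network$topology$layer_sizes[1])
    stopf("input has %d columns, network expects %d",
          ncol(X), network$topology$layer_sizes[1])
  .forward_pass(network$topology, par, X)$out
}

#' Jacobian of the network output with respect to all parameters
#'
#' Backpropagated analytic Jacobian: row i is the gradient of the output
#' for sample i with respect to the flat parameter vector, in the same
#' layout as `network$par`.
#'
#' @inheritParams ann_forward
#' @return N x P matrix.
#' @export
ann_jacobian <- function(network, X, par = network$par) {
  X <- as.matrix(X)
  topo <- network$topology
  fp <- .forward_pass(topo, par, X)
  L <- length(fp$W)
  N <- nrow(X)
  s <- topo$layer_sizes
  blocks <- vector("list", L)
  # delta_l: N x s[l+1], derivative of output wrt z_l
  delta <- matrix(
    .act[[topo$activations[L]]]$df(fp$Z[[L]], fp$A[[L + 1]]), nrow = N
  )
  for (l in L:1) {
    Aprev <- fp$A[[l]]
    n_l <- s[l + 1]; n_prev <- s[l]
    JW <- delta[, rep(seq_len(n_l), times = n_prev), drop = FALSE] *
      Aprev[, rep(seq_len(n_prev), each = n_l), drop = FALSE]
    blocks[[l]] <- cbind(JW, delta)
    if (l > 1) {
      delta <- (delta %*% fp$W[[l]]) *
        matrix(.act[[topo$activations[l - 1]]]$df(fp$Z[[l - 1]], fp$A[[l]]),
               nrow = N)
    }
  }
  do.call(cbind, blocks)
}

#' Training configuration for the Levenberg--Marquardt trainer
#'
#' @param split Named fractions for train/validation/test; must sum to 1.
#'   Default 0.70/0.15/0.15, drawn at random stratified by temperature.
#' @param max_epochs Epoch cap (default 1200).
#' @param lambda_init Initial damping.
#' @param lambda_up,lambda_down Damping adjustment factors (> 1):
#'   multiply on a rejected step, divide on an accepted one.
#' @param patience Epochs without validation improvement before early
#'   stopping (default 6).
#' @param gtol Gradient infinity-norm tolerance.
#' @param ftol Relative SSE-improvement tolerance.
#' @param seed Seed for the split and any restarts.
#' @return Object of class `rw_train_config`.
#' @export
train_config <- function(split = c(train = 0.70, validation = 0.15,
                                   test = 0.15),
                         max_epochs = 1200, lambda_init = 1e-3,
                         lambda_up = 10, lambda_down = 10, patience = 6,
                         gtol = 1e-10, ftol = 1e-12, seed = 1) {
  if (abs(sum(split) - 1) > 1e-8) stopf("split fractions must sum to 1")
  if (any(split < 0) || length(split) != 3) stopf("split needs 3 fractions")
  if (max_epochs < 1) stopf("max_epochs must be >= 1")
  if (lambda_up <= 1 || lambda_down <= 1)
    stopf("damping factors must be > 1")
  structure(list(split = split, max_epochs = as.integer(max_epochs),
                 lambda_init = lambda_init, lambda_up = lambda_up,
                 lambda_down = lambda_down, patience = as.integer(patience),
                 gtol = gtol, ftol = ftol, seed = as.integer(seed)),
            class = "rw_train_config")
}

# seeded split of indices, stratified by temperature so every partition
# covers all temperatures when counts allow
.split_indices <- function(temperature, split, seed) {
  parts <- list(train = integer(), validation = integer(), test = integer())
  strata <- split(seq_along(temperature), temperature)
  i <- 0L
  for (idx in strata) {
    i <- i + 1L
    idx <- with_seed(derive_seed(seed, 6L, i), sample(idx))
    n <- length(idx)
    n_val <- floor(split[["validation"]] * n)
    n_test <- floor(split[["test"]] * n)
    parts$validation <- c(parts$validation, idx[seq_len(n_val)])
    parts$test <- c(parts$test, idx[n_val + seq_len(n_test)])
    parts$train <- c(parts$train, idx[-seq_len(n_val + n_test)])
  }
  if (!length(parts$train) || !length(parts$validation) || !length(parts$test))
    stopf("split produced an empty partition (n = %d)", length(temperature))
  parts
}

.standardize <- function(x, lo, hi) {
  if (hi == lo) return(rep(0, length(x)))
  2 * (x - lo) / (hi - lo) - 1
}

#' Train a network by Levenberg--Marquardt
#'
#' Damped Gauss--Newton on the residual vector of the training
#' partition.  Each epoch builds the analytic Jacobian, then tries steps
#' `delta = -(J'J + lambda diag(J'J))^{-1} J'r`, escalating `lambda` by
#' `lambda_up` until the training SSE decreases (accepted step:
#' `lambda` divided by `lambda_down`).  Stops at the epoch cap, a small
#' gradient, a stalled validation MSE (`patience`), a relative SSE
#' improvement below `ftol`, or when no step is acceptable.  The weights
#' with the best validation MSE are returned; test MSE and R2 are
#' reported on those weights.
#'
#' Inputs are standardized to `[-1, 1]` per feature over the supplied
#' dataset; the scaling is stored with the model.
#'
#' @param network An `rw_ann_network` from [build_network()].
#' @param data data.frame with columns `temperature_C`, `time_min`, `mr`
#'   (>= 10 rows).
#' @param config A [train_config()].
#' @return Object of class `rw_ann`: trained parameters, scaling,
#'   per-epoch history, epochs used, test `mse` and `r2`, split indices.
#' @export
train_lm <- function(network, data, config = train_config()) {
  stopifnot(inherits(network, "rw_ann_network"),
            inherits(config, "rw_train_config"))
  need <- c("temperature_C", "time_min", "mr")
  if (!all(need %in% names(data)))
    stopf("data needs columns %s", paste(need, collapse = ", "))
  if (nrow(data) < 10) stopf("need at least 10 data points")

  scaling <- list(
    lo = c(min(data$temperature_C), min(data$time_min)),
    hi = c(max(data$temperature_C), max(data$time_min))
  )
  X <- cbind(.standardize(data$temperature_C, scaling$lo[1], scaling$hi[1]),
             .standardize(data$time_min, scaling$lo[2], scaling$hi[2]))
  y <- data$mr
  parts <- .split_indices(data$temperature_C, config$split, config$seed)
  Xtr <- X[parts$train, , drop = FALSE]; ytr <- y[parts$train]
  Xval <- X[parts$validation, , drop = FALSE]; yval <- y[parts$validation]
  Xte <- X[parts$test, , drop = FALSE]; yte <- y[parts$test]

  topo <- network$topology
  par <- network$par
  lambda <- config$lambda_init
  mse_of <- function(p, Xm, ym) mean((ann_forward(network, Xm, p) - ym)^2)

  train_mse <- mse_of(par, Xtr, ytr)
  best_val <- mse_of(par, Xval, yval)
  best_par <- par
  stall <- 0L
  history <- data.frame(epoch = integer(), train_mse = double(),
                        val_mse = double(), lambda = double())
  epoch <- 0L
  stopped <- "max_epochs"

  while (epoch < config$max_epochs) {
    epoch <- epoch + 1L
    r <- ann_forward(network, Xtr, par) - ytr
    J <- ann_jacobian(network, Xtr, par)
    g <- crossprod(J, r)
    if (max(abs(g)) < config$gtol) { stopped <- "gradient"; epoch <- epoch - 1L; break }
    JtJ <- crossprod(J)
    dJ <- pmax(diag(JtJ), 1e-8)
    accepted <- FALSE
    for (try in 1:30) {
      step <- tryCatch(
        solve(JtJ + lambda * diag(dJ, nrow = length(dJ)), -g),
        error = function(e) NULL
      )
      if (!is.null(step)) {
        cand <- par + as.numeric(step)
        cand_mse <- mse_of(cand, Xtr, ytr)
        if (is.finite(cand_mse) && cand_mse < train_mse) {
          improve <- (train_mse - cand_mse) / max(train_mse, 1e-300)
          par <- cand
          train_mse <- cand_mse
          lambda <- lambda / config$lambda_down
          accepted <- TRUE
          if (improve < config$ftol) stopped <- "ftol"
          break
        }
      }
      lambda <- lambda * config$lambda_up
    }
    if (!accepted) { stopped <- "no_step"; epoch <- epoch - 1L; break }

    val_mse <- mse_of(par, Xval, yval)
    history <- rbind(history, data.frame(
      epoch = epoch, train_mse = train_mse, val_mse = val_mse,
      lambda = lambda
    ))
    if (val_mse < best_val * (1 - 1e-12)) {
      best_val <- val_mse; best_par <- par; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) { stopped <- "patience"; break }
    }
    if (stopped == "ftol") break
    if (train_mse < 1e-30) { stopped <- "zero_residual"; break }
  }

  test_pred <- ann_forward(network, Xte, best_par)
  # tiny or zero-variance test partitions get an NA r2, not an error
  met <- if (length(yte) >= 2 && var(yte) > 0)
    evaluate_fit(yte, test_pred) else list(r2 = NA_real_)
  structure(
    list(topology = topo, activations = topo$activations,
         weights = best_par, scaling = scaling, history = history,
         epoch = epoch, stopped = stopped,
         mse = mean((test_pred - yte)^2), r2 = met$r2,
         train_mse = train_mse, val_mse = best_val,
         split = parts, seed = config$seed),
    class = "rw_ann"
  )
}

#' Predict moisture ratio from a trained network
#'
#' @param object An `rw_ann` from [train_lm()].
#' @param newdata data.frame with `temperature_C` and `time_min`.
#' @param ... Unused.
#' @return Predicted moisture ratios.
#' @export
predict.rw_ann <- function(object, newdata, ...) {
  X <- cbind(
    .standardize(newdata$temperature_C, object$scaling$lo[1],
                 object$scaling$hi[1]),
    .standardize(newdata$time_min, object$scaling$lo[2],
                 object$scaling$hi[2])
  )
  net <- list(topology = object$topology, par = object$weights)
  class(net) <- "rw_ann_network"
  ann_forward(net, X)
}

#' @export
print.rw_ann <- function(x, ...) {
  cat(sprintf(
    "<rw_ann> %s (%s) | test MSE = %.3g, R2 = %.5f, epochs = %d (%s)\n",
    format(x$topology), paste(x$activations, collapse = "-"),
    x$mse, x$r2, x$epoch, x$stopped))
  invisible(x)
}

#' Serialize a trained network to JSON
#'
#' Topology, activations, input scaling and the flat weight vector.
#'
#' @param model An `rw_ann`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ann_json <- function(model, path) {
  stopifnot(inherits(model, "rw_ann"))
  jsonlite::write_json(
    list(layer_sizes = model$topology$layer_sizes,
         activations = model$activations,
         scaling = model$scaling, weights = model$weights,
         mse = model$mse, r2 = model$r2, epoch = model$epoch),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a serialized network
#' @param path JSON file written by [write_ann_json()].
#' @return An `rw_ann` (prediction-capable; no training history).
#' @export
read_ann_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  topo <- ann_topology(j$layer_sizes[-c(1, length(j$layer_sizes))],
                       j$activations)
  structure(
    list(topology = topo, activations = j$activations,
         weights = j$weights,
         scaling = list(lo = j$scaling$lo, hi = j$scaling$hi),
         history = NULL, epoch = j$epoch, mse = j$mse, r2 = j$r2),
    class = "rw_ann"
  )
}

#' Topology search over hidden sizes and activation sets
#'
#' Trains one candidate per (hidden size, activation set) with a
#' per-candidate derived seed and ranks candidates by test MSE
#' ascending.  Activation sets of length 2 give one hidden layer of size
#' h; sets of length 3 give two hidden layers of sizes h and h-1
#' (mirroring the 2-15-14-1 pattern).
#'
#' @param data As in [train_lm()].
#' @param hidden_range Hidden sizes to try (default 2:15).
#' @param activation_sets List of activation-name vectors.
#' @param config A [train_config()].
#' @return Object of class `rw_topology_search`: `results` (ranked list
#'   of `rw_ann`, failures recorded as `NULL` with a message) and
#'   `table` (topology, activations, mse, r2, epoch).
#' @export
topology_search <- function(data, hidden_range = 2:15,
                            activation_sets = list(c("tansig", "purelin")),
                            config = train_config()) {
  if (!length(hidden_range) || !length(activation_sets))
    stopf("empty search grid")
  cands <- list()
  for (acts in activation_sets) {
    for (h in hidden_range) {
      hidden <- if (length(acts) == 2) h else c(h, max(h - 1L, 2L))
      cands[[length(cands) + 1L]] <- list(hidden = hidden, acts = acts)
    }
  }
  results <- vector("list", length(cands))
  errors <- character(length(cands))
  for (i in seq_along(cands)) {
    cd <- cands[[i]]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 7L, i)
    net <- build_network(ann_topology(cd$hidden, cd$acts), seed = cfg$seed)
    results[[i]] <- tryCatch(train_lm(net, data, cfg), error = function(e) {
      errors[i] <<- conditionMessage(e); NULL
    })
  }
  ok <- !vapply(results, is.null, TRUE)
  mse <- rep(Inf, length(results))
  mse[ok] <- vapply(results[ok], `[[`, 0, "mse")
  ord <- order(mse)
  tab <- do.call(rbind, lapply(ord, function(i) {
    if (!ok[i]) return(data.frame(
      topology = paste(c(2, cands[[i]]$hidden, 1), collapse = "-"),
      activations = paste(cands[[i]]$acts, collapse = "-"),
      mse = NA_real_, r2 = NA_real_, epoch = NA_integer_,
      error = errors[i]))
    r <- results[[i]]
    data.frame(topology = format(r$topology),
               activations = paste(r$activations, collapse = "-"),
               mse = r$mse, r2 = r$r2, epoch = r$epoch, error = "")
  }))
  structure(list(results = results[ord], table = tab),
            class = "rw_topology_search")
}

#' Compare a trained network with a kinetic model fit
#'
#' Evaluates both on the same series and reports side-by-side MSE and
#' R2, flagging the winner by lower MSE (or an explicit tie).
#'
#' @param ann An `rw_ann`.
#' @param kinetic An `rw_model_fit`.
#' @param data data.frame with `temperature_C`, `time_min`, `mr`; when
#'   the kinetic fit carries a temperature, the data must be at that
#'   temperature.
#' @return Object of class `rw_comparison` with a two-row `table` and
#'   `winner` (`"ann"`, `"kinetic"`, or `"tie"`).
#' @export
compare_models <- function(ann, kinetic, data) {
  stopifnot(inherits(ann, "rw_ann"), inherits(kinetic, "rw_model_fit"))
  if (!is.null(kinetic$temperature_C) && !is.na(kinetic$temperature_C) &&
      !all(data$temperature_C == kinetic$temperature_C))
    stopf("evaluation set temperatures do not match the kinetic fit")
  pa <- predict(ann, data)
  pk <- predict(kinetic, data$time_min)
  ma <- evaluate_fit(data$mr, pa); mk <- evaluate_fit(data$mr, pk)
  mse_a <- mean((pa - data$mr)^2); mse_k <- mean((pk - data$mr)^2)
  winner <- if (isTRUE(all.equal(mse_a, mse_k))) "tie"
            else if (mse_a < mse_k) "ann" else "kinetic"
  structure(
    list(table = data.frame(
           model = c("ann", kinetic$model_name),
           mse = c(mse_a, mse_k), r2 = c(ma$r2, mk$r2)),
         winner = winner),
    class = "rw_comparison"
  )
}

#' @export
print.rw_comparison <- function(x, ...) {
  print(x$table)
  cat("winner:", x$winner, "\n")
  invisible(x)
}
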