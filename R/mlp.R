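# Small fully-connected tanh network used for region classification.
# Architecture fixed by the method: 5 inputs -> 10 -> 3 hidden units ->
# 2 outputs, all with tangent-sigmoid transfer. The two outputs carry a
# 2-bit class code: C1 = (+1, -1), C2 = (-1, +1), C3 = (-1, -1).

CLASS_CODES <- matrix(c(1, -1,
                        -1, 1,
                        -1, -1), nrow = 3, byrow = TRUE,
                      dimnames = list(c("C1", "C2", "C3"), NULL))

mlp_sizes <- c(5L, 10L, 3L, 2L)

mlp_npar <- function(sizes = mlp_sizes) {
  sum(sizes[-length(sizes)] * sizes[-1]) + sum(sizes[-1])
}

mlp_unpack <- function(par, sizes = mlp_sizes) {
  w <- list(); b <- list(); pos <- 0L
  for (l in seq_len(length(sizes) - 1L)) {
    nin <- sizes[l]; nout <- sizes[l + 1L]
    w[[l]] <- matrix(par[pos + seq_len(nin * nout)], nin, nout)
    pos <- pos + nin * nout
    b[[l]] <- par[pos + seq_len(nout)]
    pos <- pos + nout
  }
  list(w = w, b = b)
}

mlp_forward <- function(wb, X) {
  a <- list(X)
  for (l in seq_along(wb$w)) {
    z <- sweep(a[[l]] %*% wb$w[[l]], 2L, wb$b[[l]], "+")
    a[[l + 1L]] <- tanh(z)
  }
  a
}

# mean squared error over the 2-unit code and its analytic gradient
mlp_loss_grad <- function(par, X, Y, sizes = mlp_sizes) {
  wb <- mlp_unpack(par, sizes)
  a <- mlp_forward(wb, X)
  L <- length(wb$w)
  out <- a[[L + 1L]]
  n <- nrow(X)
  err <- out - Y
  loss <- mean(err^2)
  # backprop through tanh layers
  delta <- (2 / (n * ncol(Y))) * err * (1 - out^2)
  gw <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gw[[l]] <- crossprod(a[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) delta <- (delta %*% t(wb$w[[l]])) * (1 - a[[l]]^2)
  }
  grad <- unlist(mapply(function(w, b) c(as.vector(w), b), gw, gb,
                        SIMPLIFY = FALSE))
  list(loss = loss, grad = grad)
}

mlp_train <- function(X, Y, seed = 1L, maxit = 600L, n_starts = 3L) {
  orng <- save_rng(); on.exit(restore_rng(orng), add = TRUE)
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    par0 <- stats::runif(mlp_npar(), -0.5, 0.5)
    fit <- stats::optim(par0,
                        fn = function(p) mlp_loss_grad(p, X, Y)$loss,
                        gr = function(p) mlp_loss_grad(p, X, Y)$grad,
                        method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best$par
}

mlp_predict_codes <- function(par, X) {
  wb <- mlp_unpack(par)
  a <- mlp_forward(wb, X)
  a[[length(a)]]
}
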