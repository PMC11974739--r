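## Minimal recurrent network primitives with hand-written gradients.
## Everything operates on batches as (batch x dim) matrices; sequences are
## lists of such matrices (one per time bin), which avoids repeated 3-d
## array slicing in the time loops. Gradients are exact (verified against
## central finite differences in the test suite).

sigmoid <- function(x) 1 / (1 + exp(-x))

## GRU parameters; gate column order within the 3H blocks is [r | z | n].
## Update rule (input bias and hidden bias kept separate so the candidate
## gate matches the standard formulation
##   n = tanh(Wn x + b_in_n + r * (Un h + b_hid_n)) ):
gru_init <- function(in_dim, hid, gain = 1) {
  s_in <- gain / sqrt(max(in_dim, 1))
  s_h <- gain / sqrt(hid)
  list(
    W = matrix(stats::rnorm(in_dim * 3 * hid, sd = s_in), in_dim, 3 * hid),
    U = matrix(stats::rnorm(hid * 3 * hid, sd = s_h), hid, 3 * hid),
    b_in = numeric(3 * hid),
    b_hid = numeric(3 * hid)
  )
}

gru_forward <- function(X, h0, p) {
  Tn <- length(X)
  H <- ncol(h0)
  ri <- seq_len(H); zi <- H + ri; ni <- 2 * H + ri
  h <- h0
  Hs <- vector("list", Tn)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    gx <- sweep(X[[t]] %*% p$W, 2, p$b_in, "+")
    gh <- sweep(h %*% p$U, 2, p$b_hid, "+")
    r <- sigmoid(gx[, ri, drop = FALSE] + gh[, ri, drop = FALSE])
    z <- sigmoid(gx[, zi, drop = FALSE] + gh[, zi, drop = FALSE])
    ghn <- gh[, ni, drop = FALSE]
    n <- tanh(gx[, ni, drop = FALSE] + r * ghn)
    h_new <- (1 - z) * n + z * h
    cache[[t]] <- list(x = X[[t]], h_prev = h, r = r, z = z, n = n,
                       ghn = ghn)
    h <- h_new
    Hs[[t]] <- h
  }
  list(H = Hs, cache = cache)
}

## dH: list of gradients w.r.t. each output state h_t (may contain NULLs).
## Returns gradients for inputs, initial state and parameters.
gru_backward <- function(dH, cache, p, want_dx = TRUE) {
  Tn <- length(cache)
  H <- ncol(cache[[1]]$h_prev)
  dW <- 0 * p$W; dU <- 0 * p$U
  db_in <- 0 * p$b_in; db_hid <- 0 * p$b_hid
  dh <- NULL
  dX <- if (want_dx) vector("list", Tn) else NULL
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    g <- dH[[t]]
    dh <- if (is.null(dh)) g else if (is.null(g)) dh else dh + g
    if (is.null(dh)) next
    dz <- dh * (cc$h_prev - cc$n)
    dn <- dh * (1 - cc$z)
    dh_prev <- dh * cc$z
    dpre_n <- dn * (1 - cc$n^2)
    dr <- dpre_n * cc$ghn
    dghn <- dpre_n * cc$r
    dpre_r <- dr * cc$r * (1 - cc$r)
    dpre_z <- dz * cc$z * (1 - cc$z)
    dgx <- cbind(dpre_r, dpre_z, dpre_n)
    dgh <- cbind(dpre_r, dpre_z, dghn)
    dW <- dW + crossprod(cc$x, dgx)
    db_in <- db_in + colSums(dgx)
    dU <- dU + crossprod(cc$h_prev, dgh)
    db_hid <- db_hid + colSums(dgh)
    if (want_dx) dX[[t]] <- dgx %*% t(p$W)
    dh <- dh_prev + dgh %*% t(p$U)
  }
  list(dX = dX, dh0 = dh,
       grads = list(W = dW, U = dU, b_in = db_in, b_hid = db_hid))
}

linear_init <- function(in_dim, out_dim, scale = NULL) {
  s <- scale %||% (1 / sqrt(max(in_dim, 1)))
  list(W = matrix(stats::rnorm(in_dim * out_dim, sd = s), in_dim, out_dim),
       b = numeric(out_dim))
}

linear_forward <- function(x, p) sweep(x %*% p$W, 2, p$b, "+")

linear_backward <- function(x, dy, p) {
  list(dx = dy %*% t(p$W),
       grads = list(W = crossprod(x, dy), b = colSums(dy)))
}

## --- nested parameter-list utilities (shared by Adam and grad checks) ---

param_map <- function(f, a) {
  if (is.list(a)) return(lapply(a, function(x) param_map(f, x)))
  f(a)
}

param_map2 <- function(f, a, b) {
  if (is.list(a)) {
    return(mapply(function(x, y) param_map2(f, x, y), a, b, SIMPLIFY = FALSE))
  }
  f(a, b)
}

param_zeros <- function(a) param_map(function(x) x * 0, a)

param_unlist <- function(a) unlist(a, use.names = FALSE)

param_relist <- function(v, skeleton) {
  out <- skeleton
  i <- 0L
  walk <- function(a) {
    if (is.list(a)) return(lapply(a, walk))
    k <- length(a)
    val <- v[(i + 1L):(i + k)]
    i <<- i + k
    if (is.matrix(a)) matrix(val, nrow(a), ncol(a)) else val
  }
  walk(out)
}

## Adam with global gradient-norm clipping; state carries first/second
## moments and the step counter.
adam_init <- function(params) {
  list(m = param_zeros(params), v = param_zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 200) {
  gn <- sqrt(sum(param_unlist(grads)^2))
  if (is.finite(clip) && gn > clip) {
    grads <- param_map(function(g) g * (clip / gn), grads)
  }
  state$t <- state$t + 1L
  state$m <- param_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- param_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- param_map2(function(m, v) (m / corr1) / (sqrt(v / corr2) + eps),
                    state$m, state$v)
  params <- param_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, state = state, grad_norm = gn)
}

## array (B x T x D) <-> list-of-matrices converters
seq_to_list <- function(a) {
  d <- dim(a)
  lapply(seq_len(d[2]), function(t) array(a[, t, ], dim = d[c(1, 3)]))
}

list_to_seq <- function(lst) {
  B <- nrow(lst[[1]]); D <- ncol(lst[[1]])
  a <- array(0, dim = c(B, length(lst), D))
  for (t in seq_along(lst)) a[, t, ] <- lst[[t]]
  a
}
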