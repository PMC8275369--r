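# Independent reference implementation of the classifier forward pass,
# written as direct nested-loop evaluation of the layer definitions
# (correlation sums, channel gates, max windows).  Used as the oracle for
# the compiled forward pass and, via activation overrides, for
# finite-difference checks of the Grad-CAM gradients.

ref_relu <- function(m) pmax(m, 0)
ref_sig <- function(z) 1 / (1 + exp(-z))

# SE gate on a list (per filter) of activation maps
ref_se <- function(params, l, Alist) {
  z <- vapply(Alist, mean, 0)
  h <- ref_relu(params[[paste0("se", l, "_Wr")]] %*% z +
                  params[[paste0("se", l, "_br")]])
  s <- ref_sig(params[[paste0("se", l, "_We")]] %*% h +
                 params[[paste0("se", l, "_be")]])
  lapply(seq_along(Alist), function(k) Alist[[k]] * s[k])
}

# Forward pass from a 5 x W input matrix.  If override_layer is in 1..7 the
# post-ReLU activation of that conv layer is replaced by override_A before
# continuing (layer 1: list of nf 5 x W matrices; layers 2-7: W/4 x nf
# matrix).  Returns logit plus all post-ReLU conv activations.
ref_forward <- function(params, X, override_layer = 0L, override_A = NULL) {
  nf <- ncol(params$conv1_W)
  W <- ncol(X); W1p <- W %/% 4L; W2p <- W1p %/% 4L
  # conv1: 2D 5x10 cross-correlation, same padding
  A1 <- vector("list", nf)
  for (k in seq_len(nf)) {
    M <- matrix(0, 5, W)
    for (r in 1:5) for (cc in seq_len(W)) {
      acc <- params$conv1_b[k, 1]
      for (dr in -2:2) for (dc in -4:5) {
        rr <- r + dr; c2 <- cc + dc
        if (rr >= 1 && rr <= 5 && c2 >= 1 && c2 <= W)
          acc <- acc + params$conv1_W[(dr + 2) * 10 + (dc + 4) + 1, k] * X[rr, c2]
      }
      M[r, cc] <- acc
    }
    A1[[k]] <- ref_relu(M)
  }
  if (override_layer == 1L) A1 <- override_A
  U1 <- ref_se(params, 1L, A1)
  P1 <- lapply(U1, function(M) {
    out <- matrix(0, 5, W1p)
    for (r in 1:5) for (cc in seq_len(W1p))
      out[r, cc] <- max(M[r, (4 * cc - 3):(4 * cc)])
    out
  })
  # conv2: 2D 5x10 over all filters, valid height, same width
  A2 <- matrix(0, W1p, nf)
  for (k in seq_len(nf)) for (cc in seq_len(W1p)) {
    acc <- params$conv2_b[k, 1]
    for (k2 in seq_len(nf)) for (r in 1:5) for (dc in -4:5) {
      c2 <- cc + dc
      if (c2 >= 1 && c2 <= W1p)
        acc <- acc + params$conv2_W[((k2 - 1) * 5 + (r - 1)) * 10 + (dc + 4) + 1, k] *
          P1[[k2]][r, c2]
    }
    A2[cc, k] <- acc
  }
  A2 <- ref_relu(A2)
  if (override_layer == 2L) A2 <- override_A
  acts <- list(A2)
  cur <- A2
  for (l in 3:7) {
    Ulist <- ref_se(params, l - 1L, lapply(seq_len(nf), function(k) cur[, k]))
    An <- matrix(0, W1p, nf)
    for (k in seq_len(nf)) for (cc in seq_len(W1p)) {
      acc <- params[[paste0("conv", l, "_b")]][k, 1]
      for (k2 in seq_len(nf)) for (dc in -1:2) {
        c2 <- cc + dc
        if (c2 >= 1 && c2 <= W1p)
          acc <- acc + params[[paste0("conv", l, "_W")]][(k2 - 1) * 4 + (dc + 1) + 1, k] *
            Ulist[[k2]][c2]
      }
      An[cc, k] <- acc
    }
    An <- ref_relu(An)
    if (override_layer == l) An <- override_A
    acts[[l - 1L]] <- An
    cur <- An
  }
  # pool2 + flatten (filter-major) + dense head
  f <- numeric(nf * W2p)
  for (k in seq_len(nf)) for (cc in seq_len(W2p))
    f[(k - 1) * W2p + cc] <- max(cur[(4 * cc - 3):(4 * cc), k])
  h1 <- ref_relu(t(params$dense1_W) %*% f + params$dense1_b)
  logit <- sum(params$dense2_w * h1) + params$dense2_b[1, 1]
  list(logit = as.numeric(logit), prob = ref_sig(as.numeric(logit)),
       A1 = A1, acts = acts)
}

# central finite-difference gradient of the logit w.r.t. every entry of the
# post-ReLU activation at `layer`, using the reference forward pass
ref_fd_actgrad <- function(params, X, layer, eps = 1e-4) {
  base <- ref_forward(params, X)
  if (layer == 1L) {
    A <- base$A1
    G <- lapply(A, function(m) matrix(0, nrow(m), ncol(m)))
    for (k in seq_along(A)) for (i in seq_along(A[[k]])) {
      up <- A; up[[k]][i] <- up[[k]][i] + eps
      dn <- A; dn[[k]][i] <- dn[[k]][i] - eps
      G[[k]][i] <- (ref_forward(params, X, 1L, up)$logit -
                      ref_forward(params, X, 1L, dn)$logit) / (2 * eps)
    }
    return(G)
  }
  A <- base$acts[[layer - 1L]]
  G <- matrix(0, nrow(A), ncol(A))
  for (i in seq_along(A)) {
    up <- A; up[i] <- up[i] + eps
    dn <- A; dn[i] <- dn[i] - eps
    G[i] <- (ref_forward(params, X, layer, up)$logit -
               ref_forward(params, X, layer, dn)$logit) / (2 * eps)
  }
  G
}

# Small random model + strictly positive random input for backend checks.
# Conv biases are shifted positive so activations are generically nonzero:
# exact zeros from ReLU create ties inside max-pool windows, where a
# finite-difference probe is not a valid derivative.
ref_toy_model <- function(nf = 4L, width = 20L, seed = 42L) {
  model <- build_model(model_config(n_filters = nf, dense_units = 8L,
                                    width = width), seed = seed)
  for (nm in grep("^conv[0-9]+_b$", names(model$params), value = TRUE))
    model$params[[nm]] <- model$params[[nm]] + 0.3
  x <- withr::with_seed(seed + 1L, matrix(abs(rnorm(5 * width, sd = 1)), 5, width))
  # lift the biases of the two pooled layers (1 and 7) until their
  # activations are strictly positive, so every max-pool argmax is unique
  for (probe in 1:2) {
    rf <- ref_forward(model$params, x)
    m1 <- min(unlist(lapply(rf$A1, min)))
    if (m1 <= 0) model$params$conv1_b <- model$params$conv1_b + (0.05 - pre_min(model, x, 1L))
    m7 <- min(rf$acts[[6]])
    if (m7 <= 0) model$params$conv7_b <- model$params$conv7_b + (0.05 - pre_min(model, x, 7L))
  }
  list(model = model, x = x)
}

# minimum pre-ReLU activation of conv layer l, recovered by running the
# forward pass with a large temporary bias offset
pre_min <- function(model, x, l) {
  shift <- 100
  p <- model$params
  nm <- paste0("conv", l, "_b")
  p[[nm]] <- p[[nm]] + shift
  rf <- ref_forward(p, x)
  if (l == 1L) min(unlist(lapply(rf$A1, min))) - shift
  else min(rf$acts[[l - 1L]]) - shift
}
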