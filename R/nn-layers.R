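# Parameter-holding layers (environments) and the AdamW update.
# Weight init is Kaiming-uniform (fan-in), seeded by the caller.

kaiming_u <- function(n, fan_in) {
  bound <- sqrt(6 / max(1, fan_in))
  runif(n, -bound, bound)
}

layer_conv <- function(kh, kw, cin, cout, stride = 1L, dilation = 1L,
                       groups = 1L, bias = TRUE) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- "conv"
  ly$stride <- as.integer(stride)
  ly$dilation <- as.integer(dilation)
  ly$groups <- as.integer(groups)
  cin_g <- cin %/% groups
  fan_in <- kh * kw * cin_g
  ly$W <- array(kaiming_u(kh * kw * cin_g * cout, fan_in), c(kh, kw, cin_g, cout))
  ly$b <- if (bias) numeric(cout) else NULL
  ly$gW <- array(0, dim(ly$W))
  ly$gb <- numeric(cout)
  ly$param_names <- if (bias) c("W", "b") else "W"
  ly
}

layer_bn <- function(c) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- "bn"
  ly$gamma <- rep(1, c)
  ly$beta <- numeric(c)
  ly$rm <- numeric(c)
  ly$rv <- rep(1, c)
  ly$ggamma <- numeric(c)
  ly$gbeta <- numeric(c)
  ly$param_names <- c("gamma", "beta")
  ly
}

layer_fc <- function(fin, fout, bias_init = 0) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- "fc"
  ly$W <- matrix(kaiming_u(fin * fout, fin), fin, fout)
  ly$b <- rep(bias_init, fout)
  ly$gW <- matrix(0, fin, fout)
  ly$gb <- numeric(fout)
  ly$param_names <- c("W", "b")
  ly
}

grad_name <- function(p) {
  switch(p, W = "gW", b = "gb", gamma = "ggamma", beta = "gbeta")
}

zero_grads <- function(net) {
  for (ly in net$layers) {
    for (p in ly$param_names) {
      gp <- grad_name(p)
      ly[[gp]] <- ly[[gp]] * 0
    }
  }
  invisible(net)
}

n_params_layer <- function(ly) {
  sum(vapply(ly$param_names, function(p) length(ly[[p]]), numeric(1)))
}

# realized trainable-parameter count of a network (the framework's own count)
net_n_params <- function(net) {
  sum(vapply(net$layers, n_params_layer, numeric(1)))
}

# snapshot / restore of all parameters AND batch-norm running stats
net_state_get <- function(net) {
  lapply(net$layers, function(ly) {
    fields <- c(ly$param_names, intersect(c("rm", "rv"), ls(ly)))
    setNames(lapply(fields, function(f) ly[[f]]), fields)
  })
}

net_state_set <- function(net, state) {
  for (i in seq_along(net$layers)) {
    for (f in names(state[[i]])) net$layers[[i]][[f]] <- state[[i]][[f]]
  }
  invisible(net)
}

adamw_state <- function(net) {
  lapply(net$layers, function(ly) {
    st <- list()
    for (p in ly$param_names) {
      st[[p]] <- list(m = ly[[p]] * 0, v = ly[[p]] * 0)
    }
    st
  })
}

# decoupled weight decay (AdamW): decay applied directly to the weights,
# not through the adaptive moments; BN parameters and biases are not decayed
adamw_step <- function(net, opt, lr, weight_decay, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    for (p in ly$param_names) {
      g <- ly[[grad_name(p)]]
      st <- opt[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      opt[[i]][[p]] <- st
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      upd <- lr * mhat / (sqrt(vhat) + eps)
      decay <- if (p == "W" && ly$kind != "bn") lr * weight_decay * ly[[p]] else 0
      ly[[p]] <- ly[[p]] - upd - decay
    }
  }
  opt
}
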