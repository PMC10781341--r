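# Layer constructors. A layer is a plain list carrying its ad_param objects
# plus static hyperparameters; forward helpers take (layer, x, training).
# Parameters are discovered by recursively walking the model list, so any
# nesting of layers inside blocks inside the model works unchanged.

he_init <- function(fan_in, n) rnorm(n, sd = sqrt(2 / fan_in))

layer_conv <- function(kh, kw, cin, cout, stride = 1L, pad = 0L, dil = 1L,
                       bias = FALSE) {
  w <- array(he_init(kh * kw * cin, kh * kw * cin * cout),
             dim = c(kh, kw, cin, cout))
  list(
    kind = "conv",
    w = ad_param(w),
    b = if (bias) ad_param(numeric(cout)) else NULL,
    stride = as.integer(stride), pad = as.integer(pad), dil = as.integer(dil)
  )
}

fwd_conv <- function(ly, x) {
  op_conv2d(x, ly$w, ly$b, ly$stride, ly$pad, ly$dil)
}

layer_bn2d <- function(c) {
  run <- new.env(parent = emptyenv())
  run$mean <- numeric(c)
  run$var <- rep(1, c)
  list(kind = "bn2d", gamma = ad_param(rep(1, c)), beta = ad_param(numeric(c)),
       running = run)
}

fwd_bn2d <- function(ly, x, training) {
  op_bn2d(x, ly$gamma, ly$beta, ly$running, training)
}

layer_bn1d <- function(f) {
  run <- new.env(parent = emptyenv())
  run$mean <- numeric(f)
  run$var <- rep(1, f)
  list(kind = "bn1d", gamma = ad_param(rep(1, f)), beta = ad_param(numeric(f)),
       running = run)
}

fwd_bn1d <- function(ly, x, training) {
  op_bn1d(x, ly$gamma, ly$beta, ly$running, training)
}

layer_linear <- function(fin, fout, bias = TRUE) {
  list(kind = "linear",
       w = ad_param(matrix(he_init(fin, fin * fout), fout, fin)),
       b = if (bias) ad_param(numeric(fout)) else NULL)
}

fwd_linear <- function(ly, x) op_linear(x, ly$w, ly$b)

# Bconv: convolution -> batch normalization -> ReLU.
layer_bconv <- function(kh, kw, cin, cout, stride = 1L, pad = 0L, dil = 1L) {
  list(kind = "bconv",
       conv = layer_conv(kh, kw, cin, cout, stride, pad, dil, bias = FALSE),
       bn = layer_bn2d(cout))
}

fwd_bconv <- function(ly, x, training) {
  op_relu(fwd_bn2d(ly$bn, fwd_conv(ly$conv, x), training))
}

# Recursively collect every ad_param in a nested layer/model structure.
collect_params <- function(obj) {
  if (inherits(obj, "ad_param")) return(list(obj))
  if (is.list(obj) && !is.function(obj)) {
    out <- list()
    for (el in obj) {
      if (is.null(el) || is.function(el)) next
      if (inherits(el, "ad_param")) {
        out <- c(out, list(el))
      } else if (is.list(el)) {
        out <- c(out, collect_params(el))
      }
    }
    return(out)
  }
  list()
}

# Snapshot / restore all numeric state (parameters + batch-norm running
# statistics) of a nested structure, for checkpointing.
collect_state <- function(obj, path = "") {
  out <- list()
  if (inherits(obj, "ad_param")) {
    out[[path]] <- obj$value
    return(out)
  }
  if (is.environment(obj) && !is.null(obj$mean)) {
    out[[paste0(path, ".mean")]] <- obj$mean
    out[[paste0(path, ".var")]] <- obj$var
    return(out)
  }
  if (is.list(obj) && !is.function(obj)) {
    nm <- names(obj)
    for (i in seq_along(obj)) {
      el <- obj[[i]]
      if (is.null(el) || is.function(el)) next
      key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
      out <- c(out, collect_state(el, paste0(path, "/", key)))
    }
  }
  out
}

restore_state <- function(obj, state, path = "") {
  if (inherits(obj, "ad_param")) {
    v <- state[[path]]
    if (is.null(v)) stop("checkpoint is missing parameter ", path)
    obj$value[] <- v
    return(invisible(NULL))
  }
  if (is.environment(obj) && !is.null(obj$mean)) {
    obj$mean <- state[[paste0(path, ".mean")]]
    obj$var <- state[[paste0(path, ".var")]]
    return(invisible(NULL))
  }
  if (is.list(obj) && !is.function(obj)) {
    nm <- names(obj)
    for (i in seq_along(obj)) {
      el <- obj[[i]]
      if (is.null(el) || is.function(el)) next
      key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
      restore_state(el, state, paste0(path, "/", key))
    }
  }
  invisible(NULL)
}
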