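# Small convolutional-network engine backing the segmenter and classifier.
# Activations are numeric arrays dim = c(H, W, C); heavy kernels live in
# src/nn_kernels.cpp. Training is plain per-sample SGD with momentum and a
# per-epoch multiplicative learning-rate decay. All weight initialisation and
# dropout draws come from R's RNG, so seeding makes runs reproducible.

he_init <- function(n_out, n_in_eff, n) {
  matrix(rnorm(n, sd = sqrt(2 / n_in_eff)), nrow = n_out)
}

nn_conv <- function(k, cin, cout) {
  list(type = "conv", k = k, cin = cin, cout = cout,
       w = he_init(cout, k * k * cin, cout * k * k * cin),
       b = numeric(cout))
}

nn_relu <- function() list(type = "relu")

nn_pool <- function() list(type = "pool")

nn_dropout <- function(rate) list(type = "dropout", rate = rate)

# Two parallel branches (1x1 and 3x3 convolutions) concatenated along the
# channel axis — a miniature inception module.
nn_inception <- function(cin, cout1, cout3) {
  list(type = "inception", cin = cin, cout1 = cout1, cout3 = cout3,
       w1 = he_init(cout1, cin, cout1 * cin), b1 = numeric(cout1),
       w3 = he_init(cout3, 9 * cin, cout3 * 9 * cin), b3 = numeric(cout3))
}

nn_tconv <- function(k, stride, pad, cin, cout) {
  n <- k * k * cin * cout
  list(type = "tconv", k = k, s = stride, p = pad, cin = cin, cout = cout,
       w = rnorm(n, sd = sqrt(2 / (k * k * cin))), b = numeric(cout))
}

nn_gap <- function() list(type = "gap")

# Global average + max pooling concatenated: output length 2C. Mean features
# summarise diffuse appearance; max features flag small salient lesions.
nn_gpool <- function() list(type = "gpool")

nn_dense <- function(cin, cout) {
  list(type = "dense", cin = cin, cout = cout,
       w = he_init(cout, cin, cout * cin), b = numeric(cout))
}

nn_net <- function(layers) {
  structure(list(layers = layers, velocity = NULL), class = "segassist_net")
}

nn_forward <- function(net, x, train = FALSE) {
  caches <- vector("list", length(net$layers))
  for (li in seq_along(net$layers)) {
    l <- net$layers[[li]]
    cache <- switch(
      l$type,
      conv = {
        y <- conv2d_fw(x, l$w, l$b, l$k)
        list(x = x)
      },
      relu = {
        y <- pmax(x, 0)
        list(mask = x > 0)
      },
      pool = {
        r <- maxpool2_fw(x)
        y <- r$y
        list(idx = r$idx, H = dim(x)[1], W = dim(x)[2])
      },
      dropout = {
        if (train && l$rate > 0) {
          m <- array(rbinom(length(x), 1L, 1 - l$rate) / (1 - l$rate), dim(x))
          y <- x * m
          list(mask = m)
        } else {
          y <- x
          list(mask = NULL)
        }
      },
      inception = {
        y1 <- conv2d_fw(x, l$w1, l$b1, 1L)
        y3 <- conv2d_fw(x, l$w3, l$b3, 3L)
        d <- dim(x)
        y <- array(c(y1, y3), c(d[1], d[2], l$cout1 + l$cout3))
        list(x = x)
      },
      tconv = {
        y <- tconv_fw(x, l$w, l$b, l$k, l$s, l$p, l$cout)
        list(x = x)
      },
      gap = {
        y <- apply(x, 3, mean)
        list(dim = dim(x))
      },
      gpool = {
        mns <- apply(x, 3, mean)
        mxs <- apply(x, 3, max)
        amx <- apply(x, 3, which.max)
        y <- c(mns, mxs)
        list(dim = dim(x), argmax = amx)
      },
      dense = {
        y <- drop(l$w %*% x) + l$b
        list(x = x)
      },
      abort(paste("unknown layer type:", l$type))
    )
    caches[[li]] <- cache
    x <- y
  }
  list(out = x, caches = caches)
}

nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  g <- dout
  for (li in rev(seq_along(net$layers))) {
    l <- net$layers[[li]]
    cc <- caches[[li]]
    res <- switch(
      l$type,
      conv = {
        bw <- conv2d_bw(cc$x, l$w, g, l$k)
        grads[[li]] <- list(w = bw$dw, b = as.numeric(bw$db))
        bw$dx
      },
      relu = g * cc$mask,
      pool = maxpool2_bw(g, cc$idx, cc$H, cc$W),
      dropout = if (is.null(cc$mask)) g else g * cc$mask,
      inception = {
        d <- dim(g)
        g1 <- array(g[, , seq_len(l$cout1)], c(d[1], d[2], l$cout1))
        g3 <- array(g[, , l$cout1 + seq_len(l$cout3)], c(d[1], d[2], l$cout3))
        bw1 <- conv2d_bw(cc$x, l$w1, g1, 1L)
        bw3 <- conv2d_bw(cc$x, l$w3, g3, 3L)
        grads[[li]] <- list(w1 = bw1$dw, b1 = as.numeric(bw1$db),
                            w3 = bw3$dw, b3 = as.numeric(bw3$db))
        bw1$dx + bw3$dx
      },
      tconv = {
        bw <- tconv_bw(cc$x, l$w, g, l$k, l$s, l$p, l$cout)
        grads[[li]] <- list(w = as.numeric(bw$dw), b = as.numeric(bw$db))
        bw$dx
      },
      gap = {
        d <- cc$dim
        gg <- array(0, d)
        for (c in seq_len(d[3])) gg[, , c] <- g[c] / (d[1] * d[2])
        gg
      },
      gpool = {
        d <- cc$dim
        C <- d[3]
        gg <- array(0, d)
        plane <- d[1] * d[2]
        for (c in seq_len(C)) {
          gg[, , c] <- g[c] / plane
          gg[(c - 1) * plane + cc$argmax[c]] <- gg[(c - 1) * plane + cc$argmax[c]] + g[C + c]
        }
        gg
      },
      dense = {
        grads[[li]] <- list(w = outer(g, cc$x), b = g)
        as.numeric(crossprod(l$w, g))
      }
    )
    g <- res
  }
  grads
}

nn_param_names <- function(l) {
  switch(l$type,
         conv = c("w", "b"), tconv = c("w", "b"), dense = c("w", "b"),
         inception = c("w1", "b1", "w3", "b3"),
         character(0))
}

nn_sgd_step <- function(net, grads, lr, momentum = 0.9) {
  if (is.null(net$velocity)) {
    net$velocity <- lapply(net$layers, function(l) {
      pn <- nn_param_names(l)
      setNames(lapply(pn, function(p) l[[p]] * 0), pn)
    })
  }
  for (li in seq_along(net$layers)) {
    pn <- nn_param_names(net$layers[[li]])
    for (p in pn) {
      v <- momentum * net$velocity[[li]][[p]] - lr * grads[[li]][[p]]
      net$velocity[[li]][[p]] <- v
      net$layers[[li]][[p]] <- net$layers[[li]][[p]] + v
    }
  }
  net
}

# Inventory of trainable parameters: tibble(layer, param, n, dims).
nn_param_inventory <- function(net) {
  rows <- purrr::imap(net$layers, function(l, li) {
    pn <- nn_param_names(l)
    purrr::map(pn, function(p) {
      tibble::tibble(layer = li, type = l$type, param = p,
                     n = length(l[[p]]),
                     dims = paste(dim(l[[p]]) %||% length(l[[p]]),
                                  collapse = "x"))
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Per-pixel softmax over the channel axis of an H x W x C score array.
softmax_pixelwise <- function(scores) {
  m <- apply(scores, c(1, 2), max)
  e <- exp(sweep(scores, c(1, 2), m))
  sweep(e, c(1, 2), apply(e, c(1, 2), sum), "/")
}

accumulate_grads <- function(acc, grads) {
  if (is.null(acc)) return(grads)
  for (li in seq_along(grads)) {
    for (pn in names(grads[[li]])) {
      acc[[li]][[pn]] <- acc[[li]][[pn]] + grads[[li]][[pn]]
    }
  }
  acc
}

scale_grads <- function(grads, n) {
  if (n == 1) return(grads)
  for (li in seq_along(grads)) {
    for (pn in names(grads[[li]])) grads[[li]][[pn]] <- grads[[li]][[pn]] / n
  }
  grads
}
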