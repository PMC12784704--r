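## Convolution and feature-map operators on the internal (h, w, c, n) layout.
##
## Convolution uses shifted-slice im2col: the padded input is sliced once per
## kernel tap, giving a (ho*wo*n) x (cin_g*k^2) matrix multiplied against the
## reshaped kernel with BLAS.  Depthwise convolutions take a cheaper
## multiply-accumulate path with no matrix build.

pad_hw <- function(x, p, value = 0) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(value, dim = c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L], d[4L]))
  xp[p + seq_len(d[1L]), p + seq_len(d[2L]), , ] <- x
  xp
}

conv_out_len <- function(l, k, s, p, d) (l + 2L * p - d * (k - 1L) - 1L) %/% s + 1L

## x: (h,w,cin,n); w: (k,k,cin/groups,cout); b: length cout or NULL
op_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, dilation = 1L, groups = 1L) {
  x <- as_ag(x); w <- as_ag(w)
  if (!is.null(b)) b <- as_ag(b)
  d <- dim(x$v); h <- d[1L]; wd <- d[2L]; cin <- d[3L]; n <- d[4L]
  kd <- dim(w$v); k <- kd[1L]; cing <- kd[3L]; cout <- kd[4L]
  stopifnot(k == kd[2L], cin == cing * groups, cout %% groups == 0L)
  ho <- conv_out_len(h, k, stride, pad, dilation)
  wo <- conv_out_len(wd, k, stride, pad, dilation)
  stopifnot(ho >= 1L, wo >= 1L)
  xp <- pad_hw(x$v, pad)

  if (groups == cin && cout == cin && cing == 1L) {
    ## depthwise fast path
    out <- array(0, dim = c(ho, wo, cout, n))
    ri0 <- vector("list", k); rj0 <- vector("list", k)
    for (kk in seq_len(k)) {
      ri0[[kk]] <- seq.int(1L + (kk - 1L) * dilation, by = stride, length.out = ho)
      rj0[[kk]] <- seq.int(1L + (kk - 1L) * dilation, by = stride, length.out = wo)
    }
    for (kj in seq_len(k)) for (ki in seq_len(k)) {
      wv <- w$v[ki, kj, 1L, ]
      out <- out + xp[ri0[[ki]], rj0[[kj]], , , drop = FALSE] * rep(wv, each = ho * wo)
    }
    if (!is.null(b)) out <- out + rep(b$v, each = ho * wo)
    parents <- c(list(x, w), if (!is.null(b)) list(b))
    return(new_ag(out, parents, function(g) {
      dxp <- array(0, dim = dim(xp))
      dw <- array(0, dim = dim(w$v))
      for (kj in seq_len(k)) for (ki in seq_len(k)) {
        xs <- xp[ri0[[ki]], rj0[[kj]], , , drop = FALSE]
        s1 <- colSums(matrix(g * xs, ho * wo))        # length cout*n
        dw[ki, kj, 1L, ] <- rowSums(matrix(s1, cout, n))
        wv <- w$v[ki, kj, 1L, ]
        dxp[ri0[[ki]], rj0[[kj]], , ] <- dxp[ri0[[ki]], rj0[[kj]], , , drop = FALSE] +
          g * rep(wv, each = ho * wo)
      }
      dx <- if (pad > 0L) dxp[pad + seq_len(h), pad + seq_len(wd), , , drop = FALSE] else dxp
      db <- if (!is.null(b)) rowSums(matrix(colSums(matrix(g, ho * wo)), cout, n)) else NULL
      c(list(dx, dw), if (!is.null(b)) list(db))
    }))
  }

  k2 <- k * k
  coutg <- cout %/% groups
  out <- array(0, dim = c(ho, wo, cout, n))
  Alist <- if (.ag_env$grad_on && (x$req || w$req)) vector("list", groups) else NULL
  ri <- vector("list", k); rj <- vector("list", k)
  for (kk in seq_len(k)) {
    ri[[kk]] <- seq.int(1L + (kk - 1L) * dilation, by = stride, length.out = ho)
    rj[[kk]] <- seq.int(1L + (kk - 1L) * dilation, by = stride, length.out = wo)
  }
  for (gi in seq_len(groups)) {
    cidx <- (gi - 1L) * cing + seq_len(cing)
    oidx <- (gi - 1L) * coutg + seq_len(coutg)
    A <- array(0, dim = c(ho, wo, n, cing * k2))
    pos <- 0L
    for (kj in seq_len(k)) for (ki in seq_len(k)) {
      sl <- xp[ri[[ki]], rj[[kj]], cidx, , drop = FALSE]
      A[, , , pos + seq_len(cing)] <- aperm(sl, c(1L, 2L, 4L, 3L))
      pos <- pos + cing
    }
    dim(A) <- c(ho * wo * n, cing * k2)
    Wm <- matrix(aperm(w$v[, , , oidx, drop = FALSE], c(3L, 1L, 2L, 4L)), ncol = coutg)
    om <- A %*% Wm                                     # (ho*wo*n, coutg)
    dim(om) <- c(ho, wo, n, coutg)
    out[, , oidx, ] <- aperm(om, c(1L, 2L, 4L, 3L))
    if (!is.null(Alist)) Alist[[gi]] <- A
  }
  if (!is.null(b)) out <- out + rep(b$v, each = ho * wo)
  parents <- c(list(x, w), if (!is.null(b)) list(b))
  new_ag(out, parents, function(g) {
    dxp <- array(0, dim = dim(xp))
    dw <- array(0, dim = dim(w$v))
    for (gi in seq_len(groups)) {
      cidx <- (gi - 1L) * cing + seq_len(cing)
      oidx <- (gi - 1L) * coutg + seq_len(coutg)
      gm <- matrix(aperm(g[, , oidx, , drop = FALSE], c(1L, 2L, 4L, 3L)), ncol = coutg)
      A <- Alist[[gi]]
      dWm <- crossprod(A, gm)                          # (cing*k2, coutg)
      dim(dWm) <- c(cing, k, k, coutg)
      dw[, , , oidx] <- aperm(dWm, c(2L, 3L, 1L, 4L))
      Wm <- matrix(aperm(w$v[, , , oidx, drop = FALSE], c(3L, 1L, 2L, 4L)), ncol = coutg)
      dA <- tcrossprod(gm, Wm)                          # (ho*wo*n, cing*k2)
      dim(dA) <- c(ho, wo, n, cing * k2)
      pos <- 0L
      for (kj in seq_len(k)) for (ki in seq_len(k)) {
        dxp[ri[[ki]], rj[[kj]], cidx, ] <- dxp[ri[[ki]], rj[[kj]], cidx, , drop = FALSE] +
          aperm(dA[, , , pos + seq_len(cing), drop = FALSE], c(1L, 2L, 4L, 3L))
        pos <- pos + cing
      }
    }
    dx <- if (pad > 0L) dxp[pad + seq_len(h), pad + seq_len(wd), , , drop = FALSE] else dxp
    db <- if (!is.null(b)) rowSums(matrix(colSums(matrix(g, ho * wo)), cout, n)) else NULL
    c(list(dx, dw), if (!is.null(b)) list(db))
  })
}

## batch normalisation over (h, w, n) per channel, batch statistics
op_batchnorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_ag(x); gamma <- as_ag(gamma); beta <- as_ag(beta)
  d <- dim(x$v); hw <- d[1L] * d[2L]; cc <- d[3L]; n <- d[4L]
  m <- hw * n
  xm <- aperm(x$v, c(1L, 2L, 4L, 3L)); dim(xm) <- c(m, cc)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xh <- sweep(xc, 2L, istd, `*`)
  ym <- sweep(xh, 2L, gamma$v, `*`)
  ym <- sweep(ym, 2L, beta$v, `+`)
  dim(ym) <- c(d[1L], d[2L], n, cc)
  y <- aperm(ym, c(1L, 2L, 4L, 3L))
  new_ag(y, list(x, gamma, beta), function(g) {
    gm <- aperm(g, c(1L, 2L, 4L, 3L)); dim(gm) <- c(m, cc)
    dgamma <- colSums(gm * xh)
    dbeta <- colSums(gm)
    t1 <- sweep(gm, 2L, dbeta / m)
    t2 <- sweep(xh, 2L, colSums(gm * xh) / m, `*`)
    dxm <- sweep(t1 - t2, 2L, gamma$v * istd, `*`)
    dim(dxm) <- c(d[1L], d[2L], n, cc)
    list(aperm(dxm, c(1L, 2L, 4L, 3L)), dgamma, dbeta)
  })
}

## group normalisation: statistics over (h, w, channels-in-group) per sample
op_groupnorm <- function(x, gamma, beta, ngroups, eps = 1e-5) {
  x <- as_ag(x); gamma <- as_ag(gamma); beta <- as_ag(beta)
  d <- dim(x$v); hw <- d[1L] * d[2L]; cc <- d[3L]; n <- d[4L]
  stopifnot(cc %% ngroups == 0L)
  cg <- cc %/% ngroups
  m <- hw * cg
  xm <- x$v; dim(xm) <- c(hw * cg, ngroups * n)      # (h*w*cg, group x n)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xh <- sweep(xc, 2L, istd, `*`)
  dim(xh) <- c(hw, cc, n)
  yv <- xh * rep(gamma$v, each = hw) + rep(beta$v, each = hw)
  dim(yv) <- d
  xh_keep <- xh
  new_ag(yv, list(x, gamma, beta), function(g) {
    gm <- g; dim(gm) <- c(hw, cc, n)
    dgamma <- rowSums(colSums(gm * xh_keep))           # per channel over hw, n
    dbeta <- rowSums(colSums(gm))
    gh <- gm * rep(gamma$v, each = hw)                 # dL/dxhat
    dim(gh) <- c(hw * cg, ngroups * n)
    xh2 <- xh_keep; dim(xh2) <- c(hw * cg, ngroups * n)
    t1 <- sweep(gh, 2L, colMeans(gh))
    t2 <- sweep(xh2, 2L, colMeans(gh * xh2), `*`)
    dx <- sweep(t1 - t2, 2L, istd, `*`)
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

## max pooling, stride and same-style padding (used by SPPF: k=5, s=1, p=2)
op_maxpool <- function(x, k, stride = 1L, pad = 0L) {
  x <- as_ag(x)
  d <- dim(x$v)
  ho <- conv_out_len(d[1L], k, stride, pad, 1L)
  wo <- conv_out_len(d[2L], k, stride, pad, 1L)
  xp <- pad_hw(x$v, pad, value = -Inf)
  best <- array(-Inf, dim = c(ho, wo, d[3L], d[4L]))
  arg <- array(1L, dim = c(ho, wo, d[3L], d[4L]))
  pos <- 0L
  for (kj in seq_len(k)) for (ki in seq_len(k)) {
    pos <- pos + 1L
    sl <- xp[seq.int(ki, by = stride, length.out = ho),
             seq.int(kj, by = stride, length.out = wo), , , drop = FALSE]
    upd <- sl > best
    best[upd] <- sl[upd]
    arg[upd] <- pos
  }
  new_ag(best, list(x), function(g) {
    dxp <- array(0, dim = dim(xp))
    pos <- 0L
    for (kj in seq_len(k)) for (ki in seq_len(k)) {
      pos <- pos + 1L
      sel <- (arg == pos) * g
      ri <- seq.int(ki, by = stride, length.out = ho)
      rj <- seq.int(kj, by = stride, length.out = wo)
      dxp[ri, rj, , ] <- dxp[ri, rj, , , drop = FALSE] + sel
    }
    list(if (pad > 0L) dxp[pad + seq_len(d[1L]), pad + seq_len(d[2L]), , , drop = FALSE] else dxp)
  })
}

## global average pool -> (c, n) matrix
op_gap <- function(x) {
  x <- as_ag(x)
  d <- dim(x$v); hw <- d[1L] * d[2L]
  v <- colSums(matrix(x$v, hw)) / hw
  dim(v) <- c(d[3L], d[4L])
  new_ag(v, list(x), function(g) {
    list(array(rep(as.numeric(g) / hw, each = hw), dim = d))
  })
}

## global max pool -> (c, n) matrix
op_gmp <- function(x) {
  x <- as_ag(x)
  d <- dim(x$v); hw <- d[1L] * d[2L]
  xm <- matrix(x$v, hw)
  idx <- max.col(t(xm), ties.method = "first")        # argmax per (c,n) column
  v <- xm[cbind(idx, seq_along(idx))]
  dim(v) <- c(d[3L], d[4L])
  new_ag(v, list(x), function(g) {
    dx <- matrix(0, hw, d[3L] * d[4L])
    dx[cbind(idx, seq_along(idx))] <- as.numeric(g)
    dim(dx) <- d
    list(dx)
  })
}

## nearest-neighbour 2x upsample
op_upsample2 <- function(x) {
  x <- as_ag(x)
  d <- dim(x$v)
  ri <- rep(seq_len(d[1L]), each = 2L)
  rj <- rep(seq_len(d[2L]), each = 2L)
  new_ag(x$v[ri, rj, , , drop = FALSE], list(x), function(g) {
    io <- rep(seq_len(d[1L]), each = 2L)
    jo <- rep(seq_len(d[2L]), each = 2L)
    dx <- array(0, dim = d)
    for (a in 1:2) for (b in 1:2) {
      dx <- dx + g[seq.int(a, by = 2L, length.out = d[1L]),
                   seq.int(b, by = 2L, length.out = d[2L]), , , drop = FALSE]
    }
    list(dx)
  })
}

## channel concatenation
op_concat_c <- function(xs) {
  xs <- lapply(xs, as_ag)
  ds <- lapply(xs, function(t) dim(t$v))
  cs <- vapply(ds, function(d) d[3L], integer(1L))
  d0 <- ds[[1L]]
  out <- array(0, dim = c(d0[1L], d0[2L], sum(cs), d0[4L]))
  at <- 0L
  for (i in seq_along(xs)) {
    out[, , at + seq_len(cs[i]), ] <- xs[[i]]$v
    at <- at + cs[i]
  }
  new_ag(out, xs, function(g) {
    res <- vector("list", length(xs)); at <- 0L
    for (i in seq_along(xs)) {
      res[[i]] <- g[, , at + seq_len(cs[i]), , drop = FALSE]
      at <- at + cs[i]
    }
    res
  })
}

## take a channel range
op_channels <- function(x, idx) {
  x <- as_ag(x)
  d <- dim(x$v)
  new_ag(x$v[, , idx, , drop = FALSE], list(x), function(g) {
    dx <- array(0, dim = d)
    dx[, , idx, ] <- g
    list(dx)
  })
}

## multiply feature map by per-(channel, sample) factors s: (c, n)
op_scale_channels <- function(x, s) {
  x <- as_ag(x); s <- as_ag(s)
  d <- dim(x$v); hw <- d[1L] * d[2L]
  sv <- array(rep(as.numeric(s$v), each = hw), dim = d)
  new_ag(x$v * sv, list(x, s), function(g) {
    ds <- colSums(matrix(g * x$v, hw))
    dim(ds) <- c(d[3L], d[4L])
    list(g * sv, ds)
  })
}

## multiply feature map by a spatial map m: (h, w, 1, n)
op_scale_spatial <- function(x, m) {
  x <- as_ag(x); m <- as_ag(m)
  d <- dim(x$v)
  mv <- m$v[, , rep(1L, d[3L]), , drop = FALSE]
  new_ag(x$v * mv, list(x, m), function(g) {
    dm <- g * x$v
    dm <- array(rowSums(matrix(aperm(dm, c(1L, 2L, 4L, 3L)), d[1L] * d[2L] * d[4L])),
                dim = c(d[1L], d[2L], d[4L]))
    dm <- aperm(array(dm, dim = c(d[1L], d[2L], d[4L], 1L)), c(1L, 2L, 4L, 3L))
    list(g * mv, dm)
  })
}

## channel-wise mean and max over channels -> (h, w, 1, n) maps
op_channel_mean <- function(x) {
  x <- as_ag(x)
  d <- dim(x$v)
  y <- array(0, dim = c(d[1L], d[2L], 1L, d[4L]))
  xm <- aperm(x$v, c(1L, 2L, 4L, 3L)); dim(xm) <- c(d[1L] * d[2L] * d[4L], d[3L])
  y[] <- rowMeans(xm)
  new_ag(y, list(x), function(g) {
    list(g[, , rep(1L, d[3L]), , drop = FALSE] / d[3L])
  })
}

op_channel_max <- function(x) {
  x <- as_ag(x)
  d <- dim(x$v)
  xm <- aperm(x$v, c(1L, 2L, 4L, 3L)); dim(xm) <- c(d[1L] * d[2L] * d[4L], d[3L])
  idx <- max.col(xm, ties.method = "first")
  v <- xm[cbind(seq_along(idx), idx)]
  y <- array(v, dim = c(d[1L], d[2L], 1L, d[4L]))
  new_ag(y, list(x), function(g) {
    dxm <- matrix(0, nrow(xm), d[3L])
    dxm[cbind(seq_along(idx), idx)] <- as.numeric(g)
    dim(dxm) <- c(d[1L], d[2L], d[4L], d[3L])
    list(aperm(dxm, c(1L, 2L, 4L, 3L)))
  })
}

## gather feature-vector columns at cells: idx is a matrix with columns
## (gy, gx, b); returns (C, n_pick)
op_pick_cells <- function(x, idx) {
  x <- as_ag(x)
  d <- dim(x$v)
  np <- nrow(idx)
  out <- matrix(0, d[3L], np)
  for (r in seq_len(np)) out[, r] <- x$v[idx[r, 1L], idx[r, 2L], , idx[r, 3L]]
  new_ag(out, list(x), function(g) {
    dx <- array(0, dim = d)
    for (r in seq_len(np))
      dx[idx[r, 1L], idx[r, 2L], , idx[r, 3L]] <- dx[idx[r, 1L], idx[r, 2L], , idx[r, 3L]] + g[, r]
    list(dx)
  })
}

## mean binary cross-entropy with logits against a constant target array
op_bce_logits <- function(z, target) {
  z <- as_ag(z)
  t <- if (is_ag(target)) target$v else target
  n <- length(z$v)
  v <- mean(pmax(z$v, 0) - z$v * t + log1p(exp(-abs(z$v))))
  new_ag(v, list(z), function(g) {
    s <- 1 / (1 + exp(-z$v))
    list(keepdim(as.numeric(g) * (s - t) / n, z$v))
  })
}

## mean cross-entropy of row-wise softmax against constant row distributions
op_ce_rows <- function(z, target) {
  z <- as_ag(z)
  t <- if (is_ag(target)) target$v else target
  m <- nrow(z$v)
  zs <- z$v - apply(z$v, 1L, max)
  lse <- log(rowSums(exp(zs)))
  v <- mean(rowSums(t * (lse - zs)))
  new_ag(v, list(z), function(g) {
    p <- exp(zs - lse)
    list(keepdim(as.numeric(g) * (p * rowSums(t) - t) / m, z$v))
  })
}

## replicate (edge-extend) spatial padding
op_pad_replicate <- function(x, p) {
  x <- as_ag(x)
  d <- dim(x$v)
  ri <- c(rep(1L, p), seq_len(d[1L]), rep(d[1L], p))
  rj <- c(rep(1L, p), seq_len(d[2L]), rep(d[2L], p))
  new_ag(x$v[ri, rj, , , drop = FALSE], list(x), function(g) {
    ## accumulate by index: rows then cols
    rsum <- rowsum(matrix(g, length(ri)), ri)
    dim(rsum) <- c(d[1L], length(rj), d[3L], d[4L])
    csum <- rowsum(matrix(aperm(rsum, c(2L, 1L, 3L, 4L)), length(rj)), rj)
    dim(csum) <- c(d[2L], d[1L], d[3L], d[4L])
    list(aperm(csum, c(2L, 1L, 3L, 4L)))
  })
}
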