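#' @keywords internal
"_PACKAGE"

## Reverse-mode automatic differentiation over plain R arrays.
##
## Every tensor is an environment ("ag") holding a numeric array `v`, an
## accumulated gradient `grad`, the list of parent nodes and a backward
## closure mapping the incoming gradient to per-parent gradients.  Graph
## construction is skipped entirely unless gradients are switched on and at
## least one ancestor requires them, so inference pays almost nothing.
##
## Feature maps use the internal layout (h, w, c, n): spatial dims first so
## that window slicing and im2col are contiguous, channels third so that
## per-channel broadcasts are a single `rep(..., each = h*w)`.

.ag_env <- new.env(parent = emptyenv())
.ag_env$grad_on <- FALSE
.ag_env$id <- 0L

#' Enable or disable gradient recording
#'
#' @param on logical; when `FALSE` (the default state) all operators run in
#'   inference mode and build no graph.
#' @return the previous setting, invisibly.
#' @export
ag_grad_mode <- function(on) {
  old <- .ag_env$grad_on
  .ag_env$grad_on <- isTRUE(on)
  invisible(old)
}

#' Run an expression with gradient recording enabled
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @export
with_grad <- function(expr) {
  old <- ag_grad_mode(TRUE)
  on.exit(ag_grad_mode(old))
  expr
}

new_ag <- function(v, parents = list(), bw = NULL, req = FALSE, name = NULL) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$grad <- NULL
  e$req <- req
  .ag_env$id <- .ag_env$id + 1L
  e$id <- .ag_env$id
  if (.ag_env$grad_on && (req || any(vapply(parents, function(p) p$req, logical(1L))))) {
    e$parents <- parents
    e$bw <- bw
    e$req <- TRUE
  } else {
    e$parents <- list()
    e$bw <- NULL
  }
  e$name <- name
  class(e) <- "ag"
  e
}

#' Create a tensor
#'
#' @param v numeric array or vector.
#' @param req logical, should gradients be accumulated for this leaf?
#' @param name optional label used in parameter listings.
#' @return an `ag` tensor.
#' @export
ag <- function(v, req = FALSE, name = NULL) new_ag(v, req = req, name = name)

is_ag <- function(x) inherits(x, "ag")
as_ag <- function(x) if (is_ag(x)) x else ag(x)

#' @export
print.ag <- function(x, ...) {
  d <- dim(x$v)
  cat("<ag", if (is.null(d)) paste0("len ", length(x$v)) else paste(d, collapse = "x"),
      if (x$req) "grad" else "", ">\n")
  invisible(x)
}

#' Backpropagate from a scalar tensor
#'
#' Accumulates `grad` on every reachable leaf with `req = TRUE`.
#' @param t an `ag` scalar (length-1 value).
#' @param seed gradient seed, default 1.
#' @export
ag_backward <- function(t, seed = 1) {
  stopifnot(is_ag(t), length(t$v) == 1L)
  # topological order by DFS
  order <- list(); seen <- new.env(parent = emptyenv())
  stack <- list(list(node = t, i = 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    node <- top$node
    key <- as.character(node$id)
    if (top$i == 0L && !is.null(seen[[key]])) { stack[[length(stack)]] <- NULL; next }
    if (top$i < length(node$parents)) {
      stack[[length(stack)]]$i <- top$i + 1L
      p <- node$parents[[top$i + 1L]]
      if (is.null(seen[[as.character(p$id)]])) stack[[length(stack) + 1L]] <- list(node = p, i = 0L)
    } else {
      seen[[key]] <- TRUE
      order[[length(order) + 1L]] <- node
      stack[[length(stack)]] <- NULL
    }
  }
  for (n in order) n$grad <- NULL
  t$grad <- if (is.null(dim(t$v))) seed else array(seed, dim = dim(t$v))
  for (n in rev(order)) {
    if (is.null(n$bw) || is.null(n$grad)) next
    gs <- n$bw(n$grad)
    for (k in seq_along(n$parents)) {
      p <- n$parents[[k]]
      if (!p$req || is.null(gs[[k]])) next
      p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
    }
  }
  invisible(t)
}

keepdim <- function(g, v) {
  if (!is.null(dim(v))) dim(g) <- dim(v)
  g
}

## ---- elementwise arithmetic ------------------------------------------------

op_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  new_ag(a$v + b$v, list(a, b), function(g) list(keepdim(g, a$v), keepdim(g, b$v)))
}

op_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  new_ag(a$v - b$v, list(a, b), function(g) list(keepdim(g, a$v), keepdim(-g, b$v)))
}

op_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  new_ag(a$v * b$v, list(a, b),
         function(g) list(keepdim(g * b$v, a$v), keepdim(g * a$v, b$v)))
}

op_div <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  new_ag(a$v / b$v, list(a, b),
         function(g) list(keepdim(g / b$v, a$v), keepdim(-g * a$v / (b$v^2), b$v)))
}

op_smul <- function(a, s) { # multiply by plain scalar
  a <- as_ag(a)
  new_ag(a$v * s, list(a), function(g) list(keepdim(g * s, a$v)))
}

op_pmax <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  m <- a$v >= b$v
  new_ag(pmax(a$v, b$v), list(a, b),
         function(g) list(keepdim(g * m, a$v), keepdim(g * !m, b$v)))
}

op_pmin <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  m <- a$v <= b$v
  new_ag(pmin(a$v, b$v), list(a, b),
         function(g) list(keepdim(g * m, a$v), keepdim(g * !m, b$v)))
}

## ---- activations -----------------------------------------------------------

op_relu <- function(a) {
  a <- as_ag(a)
  m <- a$v > 0
  new_ag(a$v * m, list(a), function(g) list(keepdim(g * m, a$v)))
}

op_sigmoid <- function(a) {
  a <- as_ag(a)
  s <- 1 / (1 + exp(-a$v))
  new_ag(s, list(a), function(g) list(keepdim(g * s * (1 - s), a$v)))
}

op_silu <- function(a) {
  a <- as_ag(a)
  s <- 1 / (1 + exp(-a$v))
  new_ag(a$v * s, list(a), function(g) list(keepdim(g * s * (1 + a$v * (1 - s)), a$v)))
}

## softmax over the last dimension of a matrix (m rows, K cols)
op_softmax_rows <- function(a) {
  a <- as_ag(a)
  z <- a$v - apply(a$v, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  new_ag(p, list(a), function(g) {
    keep <- g * p
    list(keepdim(keep - p * rowSums(keep), a$v))
  })
}

## ---- reductions ------------------------------------------------------------

op_mean_all <- function(a) {
  a <- as_ag(a)
  n <- length(a$v)
  new_ag(mean(a$v), list(a), function(g) list(keepdim(array(as.numeric(g) / n, dim = c(length(a$v))), a$v)))
}

op_sum_all <- function(a) {
  a <- as_ag(a)
  new_ag(sum(a$v), list(a), function(g) list(keepdim(array(as.numeric(g), dim = c(length(a$v))), a$v)))
}

## ---- linear algebra --------------------------------------------------------

## y = W %*% x (+ b), x: (in, n), W: (out, in), b: length out or NULL
op_linear <- function(x, W, b = NULL) {
  x <- as_ag(x); W <- as_ag(W)
  y <- W$v %*% x$v
  if (!is.null(b)) {
    b <- as_ag(b)
    y <- y + as.numeric(b$v)
    new_ag(y, list(x, W, b), function(g) {
      list(crossprod(W$v, g), tcrossprod(g, x$v), keepdim(rowSums(g), b$v))
    })
  } else {
    new_ag(y, list(x, W), function(g) list(crossprod(W$v, g), tcrossprod(g, x$v)))
  }
}

op_matmul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  new_ag(a$v %*% b$v, list(a, b),
         function(g) list(tcrossprod(g, b$v), crossprod(a$v, g)))
}

## reshape without copy semantics issues
op_reshape <- function(a, dims) {
  a <- as_ag(a)
  v <- a$v; dim(v) <- dims
  new_ag(v, list(a), function(g) list(keepdim(g, a$v)))
}

op_aperm <- function(a, perm) {
  a <- as_ag(a)
  inv <- order(perm)
  new_ag(aperm(a$v, perm), list(a), function(g) list(aperm(g, inv)))
}

## ---- small matrix utilities ------------------------------------------------

op_t <- function(a) {
  a <- as_ag(a)
  new_ag(t(a$v), list(a), function(g) list(t(g)))
}

## stack (1, n) / (k, n) matrices row-wise
op_rbind <- function(xs) {
  xs <- lapply(xs, as_ag)
  rs <- vapply(xs, function(t) nrow(t$v), integer(1L))
  new_ag(do.call(rbind, lapply(xs, function(t) t$v)), xs, function(g) {
    res <- vector("list", length(xs)); at <- 0L
    for (i in seq_along(xs)) {
      res[[i]] <- g[at + seq_len(rs[i]), , drop = FALSE]
      at <- at + rs[i]
    }
    res
  })
}

## extract rows of a matrix
op_rows <- function(a, idx) {
  a <- as_ag(a)
  d <- dim(a$v)
  new_ag(a$v[idx, , drop = FALSE], list(a), function(g) {
    da <- matrix(0, d[1L], d[2L])
    da[idx, ] <- da[idx, , drop = FALSE] + g
    list(da)
  })
}
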