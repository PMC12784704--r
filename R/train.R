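## Desk-scale training harness.
##
## Label assignment is the simplest rule that makes gradients flow: each
## ground-truth box is assigned to the cell containing its centre, at the
## scale whose stride best matches the box size (the scale minimising
## |log2(sqrt(area) / (4 * stride))|).  The loss is the usual three-part
## detection objective: binary cross-entropy on class logits over all cells,
## an IoU loss on the decoded box at positive cells, and the
## distribution-focal cross-entropy on the four side distributions (soft
## two-bin targets).

assign_targets <- function(labels_list, img_size, strides, grids, nc, bins) {
  nsc <- length(strides)
  n <- length(labels_list)
  tg <- lapply(seq_len(nsc), function(s) {
    g <- grids[[s]]
    list(cls = array(0, dim = c(g[1L], g[2L], nc, n)), pos = NULL)
  })
  pos <- lapply(seq_len(nsc), function(s) list())
  for (b in seq_len(n)) {
    lb <- labels_list[[b]]
    for (r in seq_len(nrow(lb))) {
      bw <- lb$w[r] * img_size; bh <- lb$h[r] * img_size
      side <- sqrt(bw * bh)
      sc <- which.min(abs(log2(pmax(side, 1e-6) / (4 * strides))))
      st <- strides[sc]; g <- grids[[sc]]
      gx <- min(g[2L], max(1L, ceiling(lb$cx[r] * img_size / st)))
      gy <- min(g[1L], max(1L, ceiling(lb$cy[r] * img_size / st)))
      cxu <- lb$cx[r] * img_size / st; cyu <- lb$cy[r] * img_size / st
      cell_cx <- gx - 0.5; cell_cy <- gy - 0.5
      ltrb <- c(cell_cx - (cxu - bw / st / 2), cell_cy - (cyu - bh / st / 2),
                (cxu + bw / st / 2) - cell_cx, (cyu + bh / st / 2) - cell_cy)
      ltrb <- pmin(pmax(ltrb, 0), bins - 1 - 1e-3)
      tg[[sc]]$cls[gy, gx, lb$class_id[r] + 1L, b] <- 1
      pos[[sc]][[length(pos[[sc]]) + 1L]] <- list(cell = c(gy, gx, b), ltrb = ltrb)
    }
  }
  list(cls = lapply(tg, `[[`, "cls"), pos = pos)
}

detection_loss <- function(raw, targets, bins, w_box = 7.5, w_cls = 0.5, w_dfl = 1.5) {
  nsc <- length(raw)
  cls_terms <- list(); box_terms <- list(); dfl_terms <- list()
  for (s in seq_len(nsc)) {
    cls_terms[[s]] <- op_bce_logits(raw[[s]]$cls, targets$cls[[s]])
    ps <- targets$pos[[s]]
    if (length(ps) == 0L) next
    idx <- do.call(rbind, lapply(ps, `[[`, "cell"))
    tl <- do.call(cbind, lapply(ps, `[[`, "ltrb"))          # (4, npos)
    np <- ncol(tl)
    picked <- op_pick_cells(raw[[s]]$reg, idx)               # (4*bins, npos)
    zrows <- op_t(op_reshape(picked, c(bins, 4L * np)))      # (4*npos, bins)
    ## soft two-bin DFL target
    tv <- as.numeric(tl)                                     # length 4*npos
    lo <- floor(tv); hi <- lo + 1
    tmat <- matrix(0, 4L * np, bins)
    tmat[cbind(seq_along(tv), lo + 1L)] <- hi - tv
    tmat[cbind(seq_along(tv), pmin(hi, bins - 1) + 1L)] <-
      tmat[cbind(seq_along(tv), pmin(hi, bins - 1) + 1L)] + (tv - lo)
    dfl_terms[[length(dfl_terms) + 1L]] <- op_ce_rows(zrows, tmat)
    ## decoded distances and IoU loss
    dhat <- op_matmul(op_softmax_rows(zrows), ag(matrix(0:(bins - 1L), bins, 1L)))  # (4*npos, 1)
    dmat <- op_t(op_reshape(dhat, c(4L, np)))               # hold as (np, 4) rows? keep (4,np)
    dmat <- op_reshape(dhat, c(4L, np))
    lp <- op_rows_mat(dmat, 1L); tp <- op_rows_mat(dmat, 2L)
    rp <- op_rows_mat(dmat, 3L); bp <- op_rows_mat(dmat, 4L)
    lt <- tl[1L, ]; tt <- tl[2L, ]; rt <- tl[3L, ]; bt <- tl[4L, ]
    iw <- op_add(op_pmin(lp, ag(matrix(lt, 1L))), op_pmin(rp, ag(matrix(rt, 1L))))
    ih <- op_add(op_pmin(tp, ag(matrix(tt, 1L))), op_pmin(bp, ag(matrix(bt, 1L))))
    inter <- op_mul(iw, ih)
    area_p <- op_mul(op_add(lp, rp), op_add(tp, bp))
    area_t <- (lt + rt) * (tt + bt)
    uni <- op_sub(op_add(area_p, ag(matrix(area_t + 1e-7, 1L))), inter)
    iou <- op_div(inter, uni)
    box_terms[[length(box_terms) + 1L]] <- op_mean_all(op_sub(ag(matrix(1, 1L, np)), iou))
  }
  tot <- NULL
  addw <- function(tot, terms, w) {
    for (t in terms) {
      t <- op_smul(t, w)
      tot <- if (is.null(tot)) t else op_add(tot, t)
    }
    tot
  }
  tot <- addw(tot, cls_terms, w_cls)
  tot <- addw(tot, box_terms, w_box)
  tot <- addw(tot, dfl_terms, w_dfl)
  tot
}

## row of a matrix as (1, n)
op_rows_mat <- function(a, i) op_rows(a, i)

#' Stochastic-gradient training on a toy dataset
#'
#' Runs plain SGD with momentum on an assembled model.  Deterministic under a
#' fixed seed; aborts with the partial trace if the loss turns non-finite.
#'
#' @param model an `sdb_model` (e.g. the `sdb-yolo-pico` preset).
#' @param dataset list of scenes (`list(image=, labels=)`), at least
#'   `batch_size` of them.
#' @param iters number of SGD iterations; 0 returns an empty trace and leaves
#'   the model unchanged.
#' @param seed RNG seed for batch sampling.
#' @param img_size square input side (scenes are resized if needed).
#' @param batch_size images per iteration.
#' @param lr,momentum SGD hyper-parameters.
#' @return numeric vector of per-iteration total losses.
#' @export
train_toy <- function(model, dataset, iters = 200L, seed = 0L, img_size = 64L,
                      batch_size = 8L, lr = 0.01, momentum = 0.9) {
  if (length(dataset) < batch_size)
    stop(sprintf("train_toy: need at least %d images", batch_size))
  if (iters == 0L) return(numeric(0L))
  head_mod <- model$layers[[length(model$layers)]]$module
  bins <- head_mod$reg_max
  nc <- model$nc
  params <- mod_params(model, trainable_only = TRUE)
  vel <- lapply(params, function(p) p$v * 0)
  ## pre-resize images once
  xs <- lapply(dataset, function(sc) {
    img <- sc$image
    if (dim(img)[1L] != img_size) img <- resize_nn(img, img_size, img_size)
    aperm(array(img, dim = c(img_size, img_size, 3L, 1L)), c(1L, 2L, 3L, 4L))
  })
  trace <- numeric(0L)
  strides <- NULL
  grids <- NULL
  local_seed(seed, {
    for (it in seq_len(iters)) {
      sel <- sample(seq_along(dataset), batch_size, replace = FALSE)
      xb <- array(0, dim = c(img_size, img_size, 3L, batch_size))
      for (j in seq_along(sel)) xb[, , , j] <- xs[[sel[j]]]
      lb <- lapply(sel, function(i) dataset[[i]]$labels)
      loss <- with_grad({
        raw <- forward_model(model, fm_wrap(xb))
        if (is.null(strides)) {
          strides <- attr(raw, "strides")
          grids <- lapply(raw, function(o) dim(o$reg$v)[1:2])
        }
        tg <- assign_targets(lb, img_size, strides, grids, nc, bins)
        l <- detection_loss(raw, tg, bins)
        ag_backward(l)
        l$v
      })
      if (!is.finite(loss)) {
        warning(sprintf("train_toy: non-finite loss at iteration %d; aborting", it))
        break
      }
      trace[it] <- loss
      for (nm in names(params)) {
        p <- params[[nm]]
        if (is.null(p$grad)) next
        vel[[nm]] <- momentum * vel[[nm]] + p$grad
        p$v <- p$v - lr * vel[[nm]]
        p$grad <- NULL
      }
    }
  })
  trace
}
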