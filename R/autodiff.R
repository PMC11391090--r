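# Reverse-mode automatic differentiation on matrices.
#
# A tape is an environment holding parallel lists of node values, op codes,
# parent ids and auxiliary data. Ops record themselves while computing their
# forward value; tp_backward() walks the tape once in reverse, dispatching on
# the op code. Node values are always numeric matrices (scalars are 1x1).
# Fused ops (layernorm, softmax rows, LSTM/GRU steps, BCE-with-logits) keep
# the node count per training example small, which is what makes pure-R
# training viable at desk scale.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  cap <- 512L
  tp$val <- vector("list", cap)
  tp$op <- character(cap)
  tp$par <- vector("list", cap)
  tp$aux <- vector("list", cap)
  tp$pname <- character(cap)
  tp
}

tp_push <- function(tp, val, op, par = integer(0), aux = NULL, pname = "") {
  i <- tp$n + 1L
  if (i > length(tp$val)) {
    cap <- 2L * length(tp$val)
    length(tp$val) <- cap
    tp$op <- c(tp$op, character(cap / 2L))
    length(tp$par) <- cap
    length(tp$aux) <- cap
    tp$pname <- c(tp$pname, character(cap / 2L))
  }
  tp$val[[i]] <- val
  tp$op[i] <- op
  tp$par[[i]] <- par
  if (!is.null(aux)) tp$aux[[i]] <- aux
  tp$pname[i] <- pname
  tp$n <- i
  i
}

tp_value <- function(tp, id) {
  force(id)
  tp$val[[id]]
}

tp_const <- function(tp, x) {
  if (!is.matrix(x)) x <- matrix(x, 1)
  tp_push(tp, x, "leafc")
}

tp_param <- function(tp, params, name) {
  tp_push(tp, params[[name]], "leafp", pname = name)
}

tp_mm <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp$val[[a]] %*% tp$val[[b]], "mm", c(a, b))
}

# a %*% t(b)
tp_mmT <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tcrossprod(tp$val[[a]], tp$val[[b]]), "mmT", c(a, b))
}

# t(a) %*% b
tp_Tmm <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, crossprod(tp$val[[a]], tp$val[[b]]), "Tmm", c(a, b))
}

tp_add <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp$val[[a]] + tp$val[[b]], "add", c(a, b))
}

# add a 1 x d row vector to every row of a
tp_addvec <- function(tp, a, b) {
  force(a); force(b)
  av <- tp$val[[a]]
  bv <- tp$val[[b]]
  tp_push(tp, av + bv[rep.int(1L, nrow(av)), , drop = FALSE], "addvec", c(a, b))
}

tp_mul <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp$val[[a]] * tp$val[[b]], "mul", c(a, b))
}

tp_scale <- function(tp, a, k) {
  force(a)
  tp_push(tp, tp$val[[a]] * k, "scale", a, aux = k)
}

tp_addc <- function(tp, a, cmat) {
  force(a)
  tp_push(tp, tp$val[[a]] + cmat, "addc", a)
}

tp_mulc <- function(tp, a, cmat) {
  force(a)
  tp_push(tp, tp$val[[a]] * cmat, "mulc", a, aux = cmat)
}

tp_tanh <- function(tp, a) {
  force(a)
  tp_push(tp, tanh(tp$val[[a]]), "tanh", a)
}

tp_sigmoid <- function(tp, a) {
  force(a)
  tp_push(tp, 1 / (1 + exp(-tp$val[[a]])), "sigm", a)
}

tp_relu <- function(tp, a) {
  force(a)
  x <- tp$val[[a]]
  tp_push(tp, x * (x > 0), "relu", a, aux = (x > 0))
}

# row-wise softmax with optional additive mask (0 = allowed, -Inf = blocked)
tp_softmax_rows <- function(tp, a, mask = NULL) {
  force(a)
  s <- tp$val[[a]]
  if (!is.null(mask)) s <- s + mask
  y <- softmax_rows_val(s)
  tp_push(tp, y, "softmaxr", a)
}

softmax_rows_val <- function(s) {
  mx <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - mx)
  e / rowSums(e)
}

# fused scaled-dot-product attention: softmax(q k' * scale + mask) %*% v.
# `mask` may be a dense additive matrix, or list(bsize =, masks =) describing
# a block-diagonal structure (rows are consecutive blocks of bsize that only
# attend within their own block, each with its own bsize x bsize mask): the
# word-level encoder stacks all posts of a user this way.
tp_attention <- function(tp, q, k, v, scale, mask = NULL) {
  force(q); force(k); force(v)
  qv <- tp$val[[q]]; kv <- tp$val[[k]]; vv <- tp$val[[v]]
  if (is.list(mask)) {
    bsize <- mask$bsize
    nb <- nrow(qv) %/% bsize
    out <- matrix(0, nrow(qv), ncol(vv))
    As <- vector("list", nb)
    for (b in seq_len(nb)) {
      r <- ((b - 1L) * bsize + 1L):(b * bsize)
      s <- tcrossprod(qv[r, , drop = FALSE], kv[r, , drop = FALSE]) * scale +
        mask$masks[[b]]
      A <- softmax_rows_val(s)
      As[[b]] <- A
      out[r, ] <- A %*% vv[r, , drop = FALSE]
    }
    return(tp_push(tp, out, "attnb", c(q, k, v),
                   aux = list(As = As, bsize = bsize, scale = scale)))
  }
  s <- tcrossprod(qv, kv) * scale
  if (!is.null(mask)) s <- s + mask
  A <- softmax_rows_val(s)
  tp_push(tp, A %*% vv, "attn", c(q, k, v),
          aux = list(A = A, scale = scale))
}

# layer normalization over each row, with gain/bias parameter nodes (1 x d)
tp_layernorm <- function(tp, a, g, b, eps = 1e-5) {
  force(a); force(g); force(b)
  x <- tp$val[[a]]
  mu <- rowMeans(x)
  va <- rowMeans((x - mu)^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- (x - mu) * inv
  gv <- tp$val[[g]]
  bv <- tp$val[[b]]
  nr <- nrow(x)
  y <- xhat * gv[rep.int(1L, nr), , drop = FALSE] +
    bv[rep.int(1L, nr), , drop = FALSE]
  tp_push(tp, y, "lnorm", c(a, g, b), aux = list(xhat = xhat, inv = inv))
}

tp_rows <- function(tp, a, idx) {
  force(a)
  tp_push(tp, tp$val[[a]][idx, , drop = FALSE], "rows", a,
          aux = list(idx = idx, nr = nrow(tp$val[[a]])))
}

tp_cols <- function(tp, a, idx) {
  force(a)
  tp_push(tp, tp$val[[a]][, idx, drop = FALSE], "cols", a,
          aux = list(idx = idx, nc = ncol(tp$val[[a]])))
}

tp_rbind <- function(tp, ids) {
  force(ids)
  vals <- tp$val[ids]
  tp_push(tp, do.call(rbind, vals), "rbindk", as.integer(ids),
          aux = vapply(vals, nrow, 1L))
}

tp_cbind <- function(tp, ids) {
  force(ids)
  vals <- tp$val[ids]
  tp_push(tp, do.call(cbind, vals), "cbindk", as.integer(ids),
          aux = vapply(vals, ncol, 1L))
}

# column-wise max over rows -> 1 x d (max-over-time pooling)
tp_colmax <- function(tp, a) {
  force(a)
  x <- tp$val[[a]]
  am <- max.col(t(x), ties.method = "first")
  tp_push(tp, matrix(x[cbind(am, seq_len(ncol(x)))], 1), "colmax", a,
          aux = list(am = am, dim = dim(x)))
}

# embedding lookup: rows of the parameter matrix; id 0 yields a zero row
tp_gather <- function(tp, emb, ids) {
  force(emb)
  e <- tp$val[[emb]]
  out <- matrix(0, length(ids), ncol(e))
  nz <- ids > 0L
  if (any(nz)) out[nz, ] <- e[ids[nz], , drop = FALSE]
  tp_push(tp, out, "gather", emb, aux = list(ids = as.integer(ids), dim = dim(e)))
}

# numerically stable binary cross-entropy with logits; z is 1 x 1, y in {0,1}
tp_bce <- function(tp, z, y) {
  force(z)
  zv <- tp$val[[z]][1, 1]
  loss <- max(zv, 0) - y * zv + log1p(exp(-abs(zv)))
  tp_push(tp, matrix(loss, 1, 1), "bce", z, aux = y)
}

# one fused LSTM step; returns cbind(h', c') (1 x 2H)
# par: x (1 x d), h (1 x H), c (1 x H), Wx (d x 4H), Wh (H x 4H), b (1 x 4H)
# gate layout: [input, forget, cell, output]
tp_lstm_step <- function(tp, x, h, c, Wx, Wh, b) {
  force(x); force(h); force(c); force(Wx); force(Wh); force(b)
  xv <- tp$val[[x]]; hv <- tp$val[[h]]; cv <- tp$val[[c]]
  H <- ncol(hv)
  z <- xv %*% tp$val[[Wx]] + hv %*% tp$val[[Wh]] + tp$val[[b]]
  ig <- 1 / (1 + exp(-z[, 1:H, drop = FALSE]))
  fg <- 1 / (1 + exp(-z[, (H + 1):(2 * H), drop = FALSE]))
  gg <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
  og <- 1 / (1 + exp(-z[, (3 * H + 1):(4 * H), drop = FALSE]))
  cn <- fg * cv + ig * gg
  tc <- tanh(cn)
  hn <- og * tc
  tp_push(tp, cbind(hn, cn), "lstm", c(x, h, c, Wx, Wh, b),
          aux = list(ig = ig, fg = fg, gg = gg, og = og, tc = tc,
                     xv = xv, hv = hv, cv = cv, H = H))
}

# one fused GRU step; returns h' (1 x H)
# par: x, h, Wx (d x 3H), Wh (H x 3H), bx (1 x 3H), bh (1 x 3H)
# gate layout: [reset, update, candidate]
tp_gru_step <- function(tp, x, h, Wx, Wh, bx, bh) {
  force(x); force(h); force(Wx); force(Wh); force(bx); force(bh)
  xv <- tp$val[[x]]; hv <- tp$val[[h]]
  H <- ncol(hv)
  zx <- xv %*% tp$val[[Wx]] + tp$val[[bx]]
  zh <- hv %*% tp$val[[Wh]] + tp$val[[bh]]
  r <- 1 / (1 + exp(-(zx[, 1:H, drop = FALSE] + zh[, 1:H, drop = FALSE])))
  u <- 1 / (1 + exp(-(zx[, (H + 1):(2 * H), drop = FALSE] +
                        zh[, (H + 1):(2 * H), drop = FALSE])))
  hn_in <- zh[, (2 * H + 1):(3 * H), drop = FALSE]
  n <- tanh(zx[, (2 * H + 1):(3 * H), drop = FALSE] + r * hn_in)
  hn <- (1 - u) * n + u * hv
  tp_push(tp, hn, "gru", c(x, h, Wx, Wh, bx, bh),
          aux = list(r = r, u = u, n = n, hn_in = hn_in, xv = xv, hv = hv, H = H))
}

# walk the tape backwards from `loss_id`; returns a named list of parameter
# gradients (accumulated across all leafp nodes sharing a name)
tp_backward <- function(tp, loss_id) {
  force(loss_id)
  n <- tp$n
  grads <- vector("list", n)
  grads[[loss_id]] <- matrix(1, 1, 1)
  pg <- list()
  acc <- function(cur, g) if (is.null(cur)) g else cur + g
  for (i in n:1) {
    g <- grads[[i]]
    if (is.null(g)) next
    op <- tp$op[i]
    p <- tp$par[[i]]
    v <- tp$val[[i]]
    switch(op,
      leafc = NULL,
      leafp = {
        nm <- tp$pname[i]
        pg[[nm]] <- acc(pg[[nm]], g)
      },
      mm = {
        grads[[p[1]]] <- acc(grads[[p[1]]], tcrossprod(g, tp$val[[p[2]]]))
        grads[[p[2]]] <- acc(grads[[p[2]]], crossprod(tp$val[[p[1]]], g))
      },
      mmT = {
        grads[[p[1]]] <- acc(grads[[p[1]]], g %*% tp$val[[p[2]]])
        grads[[p[2]]] <- acc(grads[[p[2]]], crossprod(g, tp$val[[p[1]]]))
      },
      Tmm = {
        grads[[p[1]]] <- acc(grads[[p[1]]], tcrossprod(tp$val[[p[2]]], g))
        grads[[p[2]]] <- acc(grads[[p[2]]], tp$val[[p[1]]] %*% g)
      },
      add = {
        grads[[p[1]]] <- acc(grads[[p[1]]], g)
        grads[[p[2]]] <- acc(grads[[p[2]]], g)
      },
      addvec = {
        grads[[p[1]]] <- acc(grads[[p[1]]], g)
        grads[[p[2]]] <- acc(grads[[p[2]]], matrix(colSums(g), 1))
      },
      mul = {
        grads[[p[1]]] <- acc(grads[[p[1]]], g * tp$val[[p[2]]])
        grads[[p[2]]] <- acc(grads[[p[2]]], g * tp$val[[p[1]]])
      },
      scale = grads[[p[1]]] <- acc(grads[[p[1]]], g * tp$aux[[i]]),
      addc = grads[[p[1]]] <- acc(grads[[p[1]]], g),
      mulc = grads[[p[1]]] <- acc(grads[[p[1]]], g * tp$aux[[i]]),
      tanh = grads[[p[1]]] <- acc(grads[[p[1]]], g * (1 - v^2)),
      sigm = grads[[p[1]]] <- acc(grads[[p[1]]], g * v * (1 - v)),
      relu = grads[[p[1]]] <- acc(grads[[p[1]]], g * tp$aux[[i]]),
      softmaxr = {
        gx <- v * (g - rowSums(g * v))
        grads[[p[1]]] <- acc(grads[[p[1]]], gx)
      },
      attn = {
        a <- tp$aux[[i]]
        A <- a$A
        vv <- tp$val[[p[3]]]
        dV <- crossprod(A, g)
        dA <- tcrossprod(g, vv)
        dS <- A * (dA - rowSums(dA * A))
        grads[[p[1]]] <- acc(grads[[p[1]]],
                             (dS %*% tp$val[[p[2]]]) * a$scale)
        grads[[p[2]]] <- acc(grads[[p[2]]],
                             (crossprod(dS, tp$val[[p[1]]])) * a$scale)
        grads[[p[3]]] <- acc(grads[[p[3]]], dV)
      },
      attnb = {
        a <- tp$aux[[i]]
        qv <- tp$val[[p[1]]]; kv <- tp$val[[p[2]]]; vv <- tp$val[[p[3]]]
        dQ <- matrix(0, nrow(qv), ncol(qv))
        dK <- dQ
        dV <- matrix(0, nrow(vv), ncol(vv))
        for (b in seq_along(a$As)) {
          r <- ((b - 1L) * a$bsize + 1L):(b * a$bsize)
          A <- a$As[[b]]
          gb <- g[r, , drop = FALSE]
          dV[r, ] <- crossprod(A, gb)
          dA <- tcrossprod(gb, vv[r, , drop = FALSE])
          dS <- A * (dA - rowSums(dA * A))
          dQ[r, ] <- (dS %*% kv[r, , drop = FALSE]) * a$scale
          dK[r, ] <- (crossprod(dS, qv[r, , drop = FALSE])) * a$scale
        }
        grads[[p[1]]] <- acc(grads[[p[1]]], dQ)
        grads[[p[2]]] <- acc(grads[[p[2]]], dK)
        grads[[p[3]]] <- acc(grads[[p[3]]], dV)
      },
      lnorm = {
        a <- tp$aux[[i]]
        gv <- tp$val[[p[2]]]
        nr <- nrow(v)
        dgamma <- matrix(colSums(g * a$xhat), 1)
        dbeta <- matrix(colSums(g), 1)
        dxhat <- g * gv[rep.int(1L, nr), , drop = FALSE]
        dx <- a$inv * (dxhat - rowMeans(dxhat) -
                         a$xhat * rowMeans(dxhat * a$xhat))
        grads[[p[1]]] <- acc(grads[[p[1]]], dx)
        grads[[p[2]]] <- acc(grads[[p[2]]], dgamma)
        grads[[p[3]]] <- acc(grads[[p[3]]], dbeta)
      },
      rows = {
        a <- tp$aux[[i]]
        gx <- matrix(0, a$nr, ncol(g))
        if (anyDuplicated(a$idx)) {
          gs <- rowsum(g, a$idx)
          gx[as.integer(rownames(gs)), ] <- gs
        } else {
          gx[a$idx, ] <- g
        }
        grads[[p[1]]] <- acc(grads[[p[1]]], gx)
      },
      cols = {
        a <- tp$aux[[i]]
        gx <- matrix(0, nrow(g), a$nc)
        gx[, a$idx] <- g
        grads[[p[1]]] <- acc(grads[[p[1]]], gx)
      },
      rbindk = {
        sizes <- tp$aux[[i]]
        off <- 0L
        for (k in seq_along(p)) {
          blk <- g[(off + 1L):(off + sizes[k]), , drop = FALSE]
          grads[[p[k]]] <- acc(grads[[p[k]]], blk)
          off <- off + sizes[k]
        }
      },
      cbindk = {
        sizes <- tp$aux[[i]]
        off <- 0L
        for (k in seq_along(p)) {
          blk <- g[, (off + 1L):(off + sizes[k]), drop = FALSE]
          grads[[p[k]]] <- acc(grads[[p[k]]], blk)
          off <- off + sizes[k]
        }
      },
      colmax = {
        a <- tp$aux[[i]]
        gx <- matrix(0, a$dim[1], a$dim[2])
        gx[cbind(a$am, seq_len(a$dim[2]))] <- g[1, ]
        grads[[p[1]]] <- acc(grads[[p[1]]], gx)
      },
      gather = {
        a <- tp$aux[[i]]
        gx <- matrix(0, a$dim[1], a$dim[2])
        nz <- which(a$ids > 0L)
        if (length(nz) > 0) {
          gs <- rowsum(g[nz, , drop = FALSE], a$ids[nz])
          gx[as.integer(rownames(gs)), ] <- gs
        }
        grads[[p[1]]] <- acc(grads[[p[1]]], gx)
      },
      bce = {
        zv <- tp$val[[p[1]]][1, 1]
        dz <- (1 / (1 + exp(-zv)) - tp$aux[[i]]) * g[1, 1]
        grads[[p[1]]] <- acc(grads[[p[1]]], matrix(dz, 1, 1))
      },
      lstm = {
        a <- tp$aux[[i]]
        H <- a$H
        gh <- g[, 1:H, drop = FALSE]
        gc <- g[, (H + 1):(2 * H), drop = FALSE]
        do <- gh * a$tc
        dcn <- gc + gh * a$og * (1 - a$tc^2)
        di <- dcn * a$gg
        df <- dcn * a$cv
        dg <- dcn * a$ig
        dc_prev <- dcn * a$fg
        dz <- cbind(di * a$ig * (1 - a$ig),
                    df * a$fg * (1 - a$fg),
                    dg * (1 - a$gg^2),
                    do * a$og * (1 - a$og))
        grads[[p[1]]] <- acc(grads[[p[1]]], tcrossprod(dz, tp$val[[p[4]]]))
        grads[[p[2]]] <- acc(grads[[p[2]]], tcrossprod(dz, tp$val[[p[5]]]))
        grads[[p[3]]] <- acc(grads[[p[3]]], dc_prev)
        grads[[p[4]]] <- acc(grads[[p[4]]], crossprod(a$xv, dz))
        grads[[p[5]]] <- acc(grads[[p[5]]], crossprod(a$hv, dz))
        grads[[p[6]]] <- acc(grads[[p[6]]], dz)
      },
      gru = {
        a <- tp$aux[[i]]
        H <- a$H
        du <- g * (a$hv - a$n)
        dn <- g * (1 - a$u)
        dh_prev <- g * a$u
        dn_pre <- dn * (1 - a$n^2)
        dr <- dn_pre * a$hn_in
        du_pre <- du * a$u * (1 - a$u)
        dr_pre <- dr * a$r * (1 - a$r)
        dzx <- cbind(dr_pre, du_pre, dn_pre)
        dzh <- cbind(dr_pre, du_pre, dn_pre * a$r)
        grads[[p[1]]] <- acc(grads[[p[1]]], tcrossprod(dzx, tp$val[[p[3]]]))
        dh_prev <- dh_prev + tcrossprod(dzh, tp$val[[p[4]]])
        grads[[p[2]]] <- acc(grads[[p[2]]], dh_prev)
        grads[[p[3]]] <- acc(grads[[p[3]]], crossprod(a$xv, dzx))
        grads[[p[4]]] <- acc(grads[[p[4]]], crossprod(a$hv, dzh))
        grads[[p[5]]] <- acc(grads[[p[5]]], dzx)
        grads[[p[6]]] <- acc(grads[[p[6]]], dzh)
      },
      stop("unknown op in backward pass: ", op)
    )
    grads[i] <- list(NULL)
  }
  pg
}
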