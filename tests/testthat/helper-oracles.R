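# Independent brute-force oracles: explicit loops, no shared code with the
# package internals beyond the documented contracts.

# half-sample symmetric reflection of a 0-based index
oracle_reflect <- function(i, n) {
  if (n == 1L) return(0L)
  p <- 2L * n
  i <- i %% p
  if (i < 0L) i <- i + p
  if (i < n) i else p - 1L - i
}

# whole-sample (reflect-101) reflection of a 0-based index
oracle_reflect101 <- function(i, n) {
  if (n == 1L) return(0L)
  p <- 2L * (n - 1L)
  i <- i %% p
  if (i < 0L) i <- i + p
  if (i < n) i else p - i
}

# dense 2-D convolution of a separable kernel with reflective borders
oracle_sepconv <- function(x, k, reflect = oracle_reflect) {
  h <- nrow(x); w <- ncol(x)
  r <- (length(k) - 1L) / 2L
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      for (dy in seq_along(k)) {
        for (dx in seq_along(k)) {
          ii <- reflect(i - 1L + dy - 1L - r, h) + 1L
          jj <- reflect(j - 1L + dx - 1L - r, w) + 1L
          acc <- acc + k[dy] * k[dx] * x[ii, jj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

oracle_gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

oracle_blur <- function(x, sigma) oracle_sepconv(x, oracle_gauss_kernel(sigma))

oracle_pyr_kernel <- c(1, 4, 6, 4, 1) / 16

oracle_reduce <- function(x) {
  b <- oracle_sepconv(x, oracle_pyr_kernel)
  b[seq(1L, nrow(b), by = 2L), seq(1L, ncol(b), by = 2L), drop = FALSE]
}

oracle_expand <- function(x, target_dim) {
  up <- matrix(0, target_dim[1L], target_dim[2L])
  up[seq(1L, target_dim[1L], by = 2L), seq(1L, target_dim[2L], by = 2L)] <- x
  # parity-preserving (whole-sample) borders, matching the Expand contract
  4 * oracle_sepconv(up, oracle_pyr_kernel, reflect = oracle_reflect101)
}

# naive same-size zero-padded 2-D convolution for [H, W, Cin] x [k, k, Cin, Co]
oracle_conv <- function(x, w, b = NULL) {
  h <- dim(x)[1L]; wd <- dim(x)[2L]; ci <- dim(x)[3L]
  k <- dim(w)[1L]; co <- dim(w)[4L]
  p <- (k - 1L) / 2L
  out <- array(0, c(h, wd, co))
  for (o in seq_len(co)) {
    for (i in seq_len(h)) {
      for (j in seq_len(wd)) {
        acc <- if (is.null(b)) 0 else b[o]
        for (c in seq_len(ci)) {
          for (dy in seq_len(k)) {
            for (dx in seq_len(k)) {
              ii <- i + dy - 1L - p
              jj <- j + dx - 1L - p
              if (ii >= 1L && ii <= h && jj >= 1L && jj <= wd) {
                acc <- acc + w[dy, dx, c, o] * x[ii, jj, c]
              }
            }
          }
        }
        out[i, j, o] <- acc
      }
    }
  }
  out
}

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

# bilinear x2 upsampling (half-pixel centers, clamped), explicit loops
oracle_upsample2 <- function(x, ho, wo) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, ho, wo)
  for (i in seq_len(ho)) {
    for (j in seq_len(wo)) {
      si <- min(max((i - 0.5) * h / ho - 0.5, 0), h - 1)
      sj <- min(max((j - 0.5) * w / wo - 0.5, 0), w - 1)
      i0 <- floor(si); j0 <- floor(sj)
      i1 <- min(i0 + 1, h - 1); j1 <- min(j0 + 1, w - 1)
      fi <- si - i0; fj <- sj - j0
      out[i, j] <- (1 - fi) * (1 - fj) * x[i0 + 1, j0 + 1] +
        fi * (1 - fj) * x[i1 + 1, j0 + 1] +
        (1 - fi) * fj * x[i0 + 1, j1 + 1] +
        fi * fj * x[i1 + 1, j1 + 1]
    }
  }
  out
}

# two-pass connected-component count (8-connectivity) via union-find
oracle_component_count <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(a) {
    while (parent[a] != a) a <- parent[a]
    a
  }
  nxt <- 0L
  for (j in seq_len(w)) {
    for (i in seq_len(h)) {
      if (!mask[i, j]) next
      neigh <- integer(0)
      for (dj in -1:0) {
        for (di in -1:1) {
          if (dj == 0 && di >= 0) next
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && lab[ii, jj] > 0) {
            neigh <- c(neigh, lab[ii, jj])
          }
        }
      }
      if (length(neigh) == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[i, j] <- nxt
      } else {
        roots <- vapply(neigh, find, integer(1))
        r0 <- min(roots)
        lab[i, j] <- r0
        for (r in roots) parent[r] <- r0
      }
    }
  }
  if (nxt == 0L) return(0L)
  length(unique(vapply(seq_len(nxt), find, integer(1))))
}

# brute-force dilation: max filter over a disk neighborhood
oracle_dilate_disk <- function(mask, radius) {
  h <- nrow(mask); w <- ncol(mask)
  r <- as.integer(radius)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2, ]
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      for (q in seq_len(nrow(offs))) {
        ii <- i + offs$di[q]; jj <- j + offs$dj[q]
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && mask[ii, jj]) {
          out[i, j] <- TRUE
          break
        }
      }
    }
  }
  out
}

# finite-difference Hessian (no smoothing) of a matrix, replicated borders
oracle_hessian <- function(g) {
  h <- nrow(g); w <- ncol(g)
  gp <- rbind(g[1, , drop = FALSE], g, g[h, , drop = FALSE])
  gp <- cbind(gp[, 1, drop = FALSE], gp, gp[, w, drop = FALSE])
  ci <- 2:(h + 1); cj <- 2:(w + 1)
  list(
    hxx = gp[ci, cj + 1] - 2 * gp[ci, cj] + gp[ci, cj - 1],
    hyy = gp[ci + 1, cj] - 2 * gp[ci, cj] + gp[ci - 1, cj],
    hxy = (gp[ci + 1, cj + 1] - gp[ci + 1, cj - 1] -
           gp[ci - 1, cj + 1] + gp[ci - 1, cj - 1]) / 4
  )
}
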