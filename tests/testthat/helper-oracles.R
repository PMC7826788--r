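# Independent oracles used to pin down the numerical operations: naive
# nested-loop convolution and up-sampling, a pure-R flood fill, and
# per-pixel metric counting. Deliberately slow and simple.

# x: H x W x Cin array; w: K x K x Cin x Cout; returns Ho x Wo x Cout
oracle_conv <- function(x, w, b, stride = 1L, pad = 1L) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  K <- dim(w)[1]; Cout <- dim(w)[4]
  Ho <- (H + 2L * pad - K) %/% stride + 1L
  Wo <- (W + 2L * pad - K) %/% stride + 1L
  out <- array(0, c(Ho, Wo, Cout))
  for (co in seq_len(Cout)) {
    for (oh in seq_len(Ho)) {
      for (ow in seq_len(Wo)) {
        acc <- b[co]
        for (ci in seq_len(Cin)) {
          for (kh in seq_len(K)) {
            for (kw in seq_len(K)) {
              ih <- (oh - 1L) * stride + kh - pad
              iw <- (ow - 1L) * stride + kw - pad
              if (ih >= 1L && ih <= H && iw >= 1L && iw <= W) {
                acc <- acc + x[ih, iw, ci] * w[kh, kw, ci, co]
              }
            }
          }
        }
        out[oh, ow, co] <- acc
      }
    }
  }
  out
}

# nearest-neighbour x2 up-sampling of an H x W x C array
oracle_up2_nearest <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  out <- array(0, c(2L * H, 2L * W, C))
  for (c in seq_len(C)) {
    for (i in seq_len(2L * H)) {
      for (j in seq_len(2L * W)) {
        out[i, j, c] <- x[ceiling(i / 2), ceiling(j / 2), c]
      }
    }
  }
  out
}

# the full spatial-attention graph evaluated by the oracles above;
# f: H x W x C, weights: list of five (w, b) conv layers
oracle_spatial_attention <- function(f, layers) {
  c1 <- oracle_conv(f, layers$d1$w, layers$d1$b, stride = 2L)
  c2 <- oracle_conv(c1, layers$d2$w, layers$d2$b, stride = 2L)
  bt <- oracle_conv(c2, layers$bottom$w, layers$bottom$b)
  e2 <- oracle_conv(oracle_up2_nearest(bt) + c1, layers$e2$w, layers$e2$b)
  e1 <- oracle_up2_nearest(oracle_conv(e2, layers$e1$w, layers$e1$b))
  e1 + f
}

# flood-fill labeling in scan order (rows outer, columns inner), matching the
# deterministic label convention of the implementation it checks
oracle_label <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8L) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  nxt <- 0L
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      if (mask[r, c] == 0L || lab[r, c] != 0L) next
      nxt <- nxt + 1L
      stack_r <- integer(H * W); stack_c <- integer(H * W)
      stack_r[1L] <- r; stack_c[1L] <- c
      top <- 1L
      lab[r, c] <- nxt
      while (top > 0L) {
        pr <- stack_r[top]; pc <- stack_c[top]; top <- top - 1L
        for (k in seq_len(nrow(nb))) {
          r2 <- pr + nb[k, 1]; c2 <- pc + nb[k, 2]
          if (r2 >= 1L && r2 <= H && c2 >= 1L && c2 <= W &&
              mask[r2, c2] != 0L && lab[r2, c2] == 0L) {
            lab[r2, c2] <- nxt
            top <- top + 1L
            stack_r[top] <- r2; stack_c[top] <- c2
          }
        }
      }
    }
  }
  lab
}

# keep the k largest components, ties resolved by label (scan) order
oracle_keep_largest <- function(mask, k = 2L, connectivity = 8L) {
  lab <- oracle_label(mask, connectivity)
  n <- max(lab)
  if (n <= k) return(mask)
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- order(-areas, seq_len(n))[seq_len(k)]
  out <- (matrix(lab %in% keep, nrow(mask), ncol(mask))) + 0L
  out
}

# per-pixel double-loop confusion counting
oracle_confusion <- function(pred, truth) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (r in seq_len(nrow(pred))) {
    for (c in seq_len(ncol(pred))) {
      if (pred[r, c] == 1L && truth[r, c] == 1L) tp <- tp + 1L
      else if (pred[r, c] == 1L) fp <- fp + 1L
      else if (truth[r, c] == 1L) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# identity batch norm for hand-computed channel-attention examples
make_identity_bn <- function(cp) {
  cp$bn$running_mean[] <- 0
  cp$bn$running_var[] <- 1
  cp$bn$eps <- 0
  cp$gamma$value[] <- 1
  cp$beta$value[] <- 0
  cp
}

# set every conv kernel of a spatial attention block to a constant tap value
set_constant_kernels <- function(sp, value) {
  for (nm in c("d1", "d2", "bottom", "e2", "e1")) {
    sp[[nm]]$w$value[] <- value
    sp[[nm]]$b$value[] <- 0
  }
  sp
}

random_mask <- function(h, w, p = 0.4) {
  matrix(rbinom(h * w, 1L, p), h, w)
}
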