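## Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# 26-connected component labelling of a 3D logical array.
# Breadth-first flood fill over linear indices; adequate for lesion masks.
label_components_26 <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  dm <- dim(mask)
  mask <- as.logical(mask)
  dim(mask) <- dm
  labels <- array(0L, dm)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  # neighbour offsets in index space (dx, dy, dz), excluding self
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  fg <- which(mask)
  if (length(fg) == 0L) return(labels)
  cur <- 0L
  for (start in fg) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      v0 <- v - 1L
      x <- v0 %% nx; y <- (v0 %/% nx) %% ny; z <- v0 %/% (nx * ny)
      nxt <- cbind(x + off[, 1], y + off[, 2], z + off[, 3])
      ok <- nxt[, 1] >= 0 & nxt[, 1] < nx & nxt[, 2] >= 0 & nxt[, 2] < ny &
        nxt[, 3] >= 0 & nxt[, 3] < nz
      nxt <- nxt[ok, , drop = FALSE]
      idx <- nxt[, 1] + nx * (nxt[, 2] + ny * nxt[, 3]) + 1L
      idx <- idx[mask[idx] & labels[idx] == 0L]
      if (length(idx)) {
        labels[idx] <- cur
        queue <- c(queue, idx)
      }
    }
  }
  labels
}

# Sorted (descending) eigenvalues of many symmetric 3x3 matrices at once,
# by the closed-form trigonometric method. `d6` is an n x 6 matrix with
# columns xx, yy, zz, xy, xz, yz. Returns an n x 3 matrix.
eig_sym3 <- function(d6) {
  a <- d6[, 1]; b <- d6[, 2]; c <- d6[, 3]
  d <- d6[, 4]; e <- d6[, 5]; f <- d6[, 6]
  q <- (a + b + c) / 3
  p1 <- d^2 + e^2 + f^2
  p2 <- (a - q)^2 + (b - q)^2 + (c - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  # detB for B = (A - qI)/p; guard p = 0 (isotropic/zero tensors)
  safe_p <- ifelse(p > 0, p, 1)
  aa <- (a - q) / safe_p; bb <- (b - q) / safe_p; cc <- (c - q) / safe_p
  dd <- d / safe_p; ee <- e / safe_p; ff <- f / safe_p
  detB <- aa * (bb * cc - ff^2) - dd * (dd * cc - ff * ee) + ee * (dd * ff - bb * ee)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  iso <- p == 0
  if (any(iso)) {
    l1[iso] <- q[iso]; l2[iso] <- q[iso]; l3[iso] <- q[iso]
  }
  cbind(l1, l2, l3)
}
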