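# Independent brute-force oracles used to validate the fast implementations.

# 3D connected-component labeling by breadth-first search, pure R
# frontier-expansion BFS: each level expands all frontier voxels through
# the 6/26 neighbourhood with vectorized index arithmetic
bfs_label_oracle <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  off_lin <- offs$dz + d[1] * offs$dy + d[1] * d[2] * offs$dx
  lab <- array(0L, d)
  nxt <- 0L
  for (seed in which(mask != 0)) {
    if (lab[seed] != 0L) next
    nxt <- nxt + 1L
    lab[seed] <- nxt
    frontier <- seed
    while (length(frontier) > 0) {
      fz <- (frontier - 1L) %% d[1]
      fy <- ((frontier - 1L) %/% d[1]) %% d[2]
      fx <- (frontier - 1L) %/% (d[1] * d[2])
      cands <- integer(0)
      for (k in seq_len(nrow(offs))) {
        ok <- fz + offs$dz[k] >= 0 & fz + offs$dz[k] < d[1] &
              fy + offs$dy[k] >= 0 & fy + offs$dy[k] < d[2] &
              fx + offs$dx[k] >= 0 & fx + offs$dx[k] < d[3]
        cands <- c(cands, frontier[ok] + off_lin[k])
      }
      cands <- unique(cands)
      cands <- cands[mask[cands] != 0 & lab[cands] == 0L]
      lab[cands] <- nxt
      frontier <- cands
    }
  }
  lab
}

# 2D hole fill of one slice: flood the background from the border
# (4-connectivity); anything unreached becomes foreground
# iterative vectorized reachability: dilate the border-background seed
# set through the background with 4-neighborhood shifts until stable
fill2d_oracle <- function(sl) {
  d <- dim(sl)
  bg <- sl == 0
  reach <- matrix(FALSE, d[1], d[2])
  reach[1, ] <- bg[1, ]; reach[d[1], ] <- bg[d[1], ]
  reach[, 1] <- bg[, 1]; reach[, d[2]] <- bg[, d[2]]
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-d[1], ]
    grown[-d[1], ] <- grown[-d[1], ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -d[2]]
    grown[, -d[2]] <- grown[, -d[2]] | reach[, -1]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  out <- sl
  out[bg & !reach] <- 1L
  out
}

# six-pass plane-wise fill oracle built on fill2d_oracle
fill_planewise_oracle <- function(mask) {
  m <- mask
  for (pass in 1:2) {
    for (z in seq_len(dim(m)[1])) m[z, , ] <- fill2d_oracle(m[z, , ])
    for (y in seq_len(dim(m)[2])) m[, y, ] <- fill2d_oracle(m[, y, ])
    for (x in seq_len(dim(m)[3])) m[, , x] <- fill2d_oracle(m[, , x])
  }
  m
}

# all-pairs surface Hausdorff distance
hausdorff_oracle <- function(a, b) {
  surf <- function(m) {
    d <- dim(m)
    keep <- which(m != 0)
    is_surf <- vapply(keep, function(v) {
      z <- (v - 1) %% d[1] + 1
      y <- ((v - 1) %/% d[1]) %% d[2] + 1
      x <- (v - 1) %/% (d[1] * d[2]) + 1
      for (k in 1:6) {
        zz <- z + c(1, -1, 0, 0, 0, 0)[k]
        yy <- y + c(0, 0, 1, -1, 0, 0)[k]
        xx <- x + c(0, 0, 0, 0, 1, -1)[k]
        if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] ||
            xx < 1 || xx > d[3]) return(TRUE)
        if (m[zz, yy, xx] == 0) return(TRUE)
      }
      FALSE
    }, logical(1))
    v <- keep[is_surf]
    cbind((v - 1) %% d[1], ((v - 1) %/% d[1]) %% d[2], (v - 1) %/% (d[1] * d[2]))
  }
  pa <- surf(a); pb <- surf(b)
  dmat <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)), Vectorize(function(i, j)
    sqrt(sum((pa[i, ] - pb[j, ])^2))))
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# straight tube mask between voxel centers p0, p1 with radius r (voxels)
tube_mask <- function(shape, p0, p1, r) {
  g <- expand.grid(z = 1:shape[1], y = 1:shape[2], x = 1:shape[3])
  seg <- p1 - p0
  L2 <- sum(seg^2)
  wz <- g$z - p0[1]; wy <- g$y - p0[2]; wx <- g$x - p0[3]
  t <- if (L2 > 0) pmax(0, pmin(1, (wz * seg[1] + wy * seg[2] +
                                      wx * seg[3]) / L2)) else 0
  d2 <- (wz - t * seg[1])^2 + (wy - t * seg[2])^2 + (wx - t * seg[3])^2
  array(as.integer(d2 <= r^2), shape)
}

# a vessel_tree wrapping a single straight polyline (for rasterize tests)
straight_tree <- function(spec, p0, p1, radius_um, n = 20) {
  ts <- seq(0, 1, length.out = n)
  pts <- cbind(p0[1] + ts * (p1[1] - p0[1]),
               p0[2] + ts * (p1[2] - p0[2]),
               p0[3] + ts * (p1[3] - p0[3]))
  structure(list(polylines = list(list(pts = pts,
                                       radius_um = rep(radius_um, n),
                                       parent = NA)),
                 shape = spec$shape, voxel_size_um = spec$voxel_size_um),
            class = "vessel_tree")
}

make_quick_spec <- function(...) {
  phantom_spec(shape = c(64, 64, 64), n_trees = 2, n_speckles = 5,
               seed = 7, ...)
}
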