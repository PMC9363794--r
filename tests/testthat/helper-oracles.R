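# Independent brute-force oracles used to validate the package's geometry
# and metric implementations on small inputs.

# Minimum enclosing circle by exhaustive search over all point pairs (as
# diameters) and all point triples (as circumcircles), keeping the smallest
# circle that contains every point. O(n^4); fine for n <= 10.
brute_force_mec <- function(pts) {
  n <- nrow(pts)
  best <- NULL
  contains_all <- function(cx, cy, r) {
    all(sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2) <= r + 1e-9)
  }
  consider <- function(cx, cy, r) {
    if (contains_all(cx, cy, r) && (is.null(best) || r < best$radius))
      best <<- list(center = c(cx, cy), radius = r)
  }
  consider(pts[1, 1], pts[1, 2], 0)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      consider((pts[i, 1] + pts[j, 1]) / 2, (pts[i, 2] + pts[j, 2]) / 2,
               sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2)
    }
  }
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      ax <- pts[i, 1]; ay <- pts[i, 2]
      bx <- pts[j, 1]; by <- pts[j, 2]
      cx <- pts[k, 1]; cy <- pts[k, 2]
      d <- 2 * ((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
      if (abs(d) < 1e-12) next
      b2 <- (bx - ax)^2 + (by - ay)^2
      c2 <- (cx - ax)^2 + (cy - ay)^2
      ux <- ax + ((cy - ay) * b2 - (by - ay) * c2) / d
      uy <- ay + ((bx - ax) * c2 - (cx - ax) * b2) / d
      consider(ux, uy, sqrt((ux - ax)^2 + (uy - ay)^2))
    }
  }
  best
}

# Exhaustive 8-connected flood-fill labeling in plain R.
flood_fill_components <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!bin[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        qi <- p[1] + di; qj <- p[2] + dj
        if (qi < 1 || qi > H || qj < 1 || qj > W) next
        if (bin[qi, qj] && lab[qi, qj] == 0L) {
          lab[qi, qj] <- nxt
          queue[[length(queue) + 1]] <- c(qi, qj)
        }
      }
    }
  }
  lab
}

# Direct per-pixel recomputation of IoU/PA for one class, independent of
# the confusion-count route.
direct_iou_pa <- function(predicted, truth, cl) {
  p <- predicted == cl
  t <- truth == cl
  list(iou = sum(p & t) / sum(p | t),
       pa = (sum(p & t) + sum(!p & !t)) / length(t))
}

random_mask <- function(H, W) matrix(sample(0:2, H * W, replace = TRUE), H, W)
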