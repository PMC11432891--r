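# Directional-field ground truth, learned field head, iterative
# rectification, and FN/FN' fusion.
#
# Grid conventions used throughout: label masks and feature-map channels are
# stored as H x W matrices (row = y, column = x) or as HW x C matrices in
# R's column-major pixel order (pixel index = x * H + y + 1 for 0-based
# coordinates x = column-1, y = row-1). Field semantics are (x, y) with
# pixel centers at integer coordinates and border clamping when sampling.

#' Ground-truth direction field of a label mask
#'
#' For every tissue pixel `m`, finds the nearest boundary pixel `b` of the
#' pixel's own class region (exact Euclidean distance) and stores the unit
#' vector `(m - b) / |m - b|` pointing from the boundary toward the region
#' interior. Boundary pixels themselves and background pixels get `(0, 0)`,
#' so every pixel's field magnitude is exactly 0 or 1. A boundary pixel is
#' a tissue pixel with at least one 4-connected neighbor of a different
#' class (pixels on the image edge count as boundary). Distance ties are
#' broken by the first minimizer in column-major pixel order.
#'
#' @param mask Integer `H x W` label matrix; 0 is background.
#' @return An `HW x 2` matrix (x-component, y-component) in column-major
#'   pixel order, with attributes `dim_hw = c(H, W)`.
#' @export
#' @examples
#' m <- matrix(0L, 9, 9); m[3:7, 3:7] <- 1L
#' f <- gt_direction_field(m)
#' range(sqrt(rowSums(f^2)))  # 0 and 1
gt_direction_field <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  field <- matrix(0, H * W, 2)
  classes <- setdiff(sort(unique(as.vector(mask))), 0L)
  for (cl in classes) {
    inr <- mask == cl
    bnd <- boundary_pixels(inr)
    interior <- which(inr & !bnd)
    bidx <- which(bnd)
    if (!length(interior) || !length(bidx)) next
    # 0-based coordinates: x = col-1, y = row-1
    iy <- (interior - 1L) %% H; ix <- (interior - 1L) %/% H
    by <- (bidx - 1L) %% H;     bx <- (bidx - 1L) %/% H
    d2 <- outer(ix, bx, "-")^2 + outer(iy, by, "-")^2
    j <- max.col(-d2, ties.method = "first")
    vx <- ix - bx[j]; vy <- iy - by[j]
    nrm <- sqrt(vx^2 + vy^2)
    field[interior, 1] <- vx / nrm
    field[interior, 2] <- vy / nrm
  }
  attr(field, "dim_hw") <- c(H, W)
  field
}

# logical H x W matrix: pixels of `inr` with a 4-neighbor outside the region
# (image border counts as outside)
boundary_pixels <- function(inr) {
  H <- nrow(inr); W <- ncol(inr)
  up <- rbind(FALSE, inr[-H, , drop = FALSE])
  dn <- rbind(inr[-1, , drop = FALSE], FALSE)
  lf <- cbind(FALSE, inr[, -W, drop = FALSE])
  rt <- cbind(inr[, -1, drop = FALSE], FALSE)
  inr & !(up & dn & lf & rt)
}

#' Create a direction-field head (1x1 convolution, feat -> 2)
#'
#' The field-learning module: a learnable linear map from the `feat`-channel
#' pre-classifier feature map to the two field channels, with no activation.
#' It is trained against [gt_direction_field()] targets by a mean-squared
#' field loss restricted to tissue pixels.
#'
#' @param feat Input channel count (64 in the reference architecture).
#' @param seed Integer seed for the Gaussian initialization.
#' @return List with weight matrix `W` (`feat x 2`) and bias `b` (length 2).
#' @export
df_head <- function(feat = 64L, seed = 0L) {
  withr::with_seed(seed, list(W = rmat(feat, 2), b = numeric(2)))
}

#' Apply a direction-field head to a feature map
#'
#' @param head A [df_head()].
#' @param features `HW x feat` feature matrix (column-major pixel order).
#' @return `HW x 2` predicted field.
#' @export
df_head_forward <- function(head, features) {
  if (ncol(features) != nrow(head$W)) {
    stop(sprintf("df head expects %d channels, got %d",
                 nrow(head$W), ncol(features)))
  }
  addb(features %*% head$W, head$b)
}

# Precompute the bilinear sampling stencil for displaced sampling: for
# each pixel p, the 4 corner source indices (0-based, for the compiled
# kernels) and weights of the border-clamped location
# (x + Dx(p), y + Dy(p)). Applied, and its adjoint, by the C++ kernels.
bilinear_stencil <- function(field, H, W) {
  n <- H * W
  y <- (seq_len(n) - 1L) %% H; x <- (seq_len(n) - 1L) %/% H
  xs <- pmin(pmax(x + field[, 1], 0), W - 1L)
  ys <- pmin(pmax(y + field[, 2], 0), H - 1L)
  x0 <- floor(xs); y0 <- floor(ys)
  x1 <- pmin(x0 + 1, W - 1L); y1 <- pmin(y0 + 1, H - 1L)
  fx <- xs - x0; fy <- ys - y0
  idx <- cbind(x0 * H + y0, x1 * H + y0, x0 * H + y1, x1 * H + y1)
  storage.mode(idx) <- "integer"
  w <- cbind((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  list(idx = idx, w = w)
}

#' Iterative rectification of a feature map along a direction field
#'
#' Runs `iters` rounds of `F_i(p) = F_{i-1}(px + D(p)x, py + D(p)y)` with
#' bilinear interpolation at the displaced (generally non-integer) location
#' and border clamping; the field is held fixed across iterations. With an
#' inward-pointing field this pulls confident interior features outward to
#' the boundary zone, correcting misclassified boundary pixels.
#'
#' @param F0 `HW x C` feature matrix (column-major pixel order) or an
#'   `H x W` matrix for a single channel.
#' @param field `HW x 2` direction field.
#' @param iters Number of iterations `N` (default 5); 0 returns `F0`.
#' @param dim_hw Integer `c(H, W)`; taken from `attr(field, "dim_hw")` if
#'   absent.
#' @return Rectified feature matrix, same shape as `F0`.
#' @export
rectify <- function(F0, field, iters = 5L, dim_hw = attr(field, "dim_hw")) {
  single <- is.matrix(F0) && !is.null(dim_hw) &&
    nrow(F0) == dim_hw[1] && ncol(F0) == dim_hw[2]
  Fm <- if (single) matrix(as.vector(F0), ncol = 1) else F0
  if (is.null(dim_hw)) stop("grid dimensions unknown; pass dim_hw")
  H <- dim_hw[1]; W <- dim_hw[2]
  if (nrow(Fm) != H * W || nrow(field) != H * W) {
    stop("feature map and field must share the grid")
  }
  if (iters > 0) {
    st <- bilinear_stencil(field, H, W)
    for (i in seq_len(iters)) Fm <- gather_bilinear(Fm, st)
  }
  if (single) matrix(Fm, H, W) else Fm
}

gather_bilinear <- function(Fm, st) {
  cpp_bilinear_gather(Fm, st$idx, st$w)
}

# adjoint of gather_bilinear: scatter-add gradients back to source pixels
scatter_bilinear <- function(dF, st) {
  cpp_bilinear_scatter(dF, st$idx, st$w)
}

#' Fuse original and rectified score maps and classify
#'
#' Channel-concatenates `FN` and the rectified `FN'` and applies a learnable
#' 1x1 convolution down to `C` class scores.
#'
#' @param FN,FNp `HW x C` score maps on the same grid.
#' @param W `2C x C` fusion weight matrix.
#' @param b Length-`C` bias.
#' @return `HW x C` fused class-score map.
#' @export
fuse_and_classify <- function(FN, FNp, W, b) {
  if (!all(dim(FN) == dim(FNp))) stop("FN and FN' grids differ")
  if (nrow(W) != 2 * ncol(FN)) stop("fusion weights expect 2C input channels")
  addb(cbind(FN, FNp) %*% W, b)
}
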