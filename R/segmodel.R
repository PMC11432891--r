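# Full segmentation model: linear patch embedding -> masked (or sliced)
# transformer encoder -> feature decoder with a full-resolution skip from
# the input image -> either a plain 1x1-conv classifier or the DF module
# (field head + iterative rectification + fusion classifier).

#' Assemble a segmentation model
#'
#' Builds the end-to-end model around a masked supernet encoder or, when a
#' subnet specification is given, around the physically sliced compact
#' encoder. The decoder maps final tokens to a `feat`-channel feature map by
#' a 1x1 convolution, bilinearly upsamples it to the input grid, and adds a
#' learnable per-channel skip of the raw image; positions of eliminated
#' patches contribute zero vectors when tokens are re-assembled to the grid.
#'
#' @param config A [seg_model_config()].
#' @param spec Optional [select_budget()] subnet specification; `NULL`
#'   assembles the full supernet model.
#' @param seed Integer seed for deterministic initialization.
#' @return An object of class `vitslim_segmodel` (and `vitslim_compactseg`
#'   when sliced).
#' @export
assemble_model <- function(config, spec = NULL, seed = 0L) {
  stopifnot(inherits(config, "vitslim_segconfig"))
  sp <- config$space
  enc <- build_supernet(sp, seed = seed)
  params <- enc$params
  C <- config$classes; feat <- config$feat; P <- config$patch
  extra <- withr::with_seed(seed + 1L, {
    p <- list()
    p[["embed.W"]] <- rmat(P * P, sp$D); p[["embed.b"]] <- numeric(sp$D)
    p[["dec.W"]] <- rmat(sp$D, feat);    p[["dec.b"]] <- numeric(feat)
    p[["dec.skip"]] <- stats::rnorm(feat, sd = 0.02)
    if (config$df) {
      p[["fn.W"]] <- rmat(feat, C);   p[["fn.b"]] <- numeric(C)
      p[["df.W"]] <- rmat(feat, 2);   p[["df.b"]] <- numeric(2)
      # fusion starts as a pass-through of FN (identity on the first C
      # channels); the rectified path is mixed in by training
      p[["fuse.W"]] <- rbind(diag(C), matrix(0, C, C))
      p[["fuse.b"]] <- numeric(C)
    } else {
      p[["head.W"]] <- rmat(feat, C); p[["head.b"]] <- numeric(C)
    }
    p
  })
  model <- structure(list(
    config = config, space = sp,
    params = c(params, extra), masks = enc$masks,
    precomp = seg_precompute(config)
  ), class = "vitslim_segmodel")
  if (!is.null(spec)) model <- slice_supernet(model, spec)
  model
}

# patchify index matrix (N x P^2) and bilinear upsampling operator
# (HW x N), both fixed by the geometry
seg_precompute <- function(config) {
  H <- config$size; W <- config$size; P <- config$patch; g <- config$grid
  N <- g * g
  pidx <- matrix(0L, N, P * P)
  for (n in seq_len(N)) {
    gy <- (n - 1L) %/% g; gx <- (n - 1L) %% g
    j <- seq_len(P * P) - 1L
    py <- j %/% P; px <- j %% P
    r <- gy * P + py + 1L; cl <- gx * P + px + 1L
    pidx[n, ] <- (cl - 1L) * H + r
  }
  # pixel -> fractional token-grid coordinates, clamped, bilinear weights
  n_pix <- H * W
  y <- (seq_len(n_pix) - 1L) %% H; x <- (seq_len(n_pix) - 1L) %/% H
  u <- pmin(pmax((x - (P - 1) / 2) / P, 0), g - 1L)
  v <- pmin(pmax((y - (P - 1) / 2) / P, 0), g - 1L)
  u0 <- floor(u); v0 <- floor(v)
  u1 <- pmin(u0 + 1, g - 1L); v1 <- pmin(v0 + 1, g - 1L)
  fu <- u - u0; fv <- v - v0
  tok <- function(gy, gx) gy * g + gx + 1L
  idx <- cbind(tok(v0, u0), tok(v0, u1), tok(v1, u0), tok(v1, u1))
  w <- cbind((1 - fu) * (1 - fv), fu * (1 - fv), (1 - fu) * fv, fu * fv)
  U <- matrix(0, n_pix, N)
  for (k in 1:4) {
    U[cbind(seq_len(n_pix), idx[, k])] <- U[cbind(seq_len(n_pix), idx[, k])] + w[, k]
  }
  list(pidx = pidx, U = U)
}

# shim so encoder_forward/backward see a bare supernet
enc_view <- function(model) {
  list(config = model$space, params = model$params, masks = model$masks)
}

# Forward pass of the segmentation model on one image.
#   x: H x W matrix in [0,1]
#   masks / patch_bypass / alive: passed to the encoder (supernet models)
seg_forward <- function(model, x, masks = model$masks, patch_bypass = FALSE,
                        alive = NULL, want_cache = FALSE) {
  cfg <- model$config
  pc <- model$precomp
  xvec <- as.vector(x)
  if (inherits(model, "vitslim_compactseg")) {
    a1 <- model$alive[[1]]
    Xp <- x[pc$pidx[a1, , drop = FALSE]]
    dim(Xp) <- c(length(a1), cfg$patch^2)
    T0 <- addb(Xp %*% model$params[["embed.W"]], model$params[["embed.b"]])
    enc <- compact_encoder_forward(model, T0, want_cache = want_cache)
    G <- enc$out
  } else {
    Xp <- x[pc$pidx]; dim(Xp) <- dim(pc$pidx)
    T0 <- addb(Xp %*% model$params[["embed.W"]], model$params[["embed.b"]])
    enc <- encoder_forward(enc_view(model), T0, masks = masks,
                           patch_bypass = patch_bypass, alive = alive,
                           want_cache = want_cache)
    G <- enc$out
  }
  p <- model$params
  Gd <- addb(G %*% p[["dec.W"]], p[["dec.b"]])
  F64pre <- pc$U %*% Gd + outer(xvec, p[["dec.skip"]])
  relu_mask <- F64pre > 0
  F64 <- F64pre * relu_mask
  if (cfg$df) {
    C <- cfg$classes
    # one fused product for the FN classifier and the field head
    FB <- addb(F64 %*% cbind(p[["fn.W"]], p[["df.W"]]),
               c(p[["fn.b"]], p[["df.b"]]))
    F0 <- FB[, 1:C, drop = FALSE]
    field <- FB[, C + (1:2), drop = FALSE]
    st <- bilinear_stencil(field, cfg$size, cfg$size)
    FN <- F0
    for (i in seq_len(cfg$df_iters)) FN <- gather_bilinear(FN, st)
    logits <- addb(cbind(F0, FN) %*% p[["fuse.W"]], p[["fuse.b"]])
  } else {
    field <- NULL; F0 <- NULL; st <- NULL; FN <- NULL
    logits <- addb(F64 %*% p[["head.W"]], p[["head.b"]])
  }
  res <- list(logits = logits, field = field)
  if (want_cache) {
    res$cache <- list(x = xvec, Xp = Xp, T0 = T0, enc = enc$cache, G = G,
                      Gd = Gd, relu_mask = relu_mask, F64 = F64, F0 = F0,
                      st = st, FN = FN, masks = masks)
  }
  res
}

# Backward pass; dlogits is the CE gradient, dfield the field-loss gradient
# (NULL when DF is disabled). The predicted field is treated as constant in
# the rectification path, so dfield feeds only the field head.
seg_backward <- function(model, cache, dlogits, dfield = NULL) {
  cfg <- model$config; p <- model$params; pc <- model$precomp
  C <- cfg$classes
  g <- list()
  if (cfg$df) {
    both <- cbind(cache$F0, cache$FN)
    g[["fuse.W"]] <- crossprod(both, dlogits)
    g[["fuse.b"]] <- colSums(dlogits)
    dboth <- tcrossprod(dlogits, p[["fuse.W"]])
    dF0 <- dboth[, 1:C, drop = FALSE]
    dFN <- dboth[, C + (1:C), drop = FALSE]
    for (i in seq_len(cfg$df_iters)) dFN <- scatter_bilinear(dFN, cache$st)
    dF0 <- dF0 + dFN
    if (is.null(dfield)) dfield <- matrix(0, nrow(dF0), 2)
    dFD <- cbind(dF0, dfield)
    gB <- crossprod(cache$F64, dFD)
    g[["fn.W"]] <- gB[, 1:C, drop = FALSE]
    g[["fn.b"]] <- colSums(dF0)
    g[["df.W"]] <- gB[, C + (1:2), drop = FALSE]
    g[["df.b"]] <- colSums(dfield)
    dF64 <- tcrossprod(dFD, cbind(p[["fn.W"]], p[["df.W"]]))
  } else {
    g[["head.W"]] <- crossprod(cache$F64, dlogits)
    g[["head.b"]] <- colSums(dlogits)
    dF64 <- tcrossprod(dlogits, p[["head.W"]])
  }
  dF64pre <- dF64 * cache$relu_mask
  g[["dec.skip"]] <- colSums(dF64pre * cache$x)
  dGd <- crossprod(pc$U, dF64pre)
  g[["dec.W"]] <- crossprod(cache$G, dGd)
  g[["dec.b"]] <- colSums(dGd)
  dG <- tcrossprod(dGd, p[["dec.W"]])
  if (inherits(model, "vitslim_compactseg")) {
    eb <- compact_encoder_backward(model, cache$enc, dG)
    dmasks <- NULL
  } else {
    eb <- encoder_backward(enc_view(model), cache$enc, dG, masks = cache$masks)
    dmasks <- eb$dmasks
  }
  g <- acc_grads(g, eb$grads)
  g[["embed.W"]] <- crossprod(cache$Xp, eb$dT0)
  g[["embed.b"]] <- colSums(eb$dT0)
  list(grads = g, dmasks = dmasks)
}

#' Predict a label map for one image
#'
#' @param model A `vitslim_segmodel`.
#' @param x `H x W` image matrix in `[0, 1]`.
#' @param ... Passed to the internal forward (e.g. `patch_bypass`).
#' @return `H x W` integer matrix of 0-based class labels.
#' @export
predict_labels <- function(model, x, ...) {
  logits <- seg_forward(model, x, ...)$logits
  lab <- max.col(logits, ties.method = "first") - 1L
  matrix(as.integer(lab), model$config$size, model$config$size)
}

#' Dice similarity coefficient of two pixel sets
#'
#' `DSC = 2 |mt intersect mp| / (|mt| + |mp|)`. Arguments may be logical
#' masks on the same grid or integer index sets. Two empty sets define
#' `DSC = 1` (a correct prediction of absence is not penalized).
#'
#' @param mt,mp Ground-truth and predicted sets.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' dsc(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))  # 2/3
dsc <- function(mt, mp) {
  if (is.logical(mt) != is.logical(mp)) {
    stop("mt and mp must both be masks or both index sets")
  }
  if (is.logical(mt)) {
    if (length(mt) != length(mp)) stop("mask grids differ")
    nt <- sum(mt); np <- sum(mp); ni <- sum(mt & mp)
  } else {
    nt <- length(mt); np <- length(mp); ni <- length(intersect(mt, mp))
  }
  if (nt + np == 0) return(1)
  2 * ni / (nt + np)
}

# per-class one-vs-rest DSC for 0-based label matrices
dsc_per_class <- function(truth, pred, classes) {
  vapply(seq_len(classes) - 1L,
         function(cl) dsc(as.vector(truth) == cl, as.vector(pred) == cl),
         numeric(1))
}

#' Evaluate a segmentation model on a dataset
#'
#' Computes one-vs-rest Dice per tissue class and reports three
#' aggregations: per-class means over images, the unweighted mean over
#' tissue classes of those (the headline "mean DSC", background excluded),
#' and a per-image class-mean. Parameter counts are attached.
#'
#' @param model A `vitslim_segmodel`.
#' @param data List of samples, each `list(image =, label =)`.
#' @param ... Passed to the forward (e.g. `patch_bypass = TRUE` when
#'   evaluating a supernet with identity masks).
#' @return A list of class `vitslim_eval` with elements `per_class`,
#'   `mean_dsc`, `per_image` (images x classes matrix, tissue classes),
#'   `mean_per_image`, `n_params`.
#' @export
evaluate <- function(model, data, ...) {
  stopifnot(length(data) > 0)
  C <- model$config$classes
  per_image <- t(vapply(data, function(s) {
    pred <- predict_labels(model, s$image, ...)
    dsc_per_class(s$label, pred, C)[-1]  # tissue classes only
  }, numeric(C - 1)))
  colnames(per_image) <- paste0("class", seq_len(C - 1))
  per_class <- colMeans(per_image)
  structure(list(
    per_class = per_class,
    mean_dsc = mean(per_class),
    per_image = per_image,
    mean_per_image = mean(rowMeans(per_image)),
    n_params = n_params(model)
  ), class = "vitslim_eval")
}

#' @export
print.vitslim_eval <- function(x, ...) {
  cat("<vitslim_eval>\n")
  cat(sprintf("  mean DSC (tissue classes): %.4f\n", x$mean_dsc))
  cat("  per class:", paste(sprintf("%.4f", x$per_class), collapse = " "), "\n")
  cat(sprintf("  parameters: %d\n", x$n_params))
  invisible(x)
}

#' Attach the directional-field module to a segmentation model
#'
#' Replaces the plain 1x1-conv classifier by the DF triple (field head,
#' rectification, fusion classifier), keeping all other weights — the
#' ablation that isolates the DF module's contribution. Adds
#' `(feat x 2 + 2) + (2C x C + C)` parameters net of the removed plain head
#' being replaced by the same-shaped `FN` classifier.
#'
#' @param model A `vitslim_segmodel` with `df = FALSE`.
#' @param seed Integer seed for the new heads.
#' @param df_iters,df_weight DF settings (defaults 5 and 1).
#' @return The model with the DF module enabled.
#' @export
add_df_module <- function(model, seed = 0L, df_iters = 5L, df_weight = 1.0) {
  stopifnot(inherits(model, "vitslim_segmodel"), !model$config$df)
  C <- model$config$classes; feat <- model$config$feat
  model$config$df <- TRUE
  model$config$df_iters <- as.integer(df_iters)
  model$config$df_weight <- df_weight
  # identity-initialized refinement: the existing classifier becomes the FN
  # head and the fusion starts as a pass-through of FN, so the augmented
  # model initially computes exactly what the plain model did and learns to
  # mix in the rectified FN' path
  new_p <- withr::with_seed(seed, list(
    fn.W = model$params[["head.W"]], fn.b = model$params[["head.b"]],
    df.W = rmat(feat, 2), df.b = numeric(2),
    fuse.W = rbind(diag(C), matrix(0, C, C)), fuse.b = numeric(C)))
  model$params[["head.W"]] <- NULL
  model$params[["head.b"]] <- NULL
  model$params <- c(model$params, new_p)
  model
}

#' Total parameter count of a model by tensor enumeration
#'
#' @param model Any model whose `params` is a flat list of arrays.
#' @return Integer total number of scalar parameters.
#' @export
n_params <- function(model) {
  as.integer(sum(vapply(model$params, length, numeric(1))))
}
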