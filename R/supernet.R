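# Masked transformer supernet.
#
# Every searchable linear layer stores one weight matrix at the maximal
# ("super") dimension; candidate sub-layers are slices of it. Importance
# masks multiply activations, not weights: one mask vector per (layer, head)
# multiplies q, k and v of that head, one per layer multiplies the MLP
# hidden activation, and one tanh-bounded score per (layer, patch) scales
# the token row at the entry of each encoder block. The attention softmax
# temperature is always sqrt(d) of the full per-head width, with no
# mask-dependent correction.
#
# The backward pass is derived by hand and verified against central finite
# differences in the test suite; no autodiff framework is involved.

#' Create an all-ones mask set for a search space
#'
#' Fresh importance masks are initialized at 1 for every searchable MHSA
#' head dimension, MLP hidden dimension, and patch token (pre-tanh scores
#' for patches).
#'
#' @param config A [search_space_config()].
#' @return An object of class `vitslim_masks`: list with elements `mhsa`
#'   (per-layer `H x d` matrices), `mlp` (per-layer length-`M` vectors),
#'   `patch` (per-layer length-`N` vectors of pre-tanh scores).
#' @export
mask_set <- function(config) {
  stopifnot(inherits(config, "vitslim_config"))
  structure(list(
    mhsa  = replicate(config$L, matrix(1, config$H, config$d), simplify = FALSE),
    mlp   = replicate(config$L, rep(1, config$M), simplify = FALSE),
    patch = replicate(config$L, rep(1, config$N), simplify = FALSE)
  ), class = "vitslim_masks")
}

#' Build a masked transformer supernet
#'
#' Constructs the weight-shared encoder at maximal dimensions with fresh
#' all-ones masks attached. Initialization is Gaussian (sd 0.02) for weight
#' matrices and zero for biases, deterministic under `seed`.
#'
#' @param config A [search_space_config()].
#' @param seed Integer seed; the same seed reproduces bit-identical weights.
#' @return An object of class `vitslim_supernet` with elements `config`,
#'   `params` (flat named list of arrays) and `masks` (a [mask_set()]).
#' @export
#' @examples
#' net <- build_supernet(search_space_config(2, 2, 4, M = 16, N = 9), seed = 1)
build_supernet <- function(config, seed = 0L) {
  stopifnot(inherits(config, "vitslim_config"))
  D <- config$D; Hd <- config$H * config$d; M <- config$M
  params <- withr::with_seed(seed, {
    p <- list()
    for (l in seq_len(config$L)) {
      pre <- function(nm) paste0("l", l, ".", nm)
      p[[pre("Wq")]] <- rmat(D, Hd); p[[pre("bq")]] <- numeric(Hd)
      p[[pre("Wk")]] <- rmat(D, Hd); p[[pre("bk")]] <- numeric(Hd)
      p[[pre("Wv")]] <- rmat(D, Hd); p[[pre("bv")]] <- numeric(Hd)
      p[[pre("Wo")]] <- rmat(Hd, D); p[[pre("bo")]] <- numeric(D)
      p[[pre("W1")]] <- rmat(D, M);  p[[pre("b1")]] <- numeric(M)
      p[[pre("W2")]] <- rmat(M, D);  p[[pre("b2")]] <- numeric(D)
    }
    p
  })
  structure(list(config = config, params = params, masks = mask_set(config)),
            class = "vitslim_supernet")
}

rmat <- function(n, m, sd = 0.02) matrix(stats::rnorm(n * m, sd = sd), n, m)

# add a row-broadcast bias to an n x k matrix
addb <- function(X, b) X + rep(b, each = nrow(X))

# flatten per-head mask matrix (H x d) to the concatenated-head layout
# (head 1 dims, head 2 dims, ...) used by the Hd-wide projections
flat_heads <- function(zmat) as.vector(t(zmat))

hcols <- function(h, d) ((h - 1L) * d + 1L):(h * d)

softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

#' Masked patch scaling (encoder block entry)
#'
#' Scales token row `j` by `tanh(z_patch[layer][j])`: the tanh bound keeps
#' patch mask values from exploding during the search. With `bypass = TRUE`
#' (or patch search disabled in the config) rows pass through unchanged.
#'
#' @param model A [build_supernet()] model.
#' @param t `N x D` token matrix.
#' @param layer Layer index (1-based).
#' @param masks A mask set; defaults to the model's.
#' @param bypass Skip the scaling (used when evaluating extracted subnets,
#'   where kept patches carry an implicit mask of exactly 1).
#' @return The scaled token matrix.
#' @export
masked_patch_forward <- function(model, t, layer, masks = model$masks,
                                 bypass = FALSE) {
  if (!model$config$search_patch || bypass || is.null(masks)) return(t)
  stopifnot(nrow(t) == model$config$N)
  t * tanh(masks$patch[[layer]])
}

#' Masked multi-head self-attention forward
#'
#' For each head `i` computes `A_i = softmax((q_i z)(k_i z)^T / sqrt(d))`
#' and `O_i = A_i (v_i z)` with the head's mask vector `z` multiplying the
#' biased projections q, k and v, then projects the concatenated head
#' outputs. With `masks = NULL` the standard unmasked MHSA is computed.
#' Non-finite activations raise an error rather than being clipped.
#'
#' @inheritParams masked_patch_forward
#' @param exclude Optional integer vector of token indices excluded from the
#'   attention normalization (dead patches of a binarized subnet).
#' @return `N x D` output token matrix (no residual added).
#' @export
masked_mhsa_forward <- function(model, t, layer, masks = model$masks,
                                exclude = NULL) {
  cfg <- model$config
  z_flat <- if (is.null(masks)) NULL else flat_heads(masks$mhsa[[layer]])
  out <- mhsa_block(model$params, layer, t,
                    head_cols = uniform_head_cols(cfg$H, cfg$d),
                    inv_sqrt_d = 1 / sqrt(cfg$d),
                    z_flat = z_flat, dead = exclude, cache = FALSE)$out
  if (!all(is.finite(out))) {
    stop(sprintf("non-finite MHSA activations at layer %d", layer))
  }
  out
}

#' Masked MLP forward
#'
#' Computes `t_e = relu(f1(t)) * z_mlp[layer]` followed by `f2(t_e)`; the
#' mask multiplies the hidden activation after the nonlinearity, so an
#' all-zero mask reduces the block to the bias of `f2`.
#'
#' @inheritParams masked_patch_forward
#' @return `N x D` output token matrix (no residual added).
#' @export
masked_mlp_forward <- function(model, t, layer, masks = model$masks) {
  out <- mlp_block(model$params, layer, t,
                   z = if (is.null(masks)) NULL else masks$mlp[[layer]],
                   cache = FALSE)$out
  if (!all(is.finite(out))) {
    stop(sprintf("non-finite MLP activations at layer %d", layer))
  }
  out
}

# ---- internal blocks with caches -------------------------------------------
#
# The block functions take an explicit per-head column layout `head_cols`
# (list of integer column vectors into the q/k/v/projection matrices) so
# that the same code serves the uniform-width supernet and the ragged
# sliced compact model. The softmax temperature is always sqrt(d) of the
# configured maximal per-head width, regardless of masking or slicing.

uniform_head_cols <- function(H, d) lapply(seq_len(H), hcols, d = d)

# precomputed "l<layer>.<tensor>" name tables (hot path: avoids paste0)
.lnames <- local({
  nms <- c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
           "W1", "b1", "W2", "b2")
  lapply(1:64, function(l) stats::setNames(paste0("l", l, ".", nms), nms))
})

mhsa_block <- function(params, l, Tm, head_cols, inv_sqrt_d, z_flat = NULL,
                       dead = NULL, cache = TRUE) {
  lt <- .lnames[[l]]
  pre <- function(nm) params[[lt[[nm]]]]
  q <- addb(Tm %*% pre("Wq"), pre("bq"))
  k <- addb(Tm %*% pre("Wk"), pre("bk"))
  v <- addb(Tm %*% pre("Wv"), pre("bv"))
  if (!is.null(z_flat)) {
    zf <- rep(z_flat, each = nrow(Tm))
    qz <- q * zf; kz <- k * zf; vz <- v * zf
  } else {
    qz <- q; kz <- k; vz <- v
  }
  H <- length(head_cols)
  Ocat <- matrix(0, nrow(Tm), ncol(q))
  heads <- if (cache) vector("list", H) else NULL
  for (h in seq_len(H)) {
    idx <- head_cols[[h]]
    if (!length(idx)) next  # fully eliminated head
    S <- (qz[, idx, drop = FALSE] %*% t(kz[, idx, drop = FALSE])) * inv_sqrt_d
    if (length(dead)) S[, dead] <- -Inf
    A <- softmax_rows(S)
    Ocat[, idx] <- A %*% vz[, idx, drop = FALSE]
    if (cache) heads[[h]] <- list(A = A)
  }
  out <- addb(Ocat %*% pre("Wo"), pre("bo"))
  list(out = out,
       cache = if (cache) list(q = q, k = k, v = v, qz = qz, kz = kz, vz = vz,
                               heads = heads, Ocat = Ocat, Tm = Tm) else NULL)
}

mhsa_backward <- function(params, l, cc, head_cols, inv_sqrt_d,
                          z_flat = NULL, dOut = NULL) {
  lt <- .lnames[[l]]
  pre <- function(nm) lt[[nm]]
  g <- list()
  g[[pre("Wo")]] <- crossprod(cc$Ocat, dOut)
  g[[pre("bo")]] <- colSums(dOut)
  dOcat <- tcrossprod(dOut, params[[pre("Wo")]])
  n <- nrow(dOut)
  k_tot <- ncol(cc$q)
  dqz <- matrix(0, n, k_tot); dkz <- matrix(0, n, k_tot)
  dvz <- matrix(0, n, k_tot)
  for (h in seq_along(head_cols)) {
    idx <- head_cols[[h]]
    if (!length(idx)) next
    A <- cc$heads[[h]]$A
    dO <- dOcat[, idx, drop = FALSE]
    dA <- tcrossprod(dO, cc$vz[, idx, drop = FALSE])
    dvz[, idx] <- crossprod(A, dO)
    dS <- (dA - rowSums(dA * A)) * A
    dqz[, idx] <- (dS %*% cc$kz[, idx, drop = FALSE]) * inv_sqrt_d
    dkz[, idx] <- (crossprod(dS, cc$qz[, idx, drop = FALSE])) * inv_sqrt_d
  }
  if (!is.null(z_flat)) {
    dz_flat <- colSums(dqz * cc$q) + colSums(dkz * cc$k) + colSums(dvz * cc$v)
    zf <- rep(z_flat, each = n)
    dq <- dqz * zf; dk <- dkz * zf; dv <- dvz * zf
  } else {
    dz_flat <- NULL
    dq <- dqz; dk <- dkz; dv <- dvz
  }
  g[[pre("Wq")]] <- crossprod(cc$Tm, dq); g[[pre("bq")]] <- colSums(dq)
  g[[pre("Wk")]] <- crossprod(cc$Tm, dk); g[[pre("bk")]] <- colSums(dk)
  g[[pre("Wv")]] <- crossprod(cc$Tm, dv); g[[pre("bv")]] <- colSums(dv)
  dTm <- tcrossprod(dq, params[[pre("Wq")]]) +
    tcrossprod(dk, params[[pre("Wk")]]) +
    tcrossprod(dv, params[[pre("Wv")]])
  list(grads = g, dz_flat = dz_flat, dTm = dTm)
}

mlp_block <- function(params, l, Tm, z = NULL, cache = TRUE) {
  lt <- .lnames[[l]]
  pre <- function(nm) params[[lt[[nm]]]]
  h1 <- addb(Tm %*% pre("W1"), pre("b1"))
  r <- h1 * (h1 > 0)
  e <- if (!is.null(z)) r * rep(z, each = nrow(Tm)) else r
  out <- addb(e %*% pre("W2"), pre("b2"))
  list(out = out,
       cache = if (cache) list(h1 = h1, r = r, e = e, Tm = Tm) else NULL)
}

mlp_backward <- function(params, l, cc, z = NULL, dOut = NULL) {
  lt <- .lnames[[l]]
  pre <- function(nm) lt[[nm]]
  g <- list()
  g[[pre("W2")]] <- crossprod(cc$e, dOut)
  g[[pre("b2")]] <- colSums(dOut)
  de <- tcrossprod(dOut, params[[pre("W2")]])
  if (!is.null(z)) {
    dz <- colSums(de * cc$r)
    dr <- de * rep(z, each = nrow(de))
  } else {
    dz <- NULL
    dr <- de
  }
  dh1 <- dr * (cc$h1 > 0)
  g[[pre("W1")]] <- crossprod(cc$Tm, dh1)
  g[[pre("b1")]] <- colSums(dh1)
  dTm <- tcrossprod(dh1, params[[pre("W1")]])
  list(grads = g, dz = dz, dTm = dTm)
}

# ---- full encoder ----------------------------------------------------------

# Forward through all encoder layers.
#   masks:        NULL for the plain unmasked network
#   patch_bypass: skip patch row scaling (identity check, binarized subnets)
#   alive:        optional per-layer list of alive token indices; dead tokens
#                 are excluded from attention and their rows zeroed (the
#                 zero-mask limit of the search phase)
#   want_cache:   keep per-layer activations for the backward pass (only
#                 supported without dead tokens)
encoder_forward <- function(model, T0, masks = model$masks,
                            patch_bypass = FALSE, alive = NULL,
                            want_cache = FALSE) {
  cfg <- model$config
  Tl <- T0
  head_cols <- uniform_head_cols(cfg$H, cfg$d)
  inv_sqrt_d <- 1 / sqrt(cfg$d)
  layers <- if (want_cache) vector("list", cfg$L) else NULL
  for (l in seq_len(cfg$L)) {
    dead <- if (!is.null(alive)) setdiff(seq_len(nrow(Tl)), alive[[l]]) else integer(0)
    use_patch <- cfg$search_patch && !patch_bypass && !is.null(masks)
    s <- if (use_patch) tanh(masks$patch[[l]]) else NULL
    Tin <- Tl
    Tm <- if (use_patch) Tin * s else Tin
    if (length(dead)) Tm[dead, ] <- 0
    at <- mhsa_block(model$params, l, Tm, head_cols, inv_sqrt_d,
                     z_flat = if (is.null(masks)) NULL else flat_heads(masks$mhsa[[l]]),
                     dead = dead, cache = want_cache)
    T1 <- if (cfg$residual) Tm + at$out else at$out
    if (length(dead)) T1[dead, ] <- 0
    ml <- mlp_block(model$params, l, T1,
                    z = if (is.null(masks)) NULL else masks$mlp[[l]],
                    cache = want_cache)
    Tl <- if (cfg$residual) T1 + ml$out else ml$out
    if (length(dead)) Tl[dead, ] <- 0
    if (want_cache) {
      layers[[l]] <- list(Tin = Tin, s = s, attn = at$cache, mlp = ml$cache)
    }
  }
  if (!all(is.finite(Tl))) stop("non-finite encoder activations")
  list(out = Tl, cache = layers)
}

# Backward through all encoder layers (soft masks, no dead tokens).
# Returns flat named param grads, mask grads (same shapes as the mask set),
# and the gradient w.r.t. the input tokens.
encoder_backward <- function(model, cache, dOut, masks = model$masks) {
  cfg <- model$config
  grads <- list()
  dmasks <- list(
    mhsa  = replicate(cfg$L, matrix(0, cfg$H, cfg$d), simplify = FALSE),
    mlp   = replicate(cfg$L, numeric(cfg$M), simplify = FALSE),
    patch = replicate(cfg$L, numeric(cfg$N), simplify = FALSE)
  )
  dT <- dOut
  head_cols <- uniform_head_cols(cfg$H, cfg$d)
  inv_sqrt_d <- 1 / sqrt(cfg$d)
  for (l in rev(seq_len(cfg$L))) {
    cc <- cache[[l]]
    zm <- if (is.null(masks)) NULL else masks$mlp[[l]]
    mb <- mlp_backward(model$params, l, cc$mlp, zm, dT)
    grads <- acc_grads(grads, mb$grads)
    if (!is.null(mb$dz)) dmasks$mlp[[l]] <- mb$dz
    za <- if (is.null(masks)) NULL else flat_heads(masks$mhsa[[l]])
    dT1 <- if (cfg$residual) dT + mb$dTm else mb$dTm
    ab <- mhsa_backward(model$params, l, cc$attn, head_cols, inv_sqrt_d,
                        z_flat = za, dOut = dT1)
    grads <- acc_grads(grads, ab$grads)
    if (!is.null(ab$dz_flat)) {
      dmasks$mhsa[[l]] <- t(matrix(ab$dz_flat, cfg$d, cfg$H))
    }
    dTm <- if (cfg$residual) dT1 + ab$dTm else ab$dTm
    if (!is.null(cc$s)) {
      ds <- rowSums(dTm * cc$Tin)
      dmasks$patch[[l]] <- ds * (1 - cc$s^2)
      dT <- dTm * cc$s
    } else {
      dT <- dTm
    }
  }
  list(grads = grads, dmasks = dmasks, dT0 = dT)
}

acc_grads <- function(acc, g) {
  for (nm in names(g)) {
    acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
  }
  acc
}
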