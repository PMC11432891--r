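# Single-round sparsity search: weights and masks are co-trained by AdamW
# under cross-entropy plus L1 mask penalties, then every searchable site is
# ranked by mask magnitude.

# -- loss pieces -------------------------------------------------------------

softmax_ce <- function(logits, y0) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(n), y0 + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n)
}

# L1 penalty of a mask set under the config's sparsity weights; patch
# scores are penalized through their tanh-bounded values
mask_penalty <- function(masks, config) {
  pm <- config$w_mhsa * sum(vapply(masks$mhsa, function(z) sum(abs(z)), numeric(1)))
  pl <- config$w_mlp * sum(vapply(masks$mlp, function(z) sum(abs(z)), numeric(1)))
  pp <- config$w_patch * sum(vapply(masks$patch, function(z) sum(abs(tanh(z))), numeric(1)))
  c(mhsa = pm, mlp = pl, patch = pp)
}

mask_penalty_grads <- function(masks, config) {
  list(
    mhsa = lapply(masks$mhsa, function(z) config$w_mhsa * sign(z)),
    mlp = lapply(masks$mlp, function(z) config$w_mlp * sign(z)),
    patch = lapply(masks$patch, function(z) {
      th <- tanh(z)
      config$w_patch * sign(th) * (1 - th^2)
    })
  )
}

#' Combined search objective: cross-entropy plus L1 mask penalty
#'
#' Returns `CE(logits, targets) + w_mhsa sum|z_mhsa| + w_mlp sum|z_mlp| +
#' w_patch sum|tanh(z_patch)|`, with both components retrievable from the
#' `"components"` attribute. The penalty is added once (not per pixel).
#'
#' @param logits `n x C` class-score matrix (pixels or sequences in rows).
#' @param targets Integer 0-based labels: a vector or a label matrix
#'   aligned with the rows of `logits`.
#' @param masks A [mask_set()].
#' @param config The [search_space_config()] carrying the sparsity weights.
#' @return Scalar loss with attribute `components = c(ce =, l1 =)`.
#' @export
search_loss <- function(logits, targets, masks, config) {
  y0 <- as.integer(as.vector(targets))
  if (length(y0) != nrow(logits)) {
    stop("logits and targets are not aligned")
  }
  ce <- softmax_ce(logits, y0)$loss
  l1 <- sum(mask_penalty(masks, config))
  structure(ce + l1, components = c(ce = ce, l1 = l1))
}

# -- AdamW -------------------------------------------------------------------

adamw_new <- function() list(m = list(), v = list(), t = 0L)

# decoupled weight decay on weight matrices only; biases and masks are
# never decayed (the L1 penalty is the only shrinkage applied to masks)
adamw_step <- function(opt, values, grads, lr, weight_decay, decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    if (is.null(opt$m[[nm]])) {
      opt$m[[nm]] <- gr * 0; opt$v[[nm]] <- gr * 0
    }
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * gr
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * gr^2
    step <- (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    if (decay[[nm]]) step <- step + weight_decay * values[[nm]]
    values[[nm]] <- values[[nm]] - lr * step
  }
  list(opt = opt, values = values)
}

# -- batched loss/gradient dispatch ------------------------------------------

# flatten a mask set into optimizer-addressable entries
masks_to_flat <- function(masks, config, which_kinds) {
  out <- list()
  for (l in seq_len(config$L)) {
    if (which_kinds["mhsa"]) out[[paste0("z.mhsa.", l)]] <- masks$mhsa[[l]]
    if (which_kinds["mlp"]) out[[paste0("z.mlp.", l)]] <- masks$mlp[[l]]
    if (which_kinds["patch"]) out[[paste0("z.patch.", l)]] <- masks$patch[[l]]
  }
  out
}

flat_to_masks <- function(flat, masks) {
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    masks[[parts[2]]][[as.integer(parts[3])]] <- flat[[nm]]
  }
  masks
}

# mean loss and gradients over one minibatch; dispatches on model class.
# Per-image processing keeps each image's pixel-stage working set inside
# cache, which measures faster here than stacking the batch.
batch_loss_grads <- function(model, samples, train_masks = FALSE) {
  B <- length(samples)
  acc_g <- list(); acc_dm <- NULL; ce <- 0
  for (s in samples) {
    if (inherits(model, "vitslim_segmodel")) {
      fw <- seg_forward(model, s$image, want_cache = TRUE)
      sc <- softmax_ce(fw$logits, as.integer(as.vector(s$label)))
      dfield <- NULL
      if (model$config$df) {
        tissue <- as.vector(s$label) > 0
        nt <- max(sum(tissue), 1L)
        diff <- fw$field - s$field
        diff[!tissue, ] <- 0
        lf <- sum(diff^2) / nt
        ce <- ce + model$config$df_weight * lf / B
        dfield <- (2 * model$config$df_weight / (nt * B)) * diff
      }
      bw <- seg_backward(model, fw$cache, sc$dlogits / B, dfield)
    } else {  # token classifier
      fw <- tok_forward(model, s$tokens, want_cache = TRUE)
      sc <- softmax_ce(fw$logits, s$y - 1L)
      bw <- tok_backward(model, fw$cache, sc$dlogits / B)
    }
    ce <- ce + sc$loss / B
    acc_g <- acc_grads(acc_g, bw$grads)
    if (train_masks && !is.null(bw$dmasks)) {
      acc_dm <- if (is.null(acc_dm)) bw$dmasks else {
        list(mhsa = Map(`+`, acc_dm$mhsa, bw$dmasks$mhsa),
             mlp = Map(`+`, acc_dm$mlp, bw$dmasks$mlp),
             patch = Map(`+`, acc_dm$patch, bw$dmasks$patch))
      }
    }
  }
  list(ce = ce, grads = acc_g, dmasks = acc_dm)
}

space_of <- function(model) {
  if (inherits(model, "vitslim_segmodel")) model$space else model$config
}

# shared AdamW loop for the search phase (with masks and penalty) and the
# retraining phase (weights only)
train_loop <- function(model, data, epochs, seed, lr, weight_decay, batch,
                       search, verbose = FALSE) {
  cfg <- space_of(model)
  which_kinds <- c(mhsa = cfg$search_mhsa, mlp = cfg$search_mlp,
                   patch = cfg$search_patch)
  train_masks <- search && any(which_kinds) && !is.null(model$masks)
  opt <- adamw_new()
  trace <- data.frame(epoch = integer(0), ce = numeric(0), l1 = numeric(0))
  decay <- NULL
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(data))
      ce_ep <- 0; nb <- 0
      for (start in seq(1, length(data), by = batch)) {
        ids <- ord[start:min(start + batch - 1L, length(data))]
        bl <- batch_loss_grads(model, data[ids], train_masks = train_masks)
        if (!is.finite(bl$ce)) {
          stop(sprintf("non-finite loss at epoch %d (cross-entropy term)", ep))
        }
        values <- model$params
        grads <- bl$grads
        if (train_masks) {
          pg <- mask_penalty_grads(model$masks, cfg)
          dm <- bl$dmasks
          dm$mhsa <- Map(`+`, dm$mhsa, pg$mhsa)
          dm$mlp <- Map(`+`, dm$mlp, pg$mlp)
          dm$patch <- Map(`+`, dm$patch, pg$patch)
          zflat <- masks_to_flat(model$masks, cfg, which_kinds)
          gflat <- masks_to_flat(dm, cfg, which_kinds)
          values <- c(values, zflat)
          grads <- c(grads, gflat)
        }
        if (is.null(decay) || length(decay) != length(values)) {
          decay <- grepl("\\.W", names(values)) & !grepl("^z\\.", names(values))
          names(decay) <- names(values)
        }
        upd <- adamw_step(opt, values, grads, lr, weight_decay, decay)
        opt <- upd$opt
        pn <- names(model$params)
        model$params <- upd$values[pn]
        if (train_masks) {
          model$masks <- flat_to_masks(upd$values[setdiff(names(values), pn)],
                                       model$masks)
        }
        ce_ep <- ce_ep + bl$ce; nb <- nb + 1
      }
      l1_ep <- if (!is.null(model$masks)) sum(mask_penalty(model$masks, cfg)) else 0
      if (!is.finite(l1_ep)) {
        stop(sprintf("non-finite loss at epoch %d (L1 term)", ep))
      }
      trace <- rbind(trace, data.frame(epoch = ep, ce = ce_ep / max(nb, 1),
                                       l1 = l1_ep))
      if (verbose) {
        message(sprintf("epoch %3d  CE %.5f  L1 %.6f", ep, ce_ep / max(nb, 1),
                        l1_ep))
      }
    }
  })
  list(model = model, trace = trace)
}

#' Run the single-round sparsity search
#'
#' Co-trains network weights and importance masks with AdamW, minimizing
#' [search_loss()] (cross-entropy plus the L1 mask penalties configured in
#' the search space). Deterministic under a fixed seed and data order. With
#' `epochs = 0` the masks are returned unchanged (all ones for a fresh
#' model).
#'
#' @param model A supernet-backed `vitslim_segmodel` or a token-classifier
#'   model from [generate_planted_task()].
#' @param data List of training samples (`image`/`label` pairs or
#'   `tokens`/`y` pairs).
#' @param epochs Training epochs (default 50).
#' @param seed Integer seed controlling shuffling (and nothing else; the
#'   model carries its own initialization).
#' @param lr,weight_decay AdamW settings (defaults 1e-3 and 1e-2; decoupled
#'   decay applies to weight matrices only, never to masks or biases).
#' @param batch Minibatch size.
#' @param verbose Log both loss terms per epoch.
#' @return `vitslim_search` object: the trained `model`, its `masks`, the
#'   per-epoch `trace` (CE and L1 terms separately), `epochs`, `optimizer`
#'   settings and `seed`.
#' @export
run_search <- function(model, data, epochs = 50L, seed = 0L, lr = 1e-3,
                       weight_decay = 1e-2, batch = 16L, verbose = FALSE) {
  stopifnot(length(data) > 0)
  if (model$config$df %||% FALSE) data <- ensure_fields(data)
  res <- train_loop(model, data, epochs, seed, lr, weight_decay, batch,
                    search = TRUE, verbose = verbose)
  structure(list(model = res$model, masks = res$model$masks,
                 trace = res$trace, epochs = as.integer(epochs),
                 optimizer = list(algorithm = "AdamW", lr = lr,
                                  weight_decay = weight_decay, batch = batch),
                 seed = as.integer(seed)),
            class = "vitslim_search")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# precompute ground-truth direction fields for DF training targets
ensure_fields <- function(data) {
  lapply(data, function(s) {
    if (is.null(s$field) && !is.null(s$label)) {
      s$field <- gt_direction_field(s$label)
    }
    s
  })
}

#' Retrain an extracted (or any) model without the sparsity penalty
#'
#' Optimizes cross-entropy (plus the field loss when the DF module is
#' enabled) with the same AdamW settings as the search; masks are not
#' trained. With `epochs = 0` the weights are returned unchanged.
#'
#' @inheritParams run_search
#' @return `vitslim_search`-shaped object with the retrained model and
#'   loss trace (`l1` column reports the frozen mask penalty, 0 for sliced
#'   models).
#' @export
retrain <- function(model, data, epochs = 50L, seed = 0L, lr = 1e-3,
                    weight_decay = 1e-2, batch = 16L, verbose = FALSE) {
  stopifnot(length(data) > 0)
  if (model$config$df %||% FALSE) data <- ensure_fields(data)
  res <- train_loop(model, data, epochs, seed, lr, weight_decay, batch,
                    search = FALSE, verbose = verbose)
  structure(list(model = res$model, masks = res$model$masks,
                 trace = res$trace, epochs = as.integer(epochs),
                 optimizer = list(algorithm = "AdamW", lr = lr,
                                  weight_decay = weight_decay, batch = batch),
                 seed = as.integer(seed)),
            class = "vitslim_search")
}

# -- ranking -----------------------------------------------------------------

#' Rank all searchable sites by mask importance
#'
#' Scores are `|z|` for MHSA and MLP dimensions and `|tanh(z)|` for patch
#' scores: the L1 penalty drives magnitudes toward zero, and a negative
#' mask of large magnitude still transmits signal, so elimination targets
#' low influence rather than low signed value. The result is ascending by
#' score within each kind, ties broken by (layer, head, index), stable and
#' total: every site appears exactly once.
#'
#' @param masks A (trained) [mask_set()].
#' @param config The matching [search_space_config()].
#' @return Data frame with columns `kind` ("mhsa-dim", "mlp-dim", "patch"),
#'   `layer`, `head` (NA outside mhsa), `index`, `score`.
#' @export
rank_dimensions <- function(masks, config) {
  rows <- list()
  for (l in seq_len(config$L)) {
    z <- masks$mhsa[[l]]
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "mhsa-dim", layer = l,
      head = rep(seq_len(config$H), times = config$d),
      index = rep(seq_len(config$d), each = config$H),
      score = abs(as.vector(z)))
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "mlp-dim", layer = l, head = NA_integer_,
      index = seq_len(config$M), score = abs(masks$mlp[[l]]))
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "patch", layer = l, head = NA_integer_,
      index = seq_len(config$N), score = abs(tanh(masks$patch[[l]])))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$kind, df$score, df$layer, df$head, df$index,
                 na.last = FALSE), ]
  rownames(df) <- NULL
  df
}
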