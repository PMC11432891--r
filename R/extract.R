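# Budget-based subnet extraction: convert a trained mask set plus a kept
# fraction per kind into a compact sliced network, enforce the patch
# monotonicity rule, and account for parameters and FLOPs.

#' Budget specification
#'
#' Fraction of searchable sites kept per kind, network-wide. The kept count
#' per kind is `ceiling(fraction * total sites)` so a stated budget is never
#' undershot.
#'
#' @param mhsa,mlp,patch Fractions in `(0, 1]`.
#' @return An object of class `vitslim_budget`.
#' @export
budget_spec <- function(mhsa = 1, mlp = 1, patch = 1) {
  b <- c(mhsa = mhsa, mlp = mlp, patch = patch)
  if (any(b <= 0) || any(b > 1)) stop("budget fractions must lie in (0, 1]")
  structure(as.list(b), class = "vitslim_budget")
}

#' Select a subnet under a budget
#'
#' Keeps, per kind and globally across all layers and heads, the
#' `ceiling(fraction x total)` highest-scoring sites of the ranking; the
#' per-layer kept counts may therefore differ (the budget is network-wide,
#' which is what permits varying dimensions across attention heads).
#' The returned patch kept-sets are the raw selection; apply
#' [enforce_patch_monotonicity()] before slicing.
#'
#' @param ranking A [rank_dimensions()] data frame (ascending by score).
#' @param budget A [budget_spec()].
#' @param config The [search_space_config()] the ranking came from.
#' @return An object of class `vitslim_subnet`: kept 1-based index lists
#'   `mhsa[[layer]][[head]]`, `mlp[[layer]]`, `patch[[layer]]`, plus the
#'   budget and a ranking checksum as provenance.
#' @export
select_budget <- function(ranking, budget, config) {
  stopifnot(inherits(budget, "vitslim_budget"),
            inherits(config, "vitslim_config"))
  keep_kind <- function(kind, frac) {
    rows <- ranking[ranking$kind == kind, , drop = FALSE]
    n <- nrow(rows)
    n_keep <- as.integer(ceiling(frac * n))
    rows[seq.int(n - n_keep + 1L, n), , drop = FALSE]  # top scores = tail
  }
  kept_mhsa <- keep_kind("mhsa-dim", budget$mhsa)
  kept_mlp <- keep_kind("mlp-dim", budget$mlp)
  kept_patch <- keep_kind("patch", budget$patch)
  spec <- list(
    mhsa = lapply(seq_len(config$L), function(l) {
      lapply(seq_len(config$H), function(h) {
        sort(kept_mhsa$index[kept_mhsa$layer == l & kept_mhsa$head == h])
      })
    }),
    mlp = lapply(seq_len(config$L), function(l) {
      sort(kept_mlp$index[kept_mlp$layer == l])
    }),
    patch = lapply(seq_len(config$L), function(l) {
      sort(kept_patch$index[kept_patch$layer == l])
    }),
    budget = unclass(budget),
    checksum = sum(ranking$score)
  )
  structure(spec, class = "vitslim_subnet")
}

#' Enforce the patch monotonicity rule
#'
#' The global single-round search can occasionally keep a patch in a deep
#' layer whose shallower counterpart was eliminated; once a patch dies in
#' an earlier layer it must stay dead in all subsequent layers. This
#' replaces each layer's kept set by its running intersection with all
#' shallower layers — only removals, never additions.
#'
#' @param spec A `vitslim_subnet`.
#' @return The spec with monotone patch kept-sets.
#' @export
enforce_patch_monotonicity <- function(spec) {
  stopifnot(inherits(spec, "vitslim_subnet"))
  cur <- spec$patch[[1]]
  for (l in seq_along(spec$patch)) {
    cur <- intersect(cur, spec$patch[[l]])
    spec$patch[[l]] <- sort(cur)
  }
  spec
}

#' A subnet spec keeping every site (the full architecture)
#'
#' @param config A [search_space_config()].
#' @return A `vitslim_subnet` with all sites kept.
#' @export
full_subnet_spec <- function(config) {
  structure(list(
    mhsa = replicate(config$L,
                     replicate(config$H, seq_len(config$d), simplify = FALSE),
                     simplify = FALSE),
    mlp = replicate(config$L, seq_len(config$M), simplify = FALSE),
    patch = replicate(config$L, seq_len(config$N), simplify = FALSE),
    budget = list(mhsa = 1, mlp = 1, patch = 1),
    checksum = NA_real_
  ), class = "vitslim_subnet")
}

#' Draw a random subnet spec (testing and benchmarking utility)
#'
#' Builds a ranking from random scores and applies [select_budget()] and
#' [enforce_patch_monotonicity()], so the result satisfies all spec
#' invariants.
#'
#' @param config A [search_space_config()].
#' @param seed Integer seed.
#' @param budget A [budget_spec()]; defaults to fractions drawn in
#'   `[0.4, 1]`.
#' @return A `vitslim_subnet`.
#' @export
random_subnet_spec <- function(config, seed, budget = NULL) {
  withr::with_seed(seed, {
    if (is.null(budget)) {
      budget <- budget_spec(stats::runif(1, 0.4, 1), stats::runif(1, 0.4, 1),
                            stats::runif(1, 0.4, 1))
    }
    masks <- mask_set(config)
    for (l in seq_len(config$L)) {
      masks$mhsa[[l]][] <- stats::rnorm(config$H * config$d)
      masks$mlp[[l]] <- stats::rnorm(config$M)
      masks$patch[[l]] <- stats::rnorm(config$N)
    }
    enforce_patch_monotonicity(
      select_budget(rank_dimensions(masks, config), budget, config))
  })
}

# binarized masks + per-layer alive token sets implied by a spec
spec_to_binary <- function(spec, config) {
  masks <- mask_set(config)
  for (l in seq_len(config$L)) {
    zb <- matrix(0, config$H, config$d)
    for (h in seq_len(config$H)) zb[h, spec$mhsa[[l]][[h]]] <- 1
    masks$mhsa[[l]] <- zb
    masks$mlp[[l]] <- as.numeric(seq_len(config$M) %in% spec$mlp[[l]])
    masks$patch[[l]] <- as.numeric(seq_len(config$N) %in% spec$patch[[l]])
  }
  list(masks = masks, alive = spec$patch)
}

#' Slice a supernet into a compact model
#'
#' Physically extracts the kept rows/columns of the q/k/v, projection and
#' MLP weight matrices (with their biases), removes eliminated patches from
#' the token sequence at the first layer where they die, and zero-fills
#' their grid positions when tokens are re-assembled for the decoder. Heads
#' whose entire dimension set is dropped disappear as whole heads. The
#' compact forward pass equals the masked supernet with binarized masks
#' (kept -> 1, dropped -> 0, kept patches bypassing tanh).
#'
#' @param model A `vitslim_supernet` or a supernet-backed
#'   `vitslim_segmodel`.
#' @param spec A `vitslim_subnet` (patch sets must be monotone; enforced
#'   here for safety).
#' @return A compact model of class `vitslim_compact` (bare encoder) or
#'   `c("vitslim_compactseg", "vitslim_segmodel")`.
#' @export
slice_supernet <- function(model, spec) {
  stopifnot(inherits(spec, "vitslim_subnet"))
  spec <- enforce_patch_monotonicity(spec)
  cfg <- if (inherits(model, "vitslim_segmodel")) model$space else model$config
  d <- cfg$d
  if (any(vapply(rapply(spec$mhsa, function(i) any(i > d | i < 1), how = "unlist"),
                 isTRUE, logical(1)))) {
    stop("kept mhsa index out of range")
  }
  params <- model$params
  meta <- vector("list", cfg$L)
  for (l in seq_len(cfg$L)) {
    pre <- function(nm) paste0("l", l, ".", nm)
    keep_cols <- integer(0); sizes <- integer(cfg$H)
    for (h in seq_len(cfg$H)) {
      idx <- spec$mhsa[[l]][[h]]
      sizes[h] <- length(idx)
      keep_cols <- c(keep_cols, (h - 1L) * d + idx)
    }
    if (any(spec$mlp[[l]] > cfg$M | spec$mlp[[l]] < 1)) {
      stop("kept mlp index out of range")
    }
    for (nm in c("Wq", "Wk", "Wv")) {
      params[[pre(nm)]] <- params[[pre(nm)]][, keep_cols, drop = FALSE]
    }
    for (nm in c("bq", "bk", "bv")) {
      params[[pre(nm)]] <- params[[pre(nm)]][keep_cols]
    }
    params[[pre("Wo")]] <- params[[pre("Wo")]][keep_cols, , drop = FALSE]
    mk <- spec$mlp[[l]]
    params[[pre("W1")]] <- params[[pre("W1")]][, mk, drop = FALSE]
    params[[pre("b1")]] <- params[[pre("b1")]][mk]
    params[[pre("W2")]] <- params[[pre("W2")]][mk, , drop = FALSE]
    off <- c(0L, cumsum(sizes))
    meta[[l]] <- list(
      head_cols = lapply(seq_len(cfg$H),
                         function(h) if (sizes[h]) (off[h] + 1L):off[h + 1L] else integer(0)),
      sizes = sizes, m = length(mk))
  }
  alive <- lapply(spec$patch, sort)
  if (inherits(model, "vitslim_segmodel")) {
    out <- model
    out$params <- params
    out$masks <- NULL
    out$spec <- spec
    out$layer_meta <- meta
    out$alive <- alive
    class(out) <- c("vitslim_compactseg", "vitslim_segmodel")
  } else {
    out <- structure(list(config = cfg, params = params, spec = spec,
                          layer_meta = meta, alive = alive),
                     class = "vitslim_compact")
  }
  out
}

# Forward through the sliced encoder. T0 has one row per patch alive at
# layer 1; the result is re-assembled to the full N x D grid with zeros at
# eliminated positions.
compact_encoder_forward <- function(model, T0, want_cache = FALSE) {
  cfg <- if (inherits(model, "vitslim_segmodel")) model$space else model$config
  inv_sqrt_d <- 1 / sqrt(cfg$d)
  Tl <- T0
  cur <- model$alive[[1]]
  if (nrow(Tl) != length(cur)) stop("T0 rows must match layer-1 alive patches")
  layers <- if (want_cache) vector("list", cfg$L) else NULL
  for (l in seq_len(cfg$L)) {
    sel <- match(model$alive[[l]], cur)
    if (anyNA(sel)) stop("patch kept-sets are not monotone")
    Tm <- Tl[sel, , drop = FALSE]
    cur <- model$alive[[l]]
    at <- mhsa_block(model$params, l, Tm, model$layer_meta[[l]]$head_cols,
                     inv_sqrt_d, cache = want_cache)
    T1 <- if (cfg$residual) Tm + at$out else at$out
    ml <- mlp_block(model$params, l, T1, cache = want_cache)
    Tl <- if (cfg$residual) T1 + ml$out else ml$out
    if (want_cache) layers[[l]] <- list(sel = sel, attn = at$cache, mlp = ml$cache)
  }
  G <- matrix(0, cfg$N, cfg$D)
  G[cur, ] <- Tl
  if (want_cache) list(out = G, cache = layers) else list(out = G)
}

# Backward through the sliced encoder; dG is the N x D gradient at the
# zero-filled grid. Returns parameter grads and the gradient w.r.t. T0.
compact_encoder_backward <- function(model, cache, dG) {
  cfg <- if (inherits(model, "vitslim_segmodel")) model$space else model$config
  inv_sqrt_d <- 1 / sqrt(cfg$d)
  L <- cfg$L
  grads <- list()
  dT <- dG[model$alive[[L]], , drop = FALSE]
  for (l in rev(seq_len(L))) {
    cc <- cache[[l]]
    mb <- mlp_backward(model$params, l, cc$mlp, NULL, dT)
    grads <- acc_grads(grads, mb$grads)
    dT1 <- if (cfg$residual) dT + mb$dTm else mb$dTm
    ab <- mhsa_backward(model$params, l, cc$attn,
                        model$layer_meta[[l]]$head_cols, inv_sqrt_d,
                        dOut = dT1)
    grads <- acc_grads(grads, ab$grads)
    dTm <- if (cfg$residual) dT1 + ab$dTm else ab$dTm
    # scatter back to the previous layer's token set
    n_prev <- if (l > 1) length(model$alive[[l - 1]]) else length(model$alive[[1]])
    dT <- matrix(0, n_prev, cfg$D)
    dT[cc$sel, ] <- dTm
  }
  list(grads = grads, dT0 = dT)
}

#' Closed-form parameter count of an encoder subnet
#'
#' Each kept MHSA head dimension costs `3 (D + 1)` (one biased output
#' column in each of q, k, v) plus `D` (one projection input row); each
#' kept MLP hidden dimension costs `(D + 1) + D`. Non-searchable encoder
#' parameters (projection and second-MLP biases, `2 D` per layer) are
#' reported separately. Equals exhaustive tensor-size enumeration on the
#' sliced encoder, exactly.
#'
#' @param spec A `vitslim_subnet`.
#' @param config The matching [search_space_config()].
#' @return Integer total encoder parameter count, with attribute
#'   `breakdown` = `c(searchable =, fixed =)`.
#' @export
count_params <- function(spec, config) {
  D <- config$D
  n_mhsa <- sum(unlist(lapply(spec$mhsa, function(ll) lengths(ll))))
  n_mlp <- sum(lengths(spec$mlp))
  searchable <- n_mhsa * (3 * (D + 1) + D) + n_mlp * (2 * D + 1)
  fixed <- config$L * 2 * D
  structure(as.integer(searchable + fixed),
            breakdown = c(searchable = searchable, fixed = fixed))
}

#' Closed-form FLOP count of an encoder subnet
#'
#' Counts multiply-accumulate operations (1 MAC = 1 reported FLOP) of the
#' encoder forward pass. Token-wise linear costs scale with the per-layer
#' active patch count `N_l`; the attention score and apply terms scale with
#' `N_l^2`.
#'
#' @inheritParams count_params
#' @return Numeric total MAC count with attribute `breakdown` (named
#'   vector: qkv, attn_scores, attn_apply, proj, mlp).
#' @export
count_flops <- function(spec, config) {
  D <- config$D
  qkv <- scores <- apply_ <- proj <- mlp <- 0
  for (l in seq_len(config$L)) {
    Nl <- length(spec$patch[[l]])
    dk <- lengths(spec$mhsa[[l]])
    qkv <- qkv + 3 * Nl * D * sum(dk)
    scores <- scores + Nl^2 * sum(dk)
    apply_ <- apply_ + Nl^2 * sum(dk)
    proj <- proj + Nl * sum(dk) * D
    mlp <- mlp + 2 * Nl * D * length(spec$mlp[[l]])
  }
  structure(qkv + scores + apply_ + proj + mlp,
            breakdown = c(qkv = qkv, attn_scores = scores,
                          attn_apply = apply_, proj = proj, mlp = mlp))
}

#' Serialize a subnet spec to JSON
#'
#' Index lists are written 0-based and sorted; grids are row-major. The
#' inverse is [read_subnet_spec()].
#'
#' @param spec A `vitslim_subnet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subnet_spec <- function(spec, path) {
  out <- list(
    index_base = 0L,
    mhsa = lapply(spec$mhsa, function(ll) lapply(ll, function(i) as.integer(i - 1L))),
    mlp = lapply(spec$mlp, function(i) as.integer(i - 1L)),
    patch = lapply(spec$patch, function(i) as.integer(i - 1L)),
    budget = spec$budget,
    checksum = spec$checksum
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a subnet spec from JSON
#'
#' @param path Path written by [write_subnet_spec()].
#' @return A `vitslim_subnet`.
#' @export
read_subnet_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_i <- function(x) as.integer(unlist(x)) + 1L
  structure(list(
    mhsa = lapply(raw$mhsa, function(ll) lapply(ll, as_i)),
    mlp = lapply(raw$mlp, as_i),
    patch = lapply(raw$patch, as_i),
    budget = lapply(raw$budget, function(b) as.numeric(b)),
    checksum = if (is.null(raw$checksum)) NA_real_ else as.numeric(raw$checksum)
  ), class = "vitslim_subnet")
}
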