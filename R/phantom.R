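# Synthetic data with the statistical structure the method assumes:
# cardiac-like ring phantoms (short-axis view: bright LV blood pool inside
# a mid-grey myocardial ring, with an adjacent RV crescent) for
# segmentation, and planted-importance token tasks for validating that the
# sparsity search recovers the dimensions that carry signal.

# documented area-fraction contract of the generator (fractions of image
# area per class, padded for pixel discretization); tests check against it
phantom_area_bounds <- list(
  lv = c(0.015, 0.105), myo = c(0.02, 0.16), rv = c(0.005, 0.14))

#' Generate one cardiac-like phantom
#'
#' Draws concentric ellipses (bright LV cavity, mid-grey MYO ring, adjacent
#' RV crescent on a dark background) with randomized center, radii and
#' intensities, applies Gaussian boundary blur and additive Gaussian noise,
#' and clamps to `[0, 1]`. Labels are the pre-blur geometry: 0 background,
#' 1 RV-like, 2 MYO-like (a ring strictly between the LV interior and
#' background), 3 LV-like. Degenerate geometry is rejected and resampled.
#' Regeneration with the same arguments is bit-identical.
#'
#' @param seed Integer seed.
#' @param size Image side length (>= 32).
#' @param noise_sigma Additive Gaussian noise sd (image intensity units).
#' @param blur_sigma Gaussian blur sd in pixels (0 disables).
#' @return A list of class `vitslim_phantom`: `image` (`size x size` in
#'   `[0,1]`), `label` (integer matrix), `meta` (seed, center, radii,
#'   intensities, sigmas).
#' @export
generate_phantom <- function(seed, size = 64L, noise_sigma = 0.05,
                             blur_sigma = 1.0) {
  if (size < 32) stop("size must be >= 32")
  withr::with_seed(seed, {
    for (try in 1:20) {
      cx <- size / 2 + stats::runif(1, -0.06, 0.06) * size
      cy <- size / 2 + stats::runif(1, -0.06, 0.06) * size
      r_lv <- stats::runif(1, 0.10, 0.16) * size
      th <- stats::runif(1, 0.05, 0.09) * size
      r_myo <- r_lv + th
      asp <- stats::runif(1, 0.85, 1.15)
      r_rv <- stats::runif(1, 0.10, 0.16) * size
      rv_asp <- stats::runif(1, 0.55, 0.85)
      rv_cx <- cx - (r_myo + 0.35 * r_rv)
      rv_cy <- cy + stats::runif(1, -0.05, 0.05) * size
      ok <- (cx + r_myo < size - 2) && (cx - r_myo > 2) &&
        (cy + r_myo / asp < size - 2) && (cy - r_myo / asp > 2) &&
        (rv_cx - r_rv > 1)
      if (ok) break
    }
    if (!ok) stop("could not sample non-degenerate phantom geometry")
    y <- matrix(rep(seq_len(size) - 1, size), size, size)        # row = y
    x <- matrix(rep(seq_len(size) - 1, each = size), size, size) # col = x
    in_ell <- function(ecx, ecy, rx, ry) {
      ((x - ecx) / rx)^2 + ((y - ecy) / ry)^2 <= 1
    }
    lv <- in_ell(cx, cy, r_lv, r_lv / asp)
    myo_out <- in_ell(cx, cy, r_myo, r_myo / asp)
    rv <- in_ell(rv_cx, rv_cy, r_rv, r_rv * rv_asp) & !myo_out
    label <- matrix(0L, size, size)
    label[rv] <- 1L
    label[myo_out & !lv] <- 2L
    label[lv] <- 3L
    ints <- c(bg = 0.15 + stats::rnorm(1, 0, 0.02),
              rv = 0.70 + stats::rnorm(1, 0, 0.04),
              myo = 0.45 + stats::rnorm(1, 0, 0.03),
              lv = 0.85 + stats::rnorm(1, 0, 0.04))
    img <- matrix(ints["bg"], size, size)
    img[rv] <- ints["rv"]
    img[myo_out & !lv] <- ints["myo"]
    img[lv] <- ints["lv"]
    if (blur_sigma > 0) {
      img <- matrix(EBImage::imageData(EBImage::gblur(img, sigma = blur_sigma)),
                    size, size)
    }
    if (noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(size * size, 0, noise_sigma), size, size)
    }
    img <- pmin(pmax(img, 0), 1)
    structure(list(
      image = img, label = label,
      meta = list(seed = seed, size = size, center = c(cx, cy),
                  r_lv = r_lv, r_myo = r_myo, r_rv = r_rv, asp = asp,
                  rv_center = c(rv_cx, rv_cy), rv_asp = rv_asp,
                  intensities = ints, noise_sigma = noise_sigma,
                  blur_sigma = blur_sigma)
    ), class = "vitslim_phantom")
  })
}

#' Generate a phantom dataset with a train/val/test split
#'
#' Samples `n` phantoms with seeds derived deterministically from `seed`
#' and partitions them by sample (never by slice) into splits of sizes
#' given by the largest-remainder apportionment of the normalized ratios.
#'
#' @param seed Integer seed.
#' @param n Number of phantoms.
#' @param split Ratio triple (train, val, test); default 7:1:2.
#' @param ... Passed to [generate_phantom()] (`size`, `noise_sigma`,
#'   `blur_sigma`).
#' @return List with `train`, `val`, `test` (lists of phantoms) and
#'   `assignment` (character vector over sample ids).
#' @export
generate_dataset <- function(seed, n, split = c(7, 1, 2), ...) {
  if (length(split) != 3 || any(split < 0) || sum(split) == 0) {
    stop("split must be three non-negative ratios")
  }
  counts <- largest_remainder(n, split / sum(split))
  if (counts[1] == 0 || counts[3] == 0) {
    stop("n too small for a non-empty train and test split")
  }
  base_seed <- (as.numeric(seed) * 100003) %% 2147480000
  samples <- lapply(seq_len(n), function(i) {
    generate_phantom(seed = base_seed + i, ...)
  })
  ord <- withr::with_seed(seed, sample.int(n))
  assignment <- character(n)
  assignment[ord[seq_len(counts[1])]] <- "train"
  if (counts[2] > 0) {
    assignment[ord[counts[1] + seq_len(counts[2])]] <- "val"
  }
  assignment[ord[counts[1] + counts[2] + seq_len(counts[3])]] <- "test"
  list(train = samples[assignment == "train"],
       val = samples[assignment == "val"],
       test = samples[assignment == "test"],
       assignment = assignment)
}

largest_remainder <- function(n, frac) {
  base <- floor(frac * n)
  rem <- frac * n - base
  short <- n - sum(base)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Stack phantoms into a synthetic 3-D volume
#'
#' Emulates a short-axis cine-MR stack: `depth` phantoms with smoothly
#' varying radii, for exercising NIfTI slicing. Purely synthetic stand-in
#' for volumetric data.
#'
#' @param seed Integer seed.
#' @param depth Number of slices.
#' @param size Slice side length.
#' @return List with `image` and `label` 3-D arrays (`size x size x depth`).
#' @export
generate_phantom_volume <- function(seed, depth = 10L, size = 64L) {
  base_seed <- (as.numeric(seed) * 1009) %% 2147480000
  slices <- lapply(seq_len(depth), function(k) {
    generate_phantom(base_seed + k, size = size)
  })
  img <- array(0, c(size, size, depth))
  lab <- array(0L, c(size, size, depth))
  for (k in seq_len(depth)) {
    img[, , k] <- slices[[k]]$image
    lab[, , k] <- slices[[k]]$label
  }
  list(image = img, label = lab)
}

# ---- planted-importance task -----------------------------------------------

#' Generate a planted-importance search-validation task
#'
#' Constructs a token-classification problem in which class information is
#' carried only through `k_signal` designated MHSA head dimensions, split
#' across layers (without residual connections the signal must traverse
#' every layer, so `k_signal` must be >= L; infeasible routing errors out).
#' Per sequence, a binary label `y` shifts `m = min(per-layer counts)`
#' independent signal components; token inputs carry those components in
#' their first `m` coordinates (plus per-token noise) and pure noise in the
#' rest. The frozen construction routes coordinate `i` through the i-th
#' signal site of every layer: value projections read it, attention is
#' initialized uniform (zero q/k weights) so mean pooling preserves the
#' per-sequence signal, and the MLP is initialized to the exact ReLU
#' identity so routing survives the feed-forward block. Non-signal
#' dimensions receive independent noise coordinates.
#'
#' @param seed Integer seed.
#' @param config A [search_space_config()]; must have `residual = FALSE`
#'   and `M >= 2 D` (identity MLP needs both half-spaces).
#' @param k_signal Number of planted signal MHSA dimensions.
#' @param n_seq Number of sequences.
#' @param n_tokens Tokens per sequence.
#' @param effect Mean shift of a signal component per unit label.
#' @param token_noise Per-token noise sd on signal coordinates.
#' @return List of class `vitslim_planted`: `model` (token-classifier
#'   supernet), `data` (list of `tokens`/`y` samples), `signal_sites`
#'   (data frame layer/head/index), `config`, `seed`.
#' @export
generate_planted_task <- function(seed, config, k_signal, n_seq = 256L,
                                  n_tokens = 8L, effect = 1.0,
                                  token_noise = 0.5) {
  stopifnot(inherits(config, "vitslim_config"))
  total <- config$L * config$H * config$d
  if (k_signal > total) stop("k_signal exceeds searchable mhsa sites")
  if (k_signal > 0 && k_signal < config$L) {
    stop("infeasible routing: need at least one signal site per layer")
  }
  if (config$residual) {
    stop("planted task requires residual = FALSE (signal must traverse the masked pathway)")
  }
  if (config$M < 2 * config$D) {
    stop("identity MLP initialization needs M >= 2 D")
  }
  D <- config$D; L <- config$L
  withr::with_seed(seed, {
    # distribute signal sites across layers as evenly as possible
    per_layer <- rep(k_signal %/% L, L)
    extra <- k_signal %% L
    if (extra > 0) per_layer[seq_len(extra)] <- per_layer[seq_len(extra)] + 1
    sites <- lapply(seq_len(L), function(l) {
      if (per_layer[l] == 0) return(NULL)
      pick <- sample.int(config$H * config$d, per_layer[l])
      data.frame(layer = l, head = (pick - 1L) %/% config$d + 1L,
                 index = (pick - 1L) %% config$d + 1L)
    })
    sites <- do.call(rbind, sites)
    m <- if (k_signal > 0) min(per_layer) else 0L

    model <- build_supernet(config, seed = seed)
    for (l in seq_len(L)) {
      pre <- function(nm) paste0("l", l, ".", nm)
      Hd <- config$H * config$d
      # uniform attention: q/k projections start at zero
      model$params[[pre("Wq")]] <- matrix(0, D, Hd)
      model$params[[pre("Wk")]] <- matrix(0, D, Hd)
      # route coordinates through designated head dimensions
      Wv <- matrix(0, D, Hd)
      Wo <- matrix(0, Hd, D)
      here <- sites[sites$layer == l, , drop = FALSE]
      cols <- (here$head - 1L) * config$d + here$index
      noise_cols <- setdiff(seq_len(Hd), cols)
      if (m > 0) {
        comp <- ((seq_len(nrow(here)) - 1L) %% m) + 1L  # component per site
        Wv[cbind(comp, cols)] <- 1
        Wo[cbind(cols, comp)] <- 1
      }
      if (length(noise_cols) && D > m) {
        src <- m + ((seq_along(noise_cols) - 1L) %% (D - m)) + 1L
        Wv[cbind(src, noise_cols)] <- 1
        Wo[cbind(noise_cols, src)] <- 1
      }
      model$params[[pre("Wv")]] <- Wv
      model$params[[pre("Wo")]] <- Wo
      # exact ReLU identity MLP: f2(relu(f1(x))) = x
      W1 <- matrix(0, D, config$M)
      W1[, seq_len(D)] <- diag(D)
      W1[, D + seq_len(D)] <- -diag(D)
      W2 <- matrix(0, config$M, D)
      W2[seq_len(D), ] <- diag(D)
      W2[D + seq_len(D), ] <- -diag(D)
      model$params[[pre("W1")]] <- W1
      model$params[[pre("W2")]] <- W2
    }
    # pretrained readout: the search workflow starts from converged weights
    # (classifier reads the pooled signal coordinates), so mask gradients on
    # unused dimensions are near zero and the L1 penalty can act
    Wc <- matrix(0, D, 2)
    if (m > 0) {
      Wc[seq_len(m), 1] <- -1
      Wc[seq_len(m), 2] <- 1
    }
    model$params[["cls.W"]] <- Wc + rmat(D, 2, sd = 0.01)
    model$params[["cls.b"]] <- numeric(2)
    class(model) <- "vitslim_tokcls"

    data <- lapply(seq_len(n_seq), function(i) {
      y <- sample(1:2, 1)
      X <- matrix(stats::rnorm(n_tokens * D), n_tokens, D)
      if (m > 0) {
        u <- (2 * y - 3) * effect + stats::rnorm(m)
        X[, seq_len(m)] <- rep(u, each = n_tokens) +
          matrix(stats::rnorm(n_tokens * m, 0, token_noise), n_tokens, m)
      }
      list(tokens = X, y = y)
    })
    structure(list(model = model, data = data, signal_sites = sites,
                   n_components = m, config = config, seed = seed),
              class = "vitslim_planted")
  })
}

# token-classifier forward: encoder -> mean pooling -> linear head
tok_forward <- function(model, X, want_cache = FALSE) {
  enc <- encoder_forward(model, X, masks = model$masks,
                         want_cache = want_cache)
  pooled <- colMeans(enc$out)
  logits <- matrix(pooled, 1) %*% model$params[["cls.W"]] +
    model$params[["cls.b"]]
  res <- list(logits = logits)
  if (want_cache) res$cache <- list(enc = enc$cache, pooled = pooled,
                                    n_tok = nrow(X))
  res
}

tok_backward <- function(model, cache, dlogits) {
  g <- list()
  g[["cls.W"]] <- tcrossprod(cache$pooled, as.vector(dlogits))
  g[["cls.b"]] <- as.vector(dlogits)
  dpooled <- as.vector(model$params[["cls.W"]] %*% t(dlogits))
  dOut <- matrix(dpooled, cache$n_tok, length(dpooled), byrow = TRUE) /
    cache$n_tok
  eb <- encoder_backward(model, cache$enc, dOut, masks = model$masks)
  g <- acc_grads(g, eb$grads)
  list(grads = g, dmasks = eb$dmasks)
}
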