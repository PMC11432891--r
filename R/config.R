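#' Search-space configuration for a masked transformer supernet
#'
#' Describes the maximal ("super") architecture over which the sparsity
#' search runs, plus the search hyper-parameters. The embed dimension must
#' factor as `D = H * d` so that concatenating the `H` head outputs of
#' maximal per-head width `d` reconstructs the embedding.
#'
#' @param L Number of encoder layers (each one MHSA block + one MLP block).
#' @param H Attention heads per layer.
#' @param d Maximal feature dimension per head.
#' @param D Global embed dimension; defaults to `H * d` and must equal it.
#' @param M Maximal MLP hidden dimension per layer.
#' @param N Number of patch tokens.
#' @param search_mhsa,search_mlp,search_patch Logical; which mask groups are
#'   trained (and penalized) during the search. Masks of disabled groups stay
#'   at their all-ones initialization; disabled patch masking bypasses the
#'   tanh row scaling entirely.
#' @param w_mhsa,w_mlp,w_patch Non-negative L1 sparsity weights for the three
#'   mask groups (dimensionless multipliers on the mask L1 norms).
#' @param residual Logical; include residual connections around the MHSA and
#'   MLP blocks (the standard ViT wiring). Planted-importance tasks disable
#'   them so that all signal must traverse the masked pathway.
#'
#' @return An object of class `vitslim_config`: a validated list with the
#'   fields above plus `Din` (input width of a searchable linear layer,
#'   equal to `D`) and `Dmax` (maximal output width of a shared super-weight
#'   matrix, `max(H * d, M)`).
#' @export
#' @examples
#' cfg <- search_space_config(L = 2, H = 2, d = 4, M = 16, N = 9)
#' cfg$D  # 8
search_space_config <- function(L, H, d, D = H * d, M, N,
                                search_mhsa = TRUE, search_mlp = TRUE,
                                search_patch = TRUE,
                                w_mhsa = 2e-4, w_mlp = 4e-4, w_patch = 1e-4,
                                residual = TRUE) {
  dims <- c(L = L, H = H, d = d, D = D, M = M, N = N)
  if (any(dims != round(dims)) || any(dims <= 0)) {
    stop("all architecture dimensions must be strictly positive integers")
  }
  if (D != H * d) {
    stop(sprintf("inconsistent head geometry: D (%d) must equal H*d (%d)",
                 D, H * d))
  }
  w <- c(w_mhsa = w_mhsa, w_mlp = w_mlp, w_patch = w_patch)
  if (any(w < 0)) stop("sparsity weights must be >= 0")
  structure(list(
    L = as.integer(L), H = as.integer(H), d = as.integer(d),
    D = as.integer(D), M = as.integer(M), N = as.integer(N),
    Din = as.integer(D), Dmax = as.integer(max(H * d, M)),
    search_mhsa = isTRUE(search_mhsa), search_mlp = isTRUE(search_mlp),
    search_patch = isTRUE(search_patch),
    w_mhsa = w_mhsa, w_mlp = w_mlp, w_patch = w_patch,
    residual = isTRUE(residual)
  ), class = "vitslim_config")
}

#' @export
print.vitslim_config <- function(x, ...) {
  cat(sprintf(
    "<vitslim_config> L=%d H=%d d=%d D=%d M=%d N=%d\n", x$L, x$H, x$d,
    x$D, x$M, x$N))
  cat(sprintf("  search: mhsa=%s mlp=%s patch=%s\n",
              x$search_mhsa, x$search_mlp, x$search_patch))
  cat(sprintf("  sparsity weights: w_mhsa=%g w_mlp=%g w_patch=%g\n",
              x$w_mhsa, x$w_mlp, x$w_patch))
  invisible(x)
}

#' Segmentation model configuration
#'
#' Combines the transformer search space with the image-level plumbing:
#' input size, patch size, class count, decoder feature width, and whether
#' the directional-field (DF) correction module is attached.
#'
#' @param size Input image side length (images are `size x size`).
#' @param patch Patch side length; `size` must be divisible by `patch`.
#'   The token count of `space` must equal `(size/patch)^2`.
#' @param space A [search_space_config()].
#' @param classes Number of classes `C` including background (class 0).
#' @param feat Width of the pre-classifier feature map fed to the DF head
#'   (the "64-channel mask" of the field-learning module).
#' @param df Logical; attach the DF head + rectification + fusion.
#' @param df_iters Rectification iteration count `N` (default 5).
#' @param df_weight Weight of the field regression loss added to the
#'   segmentation cross-entropy.
#' @return An object of class `vitslim_segconfig`.
#' @export
seg_model_config <- function(size, patch, space, classes = 4L, feat = 64L,
                             df = FALSE, df_iters = 5L, df_weight = 1.0) {
  stopifnot(inherits(space, "vitslim_config"))
  if (size %% patch != 0) stop("size must be divisible by patch")
  g <- size %/% patch
  if (space$N != g * g) {
    stop(sprintf("space$N (%d) must equal (size/patch)^2 = %d", space$N, g * g))
  }
  if (classes < 2) stop("need at least background plus one tissue class")
  structure(list(
    size = as.integer(size), patch = as.integer(patch), grid = as.integer(g),
    space = space, classes = as.integer(classes), feat = as.integer(feat),
    df = isTRUE(df), df_iters = as.integer(df_iters), df_weight = df_weight
  ), class = "vitslim_segconfig")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the argument names of [search_space_config()] and
#' [seg_model_config()] under `space:` and `model:` blocks, with optional
#' `train:` (epochs, lr, weight_decay, batch), `budget:` (mhsa, mlp, patch)
#' and `seed:` entries. Unknown keys are rejected so that typos never pass
#' silently.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `space`, `model` (or `NULL`), `train`,
#'   `budget`, `seed`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- c("space", "model", "train", "budget", "seed")
  check_keys(raw, known_top, "top level")
  if (is.null(raw$space)) stop("config must contain a 'space' block")
  # YAML 1.1 reads a bare `N:` key as boolean FALSE; accept it as N
  names(raw$space)[names(raw$space) == "FALSE"] <- "N"
  check_keys(raw$space,
             c("L", "H", "d", "D", "M", "N", "search_mhsa", "search_mlp",
               "search_patch", "w_mhsa", "w_mlp", "w_patch", "residual"),
             "space")
  space <- do.call(search_space_config, raw$space)
  model <- NULL
  if (!is.null(raw$model)) {
    check_keys(raw$model,
               c("size", "patch", "classes", "feat", "df", "df_iters",
                 "df_weight"), "model")
    model <- do.call(seg_model_config, c(raw$model, list(space = space)))
  }
  train <- raw$train
  if (!is.null(train)) {
    check_keys(train, c("epochs", "lr", "weight_decay", "batch"), "train")
  }
  budget <- raw$budget
  if (!is.null(budget)) {
    check_keys(budget, c("mhsa", "mlp", "patch"), "budget")
    budget <- do.call(budget_spec, budget)
  }
  list(space = space, model = model, train = train, budget = budget,
       seed = raw$seed)
}

#' Write a run configuration to YAML
#'
#' Inverse of [read_run_config()]; the round trip is lossless for all
#' recognized keys.
#'
#' @param config A list as returned by [read_run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  sp <- config$space
  out <- list(space = sp[c("L", "H", "d", "D", "M", "N", "search_mhsa",
                           "search_mlp", "search_patch", "w_mhsa", "w_mlp",
                           "w_patch", "residual")])
  if (!is.null(config$model)) {
    m <- config$model
    out$model <- list(size = m$size, patch = m$patch, classes = m$classes,
                      feat = m$feat, df = m$df, df_iters = m$df_iters,
                      df_weight = m$df_weight)
  }
  if (!is.null(config$train)) out$train <- config$train
  if (!is.null(config$budget)) {
    out$budget <- list(mhsa = config$budget$mhsa, mlp = config$budget$mlp,
                       patch = config$budget$patch)
  }
  if (!is.null(config$seed)) out$seed <- config$seed
  yaml::write_yaml(out, path)
  invisible(path)
}

check_keys <- function(x, known, where) {
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    stop(sprintf("unknown %s config key(s): %s", where,
                 paste(extra, collapse = ", ")))
  }
  invisible(TRUE)
}
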