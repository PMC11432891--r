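# Shared tiny fixtures, built in code.

toy_config <- function(N = 9, residual = TRUE, ...) {
  search_space_config(L = 2, H = 2, d = 4, M = 16, N = N,
                      residual = residual, ...)
}

toy_tokens <- function(config, seed = 1) {
  withr::with_seed(seed, matrix(rnorm(config$N * config$D), config$N, config$D))
}

planted_config <- function(...) {
  search_space_config(L = 2, H = 2, d = 4, M = 16, N = 8,
                      search_mhsa = TRUE, search_mlp = FALSE,
                      search_patch = FALSE, residual = FALSE, ...)
}

toy_phantom_sample <- function(seed, size = 32) {
  p <- generate_phantom(seed, size = size)
  list(image = p$image, label = p$label)
}

# independently coded MHSA on physically sliced weights: the brute-force
# oracle for mask/slice equivalence (no shared code with mhsa_block)
oracle_sliced_mhsa <- function(model, Tm, layer, keep) {
  cfg <- model$config
  p <- model$params
  pre <- function(nm) p[[paste0("l", layer, ".", nm)]]
  d <- cfg$d
  out_heads <- vector("list", cfg$H)
  rows_kept <- integer(0)
  for (h in seq_len(cfg$H)) {
    cols <- (h - 1) * d + keep[[h]]
    rows_kept <- c(rows_kept, cols)
    q <- Tm %*% pre("Wq")[, cols, drop = FALSE] +
      matrix(pre("bq")[cols], nrow(Tm), length(cols), byrow = TRUE)
    k <- Tm %*% pre("Wk")[, cols, drop = FALSE] +
      matrix(pre("bk")[cols], nrow(Tm), length(cols), byrow = TRUE)
    v <- Tm %*% pre("Wv")[, cols, drop = FALSE] +
      matrix(pre("bv")[cols], nrow(Tm), length(cols), byrow = TRUE)
    S <- q %*% t(k) / sqrt(d)  # temperature always uses the full d
    A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
    out_heads[[h]] <- A %*% v
  }
  O <- do.call(cbind, out_heads)
  O %*% pre("Wo")[rows_kept, , drop = FALSE] +
    matrix(pre("bo"), nrow(Tm), cfg$D, byrow = TRUE)
}

# independently coded two-layer MLP on sliced weights
oracle_sliced_mlp <- function(model, Tm, layer, keep) {
  p <- model$params
  pre <- function(nm) p[[paste0("l", layer, ".", nm)]]
  h <- Tm %*% pre("W1")[, keep, drop = FALSE] +
    matrix(pre("b1")[keep], nrow(Tm), length(keep), byrow = TRUE)
  h <- pmax(h, 0)
  h %*% pre("W2")[keep, , drop = FALSE] +
    matrix(pre("b2"), nrow(Tm), model$config$D, byrow = TRUE)
}
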