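test_that("config validation enforces head geometry and positivity", {
  cfg <- search_space_config(2, 2, 4, M = 16, N = 9)
  expect_equal(cfg$D, 8L)
  expect_equal(cfg$Dmax, 16L)
  expect_error(search_space_config(2, 2, 4, D = 7, M = 16, N = 9),
               "head geometry")
  expect_error(search_space_config(2, 2, 0, M = 16, N = 9), "positive")
  expect_error(search_space_config(2, 2, 4, M = 16, N = 9, w_mhsa = -1),
               ">= 0")
})

test_that("supernet construction is shape-correct and deterministic", {
  cfg <- toy_config()
  net <- build_supernet(cfg, seed = 0)
  expect_length(net$masks$mhsa, 2)
  expect_equal(dim(net$masks$mhsa[[1]]), c(2, 4))
  expect_length(net$masks$mlp[[2]], 16)
  expect_length(net$masks$patch[[1]], 9)
  expect_true(all(unlist(net$masks) == 1))
  expect_equal(dim(net$params[["l1.Wq"]]), c(8, 8))
  expect_equal(dim(net$params[["l2.W1"]]), c(8, 16))
  net2 <- build_supernet(cfg, seed = 0)
  expect_identical(net$params, net2$params)
  net3 <- build_supernet(cfg, seed = 1)
  expect_false(identical(net$params, net3$params))
})

test_that("all-ones masks with patch bypass reproduce the unmasked model", {
  cfg <- toy_config()
  net <- build_supernet(cfg, seed = 3)
  for (i in 1:20) {
    T0 <- toy_tokens(cfg, seed = i)
    plain <- encoder_forward(net, T0, masks = NULL)$out
    masked <- encoder_forward(net, T0, patch_bypass = TRUE)$out
    expect_lt(max(abs(plain - masked)), 1e-5)
  }
})

test_that("an all-zero head mask annihilates that head's output", {
  cfg <- toy_config()
  net <- build_supernet(cfg, seed = 4)
  t <- toy_tokens(cfg, seed = 2)
  masks <- net$masks
  masks$mhsa[[1]][2, ] <- 0
  # compare against physically removing head 2 in layer 1
  keep_full <- list(1:4, 1:4)
  keep_cut <- list(1:4, integer(0))
  out_masked <- masked_mhsa_forward(net, t, 1, masks = masks)
  out_sliced <- oracle_sliced_mhsa(net, t, 1, keep_cut)
  expect_lt(max(abs(out_masked - out_sliced)), 1e-5)
  # all-ones mask equals the full oracle
  expect_lt(max(abs(masked_mhsa_forward(net, t, 1) -
                      oracle_sliced_mhsa(net, t, 1, keep_full))), 1e-5)
})

test_that("binary MHSA masks agree with physically sliced weights", {
  cfg <- toy_config(N = 3)
  net <- build_supernet(cfg, seed = 5)
  t <- toy_tokens(cfg, seed = 3)
  withr::with_seed(11, {
    for (rep in 1:5) {
      keep <- lapply(1:2, function(h) sort(sample(4, sample(1:4, 1))))
      masks <- net$masks
      for (h in 1:2) masks$mhsa[[1]][h, ] <- as.numeric(1:4 %in% keep[[h]])
      expect_lt(max(abs(masked_mhsa_forward(net, t, 1, masks = masks) -
                          oracle_sliced_mhsa(net, t, 1, keep))), 1e-5)
    }
  })
})

test_that("MLP masking matches Eq.-style slicing and annihilation", {
  cfg <- toy_config()
  net <- build_supernet(cfg, seed = 6)
  t <- toy_tokens(cfg, seed = 4)
  # all-ones = unmasked
  expect_equal(masked_mlp_forward(net, t, 1),
               masked_mlp_forward(net, t, 1, masks = NULL), tolerance = 1e-12)
  # all-zero mask leaves only the f2 bias
  masks <- net$masks
  masks$mlp[[1]][] <- 0
  out <- masked_mlp_forward(net, t, 1, masks = masks)
  expect_equal(out,
               matrix(net$params[["l1.b2"]], cfg$N, cfg$D, byrow = TRUE),
               tolerance = 1e-12)
  # binary mask vs sliced oracle
  withr::with_seed(12, {
    for (rep in 1:5) {
      keep <- sort(sample(16, sample(1:16, 1)))
      masks$mlp[[1]] <- as.numeric(1:16 %in% keep)
      expect_lt(max(abs(masked_mlp_forward(net, t, 1, masks = masks) -
                          oracle_sliced_mlp(net, t, 1, keep))), 1e-5)
    }
  })
})

test_that("patch masking scales rows by tanh of the score", {
  cfg <- toy_config()
  net <- build_supernet(cfg, seed = 7)
  t <- toy_tokens(cfg, seed = 5)
  masks <- net$masks
  masks$patch[[1]] <- c(0, 0.5, 100, rep(1, 6))
  out <- masked_patch_forward(net, t, 1, masks = masks)
  expect_equal(out[1, ], rep(0, cfg$D))
  expect_equal(out[2, ], t[2, ] * tanh(0.5), tolerance = 1e-12)
  expect_equal(out[2, ] / t[2, ], rep(0.462117, cfg$D), tolerance = 1e-6)
  expect_lt(max(abs(out[3, ] - t[3, ])), 1e-8)  # tanh asymptote at 1
  expect_identical(masked_patch_forward(net, t, 1, bypass = TRUE), t)
})

test_that("single-coordinate annihilation equals physical removal everywhere", {
  cfg <- toy_config(N = 5)
  net <- build_supernet(cfg, seed = 8)
  t <- toy_tokens(cfg, seed = 6)
  for (l in 1:2) {
    for (h in 1:2) {
      for (i in 1:4) {
        masks <- net$masks
        masks$mhsa[[l]][h, i] <- 0
        keep <- list(1:4, 1:4)
        keep[[h]] <- setdiff(1:4, i)
        expect_lt(max(abs(masked_mhsa_forward(net, t, l, masks = masks) -
                            oracle_sliced_mhsa(net, t, l, keep))), 1e-5)
      }
    }
    for (i in c(1, 7, 16)) {
      masks <- net$masks
      masks$mlp[[l]][i] <- 0
      expect_lt(max(abs(masked_mlp_forward(net, t, l, masks = masks) -
                          oracle_sliced_mlp(net, t, l, setdiff(1:16, i)))),
                1e-5)
    }
  }
})

test_that("masking never changes shapes and mask gradients are finite", {
  cfg <- toy_config()
  net <- build_supernet(cfg, seed = 9)
  T0 <- toy_tokens(cfg, seed = 7)
  fw <- encoder_forward(net, T0, want_cache = TRUE)
  expect_equal(dim(fw$out), dim(T0))
  dOut <- toy_tokens(cfg, seed = 8)
  bw <- encoder_backward(net, fw$cache, dOut)
  expect_true(all(vapply(bw$grads, function(g) all(is.finite(g)), logical(1))))
  expect_true(all(is.finite(unlist(bw$dmasks))))
  expect_equal(dim(bw$dmasks$mhsa[[1]]), c(cfg$H, cfg$d))
})

test_that("encoder backward matches central finite differences", {
  cfg <- search_space_config(2, 2, 3, M = 10, N = 4)
  net <- build_supernet(cfg, seed = 10)
  T0 <- toy_tokens(cfg, seed = 9)
  target <- toy_tokens(cfg, seed = 10)
  loss_of <- function(net) {
    out <- encoder_forward(net, T0)$out
    sum((out - target)^2)
  }
  fw <- encoder_forward(net, T0, want_cache = TRUE)
  bw <- encoder_backward(net, fw$cache, 2 * (fw$out - target))
  eps <- 1e-6
  withr::with_seed(13, {
    for (nm in c("l1.Wq", "l1.Wv", "l2.Wo", "l1.W1", "l2.W2", "l1.bk")) {
      i <- sample(length(net$params[[nm]]), 1)
      n2 <- net; n2$params[[nm]][i] <- n2$params[[nm]][i] + eps
      n3 <- net; n3$params[[nm]][i] <- n3$params[[nm]][i] - eps
      fd <- (loss_of(n2) - loss_of(n3)) / (2 * eps)
      expect_equal(bw$grads[[nm]][i], fd, tolerance = 1e-3)
    }
    for (kind in c("mhsa", "mlp", "patch")) {
      l <- sample(2, 1)
      i <- sample(length(net$masks[[kind]][[l]]), 1)
      n2 <- net; n2$masks[[kind]][[l]][i] <- n2$masks[[kind]][[l]][i] + eps
      n3 <- net; n3$masks[[kind]][[l]][i] <- n3$masks[[kind]][[l]][i] - eps
      fd <- (loss_of(n2) - loss_of(n3)) / (2 * eps)
      expect_equal(bw$dmasks[[kind]][[l]][i], fd, tolerance = 1e-3)
    }
  })
})

test_that("non-finite activations raise instead of clipping", {
  cfg <- toy_config()
  net <- build_supernet(cfg, seed = 11)
  t <- toy_tokens(cfg, seed = 11)
  net$params[["l1.Wo"]][1, 1] <- Inf
  expect_error(masked_mhsa_forward(net, t, 1), "non-finite")
})
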