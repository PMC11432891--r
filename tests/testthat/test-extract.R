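test_that("budget selection keeps the ceiling count of top scores per kind", {
  cfg <- toy_config(N = 5)
  masks <- mask_set(cfg)
  withr::with_seed(1, {
    for (l in 1:2) {
      masks$mhsa[[l]][] <- rnorm(8)
      masks$mlp[[l]] <- rnorm(16)
      masks$patch[[l]] <- rnorm(5)
    }
  })
  rk <- rank_dimensions(masks, cfg)
  spec <- select_budget(rk, budget_spec(0.6, 0.5, 0.7), cfg)
  expect_equal(sum(unlist(lapply(spec$mhsa, lengths))), ceiling(0.6 * 16))
  expect_equal(sum(lengths(spec$mlp)), ceiling(0.5 * 32))
  expect_equal(sum(lengths(spec$patch)), ceiling(0.7 * 10))
  # threshold property: every kept score >= every dropped score
  for (kind in c("mhsa-dim", "mlp-dim", "patch")) {
    rows <- rk[rk$kind == kind, ]
    kept <- apply(rows, 1, function(x) {
      l <- as.integer(x["layer"]); i <- as.integer(x["index"])
      if (kind == "mhsa-dim") i %in% spec$mhsa[[l]][[as.integer(x["head"])]]
      else if (kind == "mlp-dim") i %in% spec$mlp[[l]]
      else i %in% spec$patch[[l]]
    })
    expect_gte(min(rows$score[kept]), max(rows$score[!kept]))
  }
  # full budget reproduces the architecture
  full <- select_budget(rk, budget_spec(1, 1, 1), cfg)
  expect_identical(full$mhsa, full_subnet_spec(cfg)$mhsa)
  expect_identical(full$mlp, full_subnet_spec(cfg)$mlp)
  expect_error(budget_spec(0, 1, 1), "\\(0, 1\\]")
})

test_that("10 sites at fraction 0.6 keeps exactly the 6 best", {
  cfg <- search_space_config(1, 1, 4, M = 10, N = 10, residual = TRUE)
  masks <- mask_set(cfg)
  masks$mlp[[1]] <- c(0.9, 0.1, 0.5, 0.8, 0.05, 0.3, 0.7, 0.2, 0.6, 0.95)
  rk <- rank_dimensions(masks, cfg)
  spec <- select_budget(rk, budget_spec(1, 0.6, 1), cfg)
  expect_equal(spec$mlp[[1]], sort(c(1, 3, 4, 7, 9, 10)))
})

test_that("patch monotonicity equals the running-intersection oracle", {
  # worked cases
  s <- full_subnet_spec(toy_config(N = 3))
  s$patch <- list(c(1, 2, 3), c(1, 2, 3))
  expect_identical(enforce_patch_monotonicity(s)$patch,
                   list(c(1, 2, 3), c(1, 2, 3)))
  s$patch <- list(c(1, 3), c(1, 2, 3))
  expect_identical(enforce_patch_monotonicity(s)$patch,
                   list(c(1, 3), c(1, 3)))
  # random draws over 4 layers vs oracle
  cfg4 <- search_space_config(4, 2, 4, M = 16, N = 12)
  withr::with_seed(2, {
    for (rep in 1:100) {
      s4 <- full_subnet_spec(cfg4)
      s4$patch <- lapply(1:4, function(l) sort(sample(12, sample(3:12, 1))))
      before <- s4$patch
      after <- enforce_patch_monotonicity(s4)$patch
      run <- before[[1]]
      for (l in 1:4) {
        run <- intersect(run, before[[l]])
        expect_identical(after[[l]], sort(run))
        expect_true(all(after[[l]] %in% before[[l]]))  # removals only
        if (l > 1) expect_true(all(after[[l]] %in% after[[l - 1]]))
      }
    }
  })
})

test_that("slicing equals binarized masking on random subnets", {
  cfg <- search_space_config(2, 2, 4, M = 16, N = 16)
  net <- build_supernet(cfg, seed = 20)
  withr::with_seed(3, {
    for (rep in 1:10) {
      spec <- random_subnet_spec(cfg, rep + 500)
      bn <- spec_to_binary(spec, cfg)
      T0 <- matrix(rnorm(16 * 8), 16, 8)
      masked <- encoder_forward(net, T0, masks = bn$masks,
                                patch_bypass = TRUE, alive = bn$alive)$out
      cm <- slice_supernet(net, spec)
      compact <- compact_encoder_forward(cm, T0[cm$alive[[1]], , drop = FALSE])$out
      expect_lt(max(abs(masked - compact)), 1e-4)
    }
  })
})

test_that("full-budget slicing is the identity computation", {
  cfg <- toy_config(N = 9)
  net <- build_supernet(cfg, seed = 21)
  cm <- slice_supernet(net, full_subnet_spec(cfg))
  T0 <- toy_tokens(cfg, seed = 30)
  expect_lt(max(abs(encoder_forward(net, T0, masks = NULL)$out -
                      compact_encoder_forward(cm, T0)$out)), 1e-5)
  expect_equal(as.integer(count_params(full_subnet_spec(cfg), cfg)),
               n_params(cm))
})

test_that("closed-form parameter count equals tensor enumeration exactly", {
  cfg <- search_space_config(2, 2, 4, M = 16, N = 16)
  net <- build_supernet(cfg, seed = 22)
  for (s in 1:20) {
    spec <- random_subnet_spec(cfg, s + 700)
    cm <- slice_supernet(net, spec)
    expect_identical(as.integer(count_params(spec, cfg)), n_params(cm))
  }
  # dropping one mhsa dim costs 3(D+1) + D; one mlp dim costs (D+1) + D
  full <- full_subnet_spec(cfg)
  D <- cfg$D
  one <- full; one$mhsa[[1]][[1]] <- 2:4
  expect_equal(as.integer(count_params(full, cfg)) - as.integer(count_params(one, cfg)),
               3 * (D + 1) + D)
  one2 <- full; one2$mlp[[2]] <- 2:16
  expect_equal(as.integer(count_params(full, cfg)) - as.integer(count_params(one2, cfg)),
               (D + 1) + D)
  # strictly decreasing in every dropped dimension
  expect_lt(as.integer(count_params(one, cfg)), as.integer(count_params(full, cfg)))
})

test_that("FLOP accounting follows the stated scaling laws", {
  cfg <- search_space_config(2, 2, 4, M = 16, N = 16)
  full <- full_subnet_spec(cfg)
  f_full <- count_flops(full, cfg)
  half <- full
  half$patch <- lapply(half$patch, function(p) p[1:8])
  f_half <- count_flops(half, cfg)
  b_full <- attr(f_full, "breakdown"); b_half <- attr(f_half, "breakdown")
  expect_equal(b_half[["attn_scores"]], b_full[["attn_scores"]] / 4)
  expect_equal(b_half[["attn_apply"]], b_full[["attn_apply"]] / 4)
  expect_equal(b_half[["qkv"]], b_full[["qkv"]] / 2)
  expect_equal(b_half[["mlp"]], b_full[["mlp"]] / 2)
  # manual MAC enumeration on a 1-layer toy
  cfg1 <- search_space_config(1, 1, 2, M = 3, N = 2)
  f1 <- count_flops(full_subnet_spec(cfg1), cfg1)
  manual <- 3 * 2 * 2 * 2 +  # qkv: 3 proj, N=2 tokens, D=2, d=2
    2^2 * 2 + 2^2 * 2 +      # scores + apply
    2 * 2 * 2 +              # projection
    2 * (2 * 2 * 3)          # two MLP linears
  expect_equal(as.numeric(f1), manual)
  # monotonicity under nesting
  sub <- random_subnet_spec(cfg, 901)
  expect_lte(as.numeric(count_flops(sub, cfg)), as.numeric(f_full))
})

test_that("subnet specs round-trip through 0-based JSON", {
  cfg <- toy_config(N = 6)
  spec <- random_subnet_spec(cfg, 42)
  path <- withr::local_tempfile(fileext = ".json")
  write_subnet_spec(spec, path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(raw$index_base, 0L)
  expect_equal(raw$mlp[[1]], spec$mlp[[1]] - 1L)
  back <- read_subnet_spec(path)
  expect_equal(back$mhsa, spec$mhsa)
  expect_equal(back$mlp, spec$mlp)
  expect_equal(back$patch, spec$patch)
})
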