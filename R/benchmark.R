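# Desk-scale benchmark mirroring the three-step compression workflow on
# synthetic cardiac phantoms: one sparsity search defines the subnet, then
# seeded retraining runs compare the extracted model with and without the
# directional-field module.

#' Phantom compression benchmark
#'
#' Generates a 200-phantom dataset (7:1:2 split), searches a tiny
#' supernet-backed segmentation model for `epochs` epochs, extracts the
#' subnet at the given budgets with patch monotonicity enforced, and then,
#' for each of `n_runs` seeds, retrains the compact model for `epochs`
#' epochs twice — once with the DF module attached (identity-initialized
#' fusion) and once without — and evaluates mean tissue DSC on the test
#' split.
#'
#' The default architecture (2 layers, 2 heads of width 10, MLP width 40,
#' 32x32 images with 8-px patches) is sized so the 70/70 MHSA/MLP budgets
#' are exact: the searchable parameter reduction is then exactly 30%.
#'
#' @param seed Base seed: the dataset, search and retraining seeds derive
#'   from it.
#' @param n Number of phantoms.
#' @param size Image side length.
#' @param n_runs Number of seeded retraining comparisons.
#' @param epochs Epochs for the search and for each retraining.
#' @param budgets Kept fractions (mhsa, mlp, patch).
#' @param lr,batch AdamW settings used throughout.
#' @param verbose Print stage progress.
#' @return List with `searchable_reduction`, `flop_reduction`, `runs`
#'   (data frame: seed, dsc_plain, dsc_df), `spec`, `search_trace`,
#'   `dsc_supernet` (search-phase model on the test split), `dsc_sliced`
#'   (before retraining), `n_train`, `n_test`.
#' @export
phantom_benchmark <- function(seed = 7, n = 200, size = 32, n_runs = 10,
                              epochs = 50, budgets = c(0.7, 0.7, 0.6),
                              lr = 3e-3, batch = 32, verbose = FALSE) {
  sp <- search_space_config(2, 2, 10, M = 40, N = (size %/% 8)^2)
  mc <- seg_model_config(size, 8, sp, classes = 4, feat = 64, df = FALSE)
  dat <- generate_dataset(seed, n, size = size)
  dat$train <- lapply(dat$train, function(s) {
    s$field <- gt_direction_field(s$label)  # DF retraining target, computed once
    s
  })
  supernet <- assemble_model(mc, seed = seed)
  if (verbose) message("searching ", epochs, " epochs on ",
                       length(dat$train), " phantoms")
  sr <- run_search(supernet, dat$train, epochs = epochs, seed = seed,
                   lr = lr, batch = batch)
  spec <- enforce_patch_monotonicity(select_budget(
    rank_dimensions(sr$masks, sp), do.call(budget_spec, as.list(budgets)), sp))
  full <- full_subnet_spec(sp)
  red <- 1 - attr(count_params(spec, sp), "breakdown")[["searchable"]] /
    attr(count_params(full, sp), "breakdown")[["searchable"]]
  fred <- 1 - as.numeric(count_flops(spec, sp)) /
    as.numeric(count_flops(full, sp))
  compact <- slice_supernet(sr$model, spec)
  dsc_sliced <- evaluate(compact, dat$test)$mean_dsc
  runs <- data.frame(seed = integer(0), dsc_plain = numeric(0),
                     dsc_df = numeric(0))
  for (r in seq_len(n_runs)) {
    rseed <- seed + 100L * r
    rt_plain <- retrain(compact, dat$train, epochs = epochs, seed = rseed,
                        lr = lr, batch = batch)
    dsc_plain <- evaluate(rt_plain$model, dat$test)$mean_dsc
    with_df <- add_df_module(compact, seed = rseed + 1L)
    rt_df <- retrain(with_df, dat$train, epochs = epochs, seed = rseed,
                     lr = lr, batch = batch)
    dsc_df <- evaluate(rt_df$model, dat$test)$mean_dsc
    runs <- rbind(runs, data.frame(seed = rseed, dsc_plain = dsc_plain,
                                   dsc_df = dsc_df))
    if (verbose) {
      message(sprintf("run %d: plain %.4f  df %.4f", r, dsc_plain, dsc_df))
    }
  }
  list(searchable_reduction = red, flop_reduction = fred, runs = runs,
       spec = spec, search_trace = sr$trace,
       dsc_supernet = evaluate(sr$model, dat$test)$mean_dsc,
       dsc_sliced = dsc_sliced,
       n_train = length(dat$train), n_test = length(dat$test))
}
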