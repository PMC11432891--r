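# Readers/writers for the standard formats the pipeline touches (PNG pairs,
# NIfTI volumes, JSON artifacts) and the end-to-end orchestrator.
#
# Serialized grids are row-major with 0-based indices; matrices in memory
# are H x W with (x = column-1, y = row-1) field semantics.

#' Read an image/label pair
#'
#' PNG pairs yield one 2-D sample; NIfTI volumes (`.nii`/`.nii.gz`) are
#' sliced along the last axis into one 2-D sample per slice. Images are
#' rescaled to `[0, 1]` (PNG readers already provide that scale); labels
#' are read as integers unchanged.
#'
#' @param path_img,path_label File paths (both PNG or both NIfTI).
#' @param classes Permitted label range is `0 .. classes - 1`.
#' @return A list of samples, each `list(image =, label =)`.
#' @export
read_image_pair <- function(path_img, path_label, classes = 4L) {
  if (!file.exists(path_img)) stop("image file not found: ", path_img)
  if (!file.exists(path_label)) stop("label file not found: ", path_label)
  is_nifti <- grepl("\\.nii(\\.gz)?$", path_img)
  if (is_nifti) {
    img <- as.array(RNifti::readNifti(path_img))
    lab <- as.array(RNifti::readNifti(path_label))
    rng <- range(img)
    if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng)
    if (length(dim(img)) == 2) {
      img <- array(img, c(dim(img), 1)); lab <- array(lab, c(dim(lab), 1))
    }
    samples <- lapply(seq_len(dim(img)[3]), function(k) {
      list(image = img[, , k], label = matrix(as.integer(round(lab[, , k])),
                                              dim(lab)[1], dim(lab)[2]))
    })
  } else {
    img <- png::readPNG(path_img)
    if (length(dim(img)) == 3) img <- img[, , 1]
    labraw <- png::readPNG(path_label)
    if (length(dim(labraw)) == 3) labraw <- labraw[, , 1]
    lab <- matrix(as.integer(round(labraw * 255)), nrow(labraw), ncol(labraw))
    samples <- list(list(image = img, label = lab))
  }
  for (s in samples) {
    if (!all(dim(s$image) == dim(s$label))) {
      stop("image and label grids differ")
    }
    if (any(s$label < 0 | s$label >= classes)) {
      stop(sprintf("label values outside configured class range [0, %d]",
                   classes - 1L))
    }
  }
  samples
}

#' Write an image/label pair as 8-bit grey PNGs
#'
#' Labels `k` are stored as grey level `k/255`, so the round trip through
#' [read_image_pair()] is bit-identical for class counts up to 256.
#'
#' @param sample A `list(image =, label =)`.
#' @param path_img,path_label Output paths.
#' @return Invisibly, the two paths.
#' @export
write_image_pair <- function(sample, path_img, path_label) {
  png::writePNG(pmin(pmax(sample$image, 0), 1), path_img)
  png::writePNG(sample$label / 255, path_label)
  invisible(c(path_img, path_label))
}

#' Write phantoms to a directory as PNG pairs plus a manifest
#'
#' @param samples List of phantoms (or `image`/`label` samples).
#' @param dir Output directory (created if needed).
#' @param nifti Also write 3-D NIfTI image/label volumes stacking the
#'   samples.
#' @return The manifest path, invisibly.
#' @export
write_phantom_dir <- function(samples, dir, nifti = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(samples), function(i) {
    pi <- file.path(dir, sprintf("img_%04d.png", i))
    pl <- file.path(dir, sprintf("lab_%04d.png", i))
    write_image_pair(samples[[i]], pi, pl)
    list(image = basename(pi), label = basename(pl),
         seed = samples[[i]]$meta$seed)
  })
  if (nifti) {
    size <- nrow(samples[[1]]$image)
    img <- array(0, c(size, size, length(samples)))
    lab <- array(0L, c(size, size, length(samples)))
    for (k in seq_along(samples)) {
      img[, , k] <- samples[[k]]$image
      lab[, , k] <- samples[[k]]$label
    }
    RNifti::writeNifti(img, file.path(dir, "volume_img.nii.gz"))
    RNifti::writeNifti(lab, file.path(dir, "volume_lab.nii.gz"))
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(n = length(samples), files = entries,
                            convention = "labels stored as grey k/255; grids row-major"),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the full pipeline: search, extract, retrain, evaluate
#'
#' Executes the three-step workflow — (1) co-train weights and masks under
#' the sparsity objective, (2) rank masks and extract the budgeted subnet
#' with patch monotonicity enforced, (3) retrain the compact model with the
#' same optimizer settings and no penalty — then evaluates the compact
#' model, writing all artifacts to `out_dir`: the search checkpoint and
#' mask dump (JSON), the subnet spec (JSON), the compact checkpoint, the
#' evaluation report (JSON), and a log with both loss terms per epoch.
#'
#' @param model_config A [seg_model_config()].
#' @param data List with `train` and `test` sample lists (e.g. from
#'   [generate_dataset()]).
#' @param budget A [budget_spec()].
#' @param out_dir Output directory.
#' @param epochs_search,epochs_retrain Epoch counts (default 50 each).
#' @param seed Integer seed.
#' @param lr,weight_decay,batch AdamW settings.
#' @param verbose Print stage progress.
#' @return Invisibly, a list with `search`, `spec`, `compact` (retrained
#'   model), `eval`, and artifact `paths`.
#' @export
pipeline_run <- function(model_config, data, budget, out_dir,
                         epochs_search = 50L, epochs_retrain = 50L,
                         seed = 0L, lr = 1e-3, weight_decay = 1e-2,
                         batch = 16L, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(nm, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", nm, conditionMessage(e)),
           call. = FALSE)
    })
  }
  log_path <- file.path(out_dir, "pipeline_log.txt")
  cat(sprintf("pipeline seed=%d budgets mhsa=%.2f mlp=%.2f patch=%.2f\n",
              seed, budget$mhsa, budget$mlp, budget$patch), file = log_path)

  supernet <- stage("build", assemble_model(model_config, seed = seed))
  search <- stage("search", run_search(supernet, data$train,
                                       epochs = epochs_search, seed = seed,
                                       lr = lr, weight_decay = weight_decay,
                                       batch = batch, verbose = verbose))
  write_trace(search$trace, log_path, "search")
  saveRDS(search, file.path(out_dir, "search_result.rds"))
  ranking <- rank_dimensions(search$masks, model_config$space)
  jsonlite::write_json(ranking, file.path(out_dir, "mask_scores.json"),
                       digits = NA)
  spec <- stage("extract", enforce_patch_monotonicity(
    select_budget(ranking, budget, model_config$space)))
  write_subnet_spec(spec, file.path(out_dir, "subnet_spec.json"))
  compact <- stage("slice", slice_supernet(search$model, spec))
  rt <- stage("retrain", retrain(compact, data$train, epochs = epochs_retrain,
                                 seed = seed + 1L, lr = lr,
                                 weight_decay = weight_decay, batch = batch,
                                 verbose = verbose))
  write_trace(rt$trace, log_path, "retrain")
  saveRDS(rt$model, file.path(out_dir, "compact_model.rds"))
  ev <- stage("evaluate", evaluate(rt$model, data$test))
  report <- list(
    per_class_dsc = as.list(ev$per_class),
    mean_dsc = ev$mean_dsc,
    mean_per_image_dsc = ev$mean_per_image,
    n_params_total = ev$n_params,
    encoder_params = as.integer(count_params(spec, model_config$space)),
    encoder_params_full = as.integer(count_params(
      full_subnet_spec(model_config$space), model_config$space)),
    encoder_macs = as.numeric(count_flops(spec, model_config$space)),
    encoder_macs_full = as.numeric(count_flops(
      full_subnet_spec(model_config$space), model_config$space)),
    flop_convention = "1 MAC = 1 reported FLOP"
  )
  jsonlite::write_json(report, file.path(out_dir, "eval_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(search = search, spec = spec, compact = rt$model, eval = ev,
                 report = report,
                 paths = file.path(out_dir, c("search_result.rds",
                                              "mask_scores.json",
                                              "subnet_spec.json",
                                              "compact_model.rds",
                                              "eval_report.json",
                                              "pipeline_log.txt"))))
}

write_trace <- function(trace, log_path, label) {
  lines <- sprintf("%s epoch %3d  CE %.6f  L1 %.6f", label, trace$epoch,
                   trace$ce, trace$l1)
  cat(lines, file = log_path, sep = "\n", append = TRUE)
}
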