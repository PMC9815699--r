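#' The five-configuration ablation grid
#'
#' @param base a [model_config()] whose toggles are overridden per row.
#' @return List of model configurations named after their enabled blocks.
#' @export
ablation_grid <- function(base = model_config()) {
  grid <- ablation_benchmark()[, c("model", "use_transformer", "use_cffi",
                                   "use_asff")]
  configs <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- base
    cfg$use_transformer <- grid$use_transformer[i]
    cfg$use_cffi <- grid$use_cffi[i]
    cfg$use_asff <- grid$use_asff[i]
    cfg
  })
  stats::setNames(configs, grid$model)
}

#' Run the module ablation on one dataset split
#'
#' Builds, trains and evaluates every toggle configuration on the same
#' train/validation split, and reports the weed-class metrics plus mAP, one
#' row per configuration.  A configuration that fails to build or train is
#' marked failed and the run continues.
#'
#' @param train_images,val_images lists of [annotated_image()].
#' @param epochs training epochs per configuration.
#' @param seed seed shared by all configurations (identical data order).
#' @param base a [model_config()] template; its `seed` fixes the weight
#'   initialisation.
#' @param lr learning rate.
#' @return data.frame with columns model, the three toggles, n_params,
#'   recall_weed, precision_weed, f1_weed, ap_weed, map50, map50_95,
#'   failed.
#' @export
run_ablation <- function(train_images, val_images, epochs = 1L, seed = 1L,
                         base = model_config(), lr = 5e-3) {
  configs <- ablation_grid(base)
  rows <- list()
  for (nm in names(configs)) {
    cfg <- configs[[nm]]
    row <- data.frame(model = nm,
                      use_transformer = cfg$use_transformer,
                      use_cffi = cfg$use_cffi,
                      use_asff = cfg$use_asff,
                      n_params = NA_real_, recall_weed = NA_real_,
                      precision_weed = NA_real_, f1_weed = NA_real_,
                      ap_weed = NA_real_, map50 = NA_real_,
                      map50_95 = NA_real_, failed = FALSE,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      model <- build_model(cfg)
      train_detector(model, train_images, epochs = epochs, seed = seed,
                     lr = lr)
      rep <- evaluate_model(model, val_images)
      weed <- rep$per_class[rep$per_class$class_id == 1L, ]
      row$n_params <- n_parameters(unclass(model))
      row$recall_weed <- weed$recall
      row$precision_weed <- weed$precision
      row$f1_weed <- weed$f1
      row$ap_weed <- weed$ap50
      row$map50 <- rep$map50
      row$map50_95 <- rep$map50_95
      row
    }, error = function(e) {
      row$failed <- TRUE
      attr(row, "error") <- conditionMessage(e)
      row
    })
    rows[[nm]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
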