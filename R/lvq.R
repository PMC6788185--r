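# Supervised LVQ1 fine-tuning of a labelled map. Only the best-matching
# prototype moves: towards a training case of its own class, away from one of
# a different class. Node labels are frozen; validation quality is monitored
# each epoch and the best-validation prototypes are the ones returned.

#' LVQ1 training schedule
#'
#' Defaults follow the classifier's published operating point: 3000 epochs
#' with the learning rate decaying linearly from 0.9 to 0.01 and shuffled
#' ("mixed") case presentation. `epsilon` and `beta` are carried in the
#' model metadata for provenance; the textbook LVQ1 rule does not use them
#' (they belong to LVQ2/3-style window variants).
#'
#' @param epochs Number of passes over the training cases.
#' @param lr_start,lr_end Linear learning-rate range.
#' @param epsilon,beta Recorded but unused by the LVQ1 update.
#' @param shuffle Shuffle case order each epoch.
#' @param seed Integer seed for shuffling.
#' @param early_stop_patience Stop when validation quality has not improved
#'   for this many epochs; `NULL` (default) disables early stopping.
#' @return An `lvq_schedule` list.
#' @export
lvq_schedule <- function(epochs = 3000L, lr_start = 0.9, lr_end = 0.01,
                         epsilon = 0.35, beta = 0.25, shuffle = TRUE,
                         seed = 1L, early_stop_patience = NULL) {
  stopifnot(epochs >= 1, lr_end > 0, lr_end <= lr_start, lr_start <= 1)
  structure(list(epochs = as.integer(epochs), lr_start = lr_start,
                 lr_end = lr_end, epsilon = epsilon, beta = beta,
                 shuffle = isTRUE(shuffle), seed = as.integer(seed),
                 early_stop_patience = early_stop_patience),
            class = "lvq_schedule")
}

#' Single LVQ1 prototype update
#'
#' Attraction when the prototype's class matches the case's
#' (`w + lr (x - w)`), repulsion otherwise (`w - lr (x - w)`).
#'
#' @param prototype,x Numeric vectors of equal length.
#' @param proto_label,x_label Class labels.
#' @param lr Learning rate in (0, 1).
#' @return Updated prototype vector.
#' @export
#' @examples
#' lvq1_update(c(0, 0), 1, c(1, 0), 1, 0.5)
lvq1_update <- function(prototype, proto_label, x, x_label, lr) {
  stopifnot(length(prototype) == length(x), lr > 0, lr < 1)
  s <- if (identical(proto_label, x_label)) lr else -lr
  prototype + s * (x - prototype)
}

#' LVQ1 fine-tuning of a labelled map
#'
#' Runs LVQ1 over the training partition for `schedule$epochs` epochs,
#' scoring the validation partition after each epoch, and returns the map
#' whose prototypes achieved the best validation quality (ties keep the
#' earliest epoch). The per-epoch validation trace and the best epoch are
#' stored in `meta$lvq`.
#'
#' @param data Split tibble with `class_id` and `partition` columns
#'   (train and valid partitions required), features on the normalised scale.
#' @param map A labelled `topo_map` (see [label_map()]).
#' @param schedule An [lvq_schedule()].
#' @return The fine-tuned `topo_map`.
#' @export
train_lvq1 <- function(data, map, schedule = lvq_schedule()) {
  if (is.null(map$labels) || anyNA(map$labels))
    abort("unlabelled-map: every node must carry a class label before LVQ1",
          class = "compostmap_unlabelled")
  train <- partition_rows(data, "train")
  valid <- partition_rows(data, "valid")
  if (nrow(train) == 0) abort("empty training partition")
  if (!"partition" %in% names(data) || nrow(valid) == 0)
    abort("missing validation partition: LVQ1 monitors validation quality")
  Xt <- as_feature_matrix(train)
  Xv <- as_feature_matrix(valid)
  lr <- lin_seq(schedule$lr_start, schedule$lr_end, schedule$epochs)
  res <- cpp_train_lvq1(map$prototypes, as.integer(map$labels),
                        Xt, as.integer(train$class_id),
                        Xv, as.integer(valid$class_id),
                        lr, schedule$shuffle, schedule$seed,
                        as.integer(schedule$early_stop_patience %||% 0L))
  out <- map
  W <- res$prototypes
  colnames(W) <- colnames(map$prototypes)
  out$prototypes <- W
  fin <- res$final_prototypes
  colnames(fin) <- colnames(map$prototypes)
  out$meta$lvq <- list(schedule = unclass(schedule),
                       best_epoch = res$best_epoch,
                       final_prototypes = fin,
                       val_quality = res$val_quality,
                       final_val_quality = res$val_quality[length(res$val_quality)])
  out
}
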