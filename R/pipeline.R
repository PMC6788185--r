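# End-to-end benchmark pipeline and model serialisation. A single master
# seed is expanded (counter-based, see derive_seed) into the generator,
# split, map-initialisation, SOFM and LVQ seeds, so a whole run is
# reproducible from one number.

MODEL_SCHEMA_VERSION <- "1"

#' Configuration of an end-to-end benchmark run
#'
#' @param benchmark A [benchmark_spec()]; its `seed` is replaced by a seed
#'   derived from `seed` so the master seed governs the whole run.
#' @param sofm A [sofm_schedule()].
#' @param lvq An [lvq_schedule()].
#' @param black_threshold Black-pixel threshold for feature extraction.
#' @param seed Master seed of the run.
#' @param out_dir Optional run directory; when set, the features CSV, model
#'   JSON, evaluation report and the effective configuration are written
#'   there.
#' @param write_images Also render the benchmark PNGs under
#'   `out_dir/images` and extract features from disk instead of in memory.
#' @return A `run_config` list.
#' @export
run_config <- function(benchmark = default_benchmark_spec(),
                       sofm = sofm_schedule(), lvq = lvq_schedule(),
                       black_threshold = 0, seed = 1L, out_dir = NULL,
                       write_images = FALSE) {
  structure(list(benchmark = benchmark, sofm = sofm, lvq = lvq,
                 black_threshold = black_threshold, seed = as.integer(seed),
                 out_dir = out_dir, write_images = isTRUE(write_images)),
            class = "run_config")
}

#' Run the full benchmark pipeline
#'
#' generate images -> extract the 30 descriptors -> stratified 2:1:1 split ->
#' min-max normalisation (training partition only) -> SOFM training ->
#' majority-vote node labelling -> LVQ1 fine-tuning -> evaluation. Stage
#' errors are rethrown with the stage name prefixed.
#'
#' @param config A [run_config()].
#' @return A `compost_run` list with elements `model` (labelled, fine-tuned
#'   `topo_map` carrying the normaliser), `report` (a `compost_eval`),
#'   `features` (the split feature table) and `config`.
#' @export
#' @examples
#' \donttest{
#' spec <- benchmark_spec(default_benchmark_spec()$classes,
#'                        n_images_total = 50, image_size = c(16, 16))
#' cfg <- run_config(benchmark = spec,
#'                   sofm = sofm_schedule(phase1_epochs = 5, phase2_epochs = 10),
#'                   lvq = lvq_schedule(epochs = 10), seed = 1)
#' run <- run_benchmark(cfg)
#' run$report
#' }
run_benchmark <- function(config = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
            parent = e))
  }
  seeds <- list(generate = derive_seed(config$seed, 1),
                split = derive_seed(config$seed, 2),
                init = derive_seed(config$seed, 3),
                sofm = derive_seed(config$seed, 4),
                lvq = derive_seed(config$seed, 5))
  bench <- config$benchmark
  bench$seed <- seeds$generate
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  features <- stage("generate/extract", {
    if (config$write_images) {
      img_dir <- file.path(out_dir %||% tempdir(), "images")
      generate_benchmark(bench, img_dir)
      extract_table(img_dir, manifest = file.path(img_dir, "manifest.csv"),
                    black_threshold = config$black_threshold)
    } else {
      generate_feature_table(bench, black_threshold = config$black_threshold)
    }
  })
  split <- stage("split", split_211(features, seed = seeds$split))
  norm <- stage("normalise", fit_normaliser(split))
  split_n <- apply_normaliser(split, norm)

  sofm_sched <- config$sofm
  sofm_sched$seed <- seeds$sofm
  map0 <- stage("init", init_map(c(15L, 15L), dim = 30L, seed = seeds$init))
  map <- stage("train_sofm", train_sofm(split_n, map0, sofm_sched))
  map <- stage("label_map", label_map(split_n, map))

  lvq_sched <- config$lvq
  lvq_sched$seed <- seeds$lvq
  map <- stage("train_lvq1", train_lvq1(split_n, map, lvq_sched))
  map$normaliser <- norm
  map$meta$seeds <- seeds
  map$meta$master_seed <- config$seed
  map$meta$black_threshold <- config$black_threshold

  report <- stage("evaluate", evaluate_model(split, map))

  if (!is.null(out_dir)) {
    readr::write_csv(split, file.path(out_dir, "features_split.csv"))
    save_model(map, file.path(out_dir, "model.json"))
    write_eval_report(report, file.path(out_dir, "report.json"),
                      file.path(out_dir, "report.txt"), out_dir)
    yaml::write_yaml(list(seed = config$seed,
                          black_threshold = config$black_threshold,
                          n_images_total = bench$n_images_total,
                          image_size = bench$image_size,
                          sofm = unclass(sofm_sched),
                          lvq = unclass(lvq_sched)),
                     file.path(out_dir, "config.yaml"))
  }
  structure(list(model = map, report = report, features = split,
                 config = config),
            class = "compost_run")
}

#' @export
print.compost_run <- function(x, ...) {
  cat("<compost_run> master seed", x$config$seed, "\n")
  print(x$report)
  invisible(x)
}

#' Save a topological-map model as JSON
#'
#' Full-precision serialisation of the prototypes, grid shape, node labels
#' and support, normaliser, schedules and seeds; [load_model()] round-trips
#' prototypes bit-exactly.
#'
#' @param model A `topo_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  obj <- list(schema_version = MODEL_SCHEMA_VERSION,
              package_version = as.character(packageVersion("compostmap")),
              grid_shape = model$grid_shape,
              dim = ncol(model$prototypes),
              feature_names = colnames(model$prototypes),
              prototypes = lapply(seq_len(nrow(model$prototypes)),
                                  function(i) unname(model$prototypes[i, ])),
              labels = model$labels,
              label_support = model$label_support,
              normaliser = if (!is.null(model$normaliser))
                list(min = unname(model$normaliser$min),
                     max = unname(model$normaliser$max),
                     features = model$normaliser$features),
              meta = model$meta)
  # I(17) = 17 significant digits, enough to round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a topological-map model saved by [save_model()]
#'
#' @param path Path to a model JSON file.
#' @return A `topo_map`.
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    abort(paste0("cannot parse model file: ",
                                 conditionMessage(e))))
  if (is.null(obj$schema_version) ||
      !identical(as.character(obj$schema_version), MODEL_SCHEMA_VERSION))
    abort(sprintf("model schema version mismatch: expected %s, found %s",
                  MODEL_SCHEMA_VERSION,
                  obj$schema_version %||% "<missing>"))
  dim <- obj$dim
  W <- do.call(rbind, lapply(obj$prototypes, function(p) {
    v <- as.numeric(unlist(p))
    if (length(v) != dim) abort("corrupt model file: prototype length mismatch")
    v
  }))
  colnames(W) <- unlist(obj$feature_names)
  norm <- NULL
  if (!is.null(obj$normaliser)) {
    feats <- unlist(obj$normaliser$features)
    norm <- structure(list(
      min = stats::setNames(as.numeric(unlist(obj$normaliser$min)), feats),
      max = stats::setNames(as.numeric(unlist(obj$normaliser$max)), feats),
      features = feats), class = "compost_normaliser")
  }
  new_topo_map(W, unlist(obj$grid_shape),
               labels = if (!is.null(obj$labels)) as.integer(unlist(obj$labels)),
               label_support = if (!is.null(obj$label_support))
                 as.integer(unlist(obj$label_support)),
               normaliser = norm,
               meta = obj$meta)
}
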