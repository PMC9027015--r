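# End-to-end experiment runner: synthesize data, train the automatic
# colorizer, run exemplar transfer for each reference class, and evaluate
# both methods against ground truth on held-out synthetic pairs. A run is
# reproducible from its config alone; all randomness flows from the two
# named seeds.

.default_run_config <- function() {
  list(
    experiment = "both",                # auto | exemplar | both
    data_seed = 1L,
    model_seed = 1L,
    out_dir = "ctcolor_run",
    data = list(
      n_train = 30L,                    # the small supervised regime
      n_eval = 4L,
      texture_size = c(224L, 224L),
      phantom_size = c(224L, 224L)),
    train = list(
      epochs = 10L,
      batch_size = 10L,
      learning_rate = 1e-3,
      chroma_space = "LAB_AB",
      input_size = c(224L, 224L)),
    exemplar = list(
      iterations = 200L,
      step_size = 0.02,
      style_weight = 1,
      content_weight = 1e-4,
      snapshot_every = 20L,
      working_size = c(400L, 585L),
      extractor_conv_counts = c(2L, 2L, 4L, 4L, 4L),
      extractor_filters = c(64L, 128L, 256L, 512L, 512L)))
}

.validate_run_config <- function(cfg) {
  pos_int <- function(v, name) {
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != floor(v))
      stop(sprintf("invalid value for '%s': must be a positive integer", name))
    as.integer(v)
  }
  if (!cfg$experiment %in% c("auto", "exemplar", "both"))
    stop("invalid value for 'experiment': must be auto, exemplar or both")
  cfg$data_seed <- pos_int(abs(cfg$data_seed) + 1L, "data_seed") - 1L
  cfg$model_seed <- pos_int(abs(cfg$model_seed) + 1L, "model_seed") - 1L
  cfg$data$n_train <- pos_int(cfg$data$n_train, "n_train")
  cfg$data$n_eval <- pos_int(cfg$data$n_eval, "n_eval")
  cfg$train$epochs <- pos_int(cfg$train$epochs, "epochs")
  cfg$train$batch_size <- pos_int(cfg$train$batch_size, "batch_size")
  if (cfg$train$learning_rate <= 0)
    stop("invalid value for 'learning_rate': must be positive")
  if (!cfg$train$chroma_space %in% c("LAB_AB", "LUV_UV"))
    stop("invalid value for 'chroma_space'")
  cfg$exemplar$iterations <- pos_int(cfg$exemplar$iterations, "iterations")
  cfg$exemplar$snapshot_every <- pos_int(cfg$exemplar$snapshot_every,
                                         "snapshot_every")
  if (cfg$exemplar$step_size <= 0)
    stop("invalid value for 'step_size': must be positive")
  if (length(cfg$exemplar$extractor_conv_counts) !=
      length(cfg$exemplar$extractor_filters))
    stop("extractor_conv_counts and extractor_filters must match in length")
  cfg
}

# deep-merge user values into defaults; unknown keys are an error
.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste(paste0(path, unknown), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]],
                                     paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load (or default) a run configuration
#'
#' Reads a YAML config file, fills every omitted field with its default,
#' validates values, and returns the fully populated config. An empty
#' file (or `NULL` path) yields the all-defaults config. Unknown keys and
#' invalid values are errors naming the offending field.
#'
#' @param path YAML file path, or `NULL` for defaults.
#' @return a validated `run_config` list.
#' @export
load_config <- function(path = NULL) {
  user <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
  }
  cfg <- .merge_config(.default_run_config(), user)
  cfg <- .validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' Save a run configuration as YAML
#'
#' @param config a `run_config`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run a full colorization experiment
#'
#' Stages (logged with timestamps to `log.txt` in the run directory):
#' \enumerate{
#'   \item synth: paired training textures, held-out paired eval textures,
#'     and one healthy + one infected lung phantom.
#'   \item auto (experiments `auto`/`both`): build + train the chroma
#'     regressor, checkpoint it, colorize the phantoms and the eval grays.
#'   \item exemplar (experiments `exemplar`/`both`): transfer each of the
#'     four reference texture classes onto the healthy phantom, and
#'     transfer a same-class reference onto each eval gray.
#'   \item evaluate: full-reference MSE/PSNR/SSIM of every method output
#'     against the eval ground-truth color textures (`report.tsv`).
#' }
#'
#' @param config a `run_config` from [load_config()].
#' @return invisibly, a list with `out_dir`, `steps_per_epoch` (when
#'   training ran), `report` (a `quality_report`) and `checkpoint` path.
#' @export
run_experiment <- function(config = load_config()) {
  cfg <- .validate_run_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out, "log.txt")
  log_line <- function(stage, fmt, ...) {
    line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, sprintf(fmt, ...))
    cat(line, "\n", file = logfile, append = TRUE, sep = "")
  }
  stage <- "config"
  result <- list(out_dir = out)
  tryCatch({
    save_config(cfg, file.path(out, "config.yaml"))

    stage <- "synth"
    log_line(stage, "generating %d training pairs", cfg$data$n_train)
    train_man <- generate_dataset(cfg$data$n_train, "paired",
                                  seed = cfg$data_seed,
                                  out_dir = file.path(out, "train"),
                                  size = cfg$data$texture_size)
    eval_man <- generate_dataset(cfg$data$n_eval, "paired",
                                 seed = cfg$data_seed + 10000L,
                                 out_dir = file.path(out, "eval"),
                                 size = cfg$data$texture_size)
    phantoms <- list(
      healthy = generate_lung_phantom(
        phantom_spec("healthy", cfg$data$phantom_size, cfg$data_seed + 501L)),
      infected = generate_lung_phantom(
        phantom_spec("infected", cfg$data$phantom_size, cfg$data_seed + 502L)))
    for (nm in names(phantoms))
      write_image(phantoms[[nm]], file.path(out, paste0("phantom_", nm, ".png")))

    ref_rows <- character(0); test_rows <- character(0)

    if (cfg$experiment %in% c("auto", "both")) {
      stage <- "train"
      spec <- colorizer_spec(cfg$train$input_size, cfg$train$chroma_space)
      model <- build_colorizer(spec, seed = cfg$model_seed)
      steps <- as.integer(ceiling(cfg$data$n_train / cfg$train$batch_size))
      log_line(stage, "steps_per_epoch = %d", steps)
      tc <- training_config(cfg$train$epochs, cfg$train$batch_size,
                            cfg$train$learning_rate, seed = cfg$model_seed,
                            chroma_space = cfg$train$chroma_space)
      model <- train_colorizer(model, train_man,
                               tc, dataset_dir = file.path(out, "train"))
      log_line(stage, "final epoch loss %.6f", utils::tail(model$history, 1))
      result$checkpoint <- file.path(out, "colorizer.rds")
      result$steps_per_epoch <- steps
      save_colorizer(model, result$checkpoint)

      stage <- "colorize-auto"
      dir.create(file.path(out, "auto"), showWarnings = FALSE)
      for (nm in names(phantoms)) {
        res <- colorize_image(model, phantoms[[nm]])
        write_image(res, file.path(out, "auto",
                                   paste0("phantom_", nm, "_color.png")))
      }
      for (i in seq_len(nrow(eval_man))) {
        gray <- read_image(file.path(out, "eval", eval_man$gray_file[i]))
        res <- colorize_image(model, gray)
        fn <- file.path(out, "auto", sprintf("eval_%03d.png", i))
        write_image(res, fn)
        ref_rows <- c(ref_rows, file.path(out, "eval", eval_man$file[i]))
        test_rows <- c(test_rows, fn)
      }
    }

    if (cfg$experiment %in% c("exemplar", "both")) {
      stage <- "colorize-exemplar"
      dir.create(file.path(out, "exemplar"), showWarnings = FALSE)
      ex_spec <- feature_extractor_spec(
        blocks = Map(c, cfg$exemplar$extractor_conv_counts,
                     cfg$exemplar$extractor_filters))
      extractor <- build_feature_extractor(ex_spec, seed = cfg$model_seed)
      st_cfg <- style_transfer_config(
        style_weight = cfg$exemplar$style_weight,
        content_weight = cfg$exemplar$content_weight,
        iterations = cfg$exemplar$iterations,
        step_size = cfg$exemplar$step_size,
        seed = cfg$model_seed,
        snapshot_every = cfg$exemplar$snapshot_every,
        working_size = cfg$exemplar$working_size)
      classes <- c("pork", "steak", "lamb", "rotten")
      for (ci in seq_along(classes)) {
        ref <- generate_meat_texture(texture_spec(
          classes[ci], cfg$data$texture_size, cfg$data_seed + 30000L + ci))
        tr <- transfer_colors(phantoms$healthy, ref, extractor, st_cfg)
        write_image(tr$result,
                    file.path(out, "exemplar",
                              paste0("phantom_", classes[ci], ".png")))
        log_line(stage, "%s reference: final loss %.6g", classes[ci],
                 utils::tail(tr$loss_trace, 1))
      }
      for (i in seq_len(nrow(eval_man))) {
        gray <- read_image(file.path(out, "eval", eval_man$gray_file[i]))
        ref <- generate_meat_texture(texture_spec(
          eval_man$class[i], cfg$data$texture_size,
          cfg$data_seed + 40000L + i))
        tr <- transfer_colors(gray, ref, extractor, st_cfg)
        fn <- file.path(out, "exemplar", sprintf("eval_%03d.png", i))
        write_image(tr$result, fn)
        ref_rows <- c(ref_rows, file.path(out, "eval", eval_man$file[i]))
        test_rows <- c(test_rows, fn)
      }
    }

    stage <- "evaluate"
    report <- evaluate_batch(data.frame(ref = ref_rows, test = test_rows))
    write_report(report, file.path(out, "report.tsv"))
    log_line(stage, "mean PSNR %.4f, mean SSIM %.4f",
             report$aggregate$mean_psnr, report$aggregate$mean_ssim)
    result$report <- report
    invisible(result)
  }, error = function(e) {
    log_line(stage, "FAILED: %s", conditionMessage(e))
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}
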