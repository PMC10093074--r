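# End-to-end demo: wrap -> attack -> audit/restore -> extract -> fuse ->
# order -> select -> classify, with structured logging and a provenance
# record. This, plus the thin Rscript under inst/cli/, is the package's
# command-line surface.

#' Default run configuration
#'
#' @param seed master seed for every stage.
#' @param suite cipher suite name (`"rsa"` or `"symmetric"`).
#' @param split training fraction for the final classification (0.7, the
#'   conventional 70/30 split).
#' @param classifier final classifier name (see [classify()]).
#' @param images list of [image_gen_config()] overrides.
#' @param attack list: `attack_type`, `noise_std`, `auto_restore`; `NULL`
#'   disables the attack stage.
#' @param ga list of [ga_config()] overrides.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, suite = "rsa", split = 0.7,
                       classifier = "gaussian_nb",
                       images = list(), attack = list(attack_type = 2L,
                                                      noise_std = 0.1,
                                                      auto_restore = TRUE),
                       ga = list()) {
  structure(list(seed = as.integer(seed), suite = suite, split = split,
                 classifier = classifier, images = images, attack = attack,
                 ga = ga),
            class = "run_config")
}

#' Read a run configuration from JSON or YAML
#' @param path `.json` or `.yaml`/`.yml` file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- run_config()
  for (k in names(raw)) cfg[[k]] <- raw[[k]]
  if (!is.null(cfg$attack)) cfg$attack <- as.list(cfg$attack)
  cfg$images <- as.list(cfg$images)
  cfg$ga <- as.list(cfg$ga)
  cfg
}

#' Write a run configuration (lossless round trip)
#' @param cfg a `run_config`.
#' @param path `.json` or `.yaml` destination.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  plain <- unclass(cfg)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(plain, path)
  else jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                            null = "null")
  invisible(path)
}

demo_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  cat(line, "\n", sep = "")
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full secured pipeline on synthetic fixtures
#'
#' Generates the image fixtures, builds and wraps the three toy backbones,
#' optionally attacks one of them and audits/restores it, extracts the
#' three named feature layers, fuses and mode-orders them, runs GA
#' selection and classifies on the selected features. All artifacts
#' (metrics, validation report, provenance, log) land under `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return list with `metrics`, `validation`, `selected`, `provenance`
#'   (invisibly).
#' @export
run_demo <- function(config = run_config(), out_dir = tempfile("scnn_demo_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(logcon))
  seed <- config$seed
  suite <- cipher_suite(config$suite)

  demo_log(logcon, "fixtures", "generating synthetic image set")
  icfg <- do.call(image_gen_config, c(list(seed = seed), config$images))
  set <- gen_image_set(icfg)

  demo_log(logcon, "backbones", "building and wrapping toy backbones")
  backbones <- build_toy_backbones(seed = seed,
                                   input_shape = icfg$image_size,
                                   classes = icfg$classes)
  secured <- lapply(backbones, wrap_secure, suite = suite, seed = seed)

  validation <- list()
  if (!is.null(config$attack) && length(config$attack)) {
    spec <- attack_spec(config$attack$attack_type %||% 2L,
                        noise_std = config$attack$noise_std %||% 0.1,
                        seed = seed)
    demo_log(logcon, "attack", sprintf("type %d tampering on backbone 1",
                                       spec$attack_type))
    atk <- apply_attack(backbones[[1]], spec)
    tampered <- tamper_secure(secured[[1]], atk$model)
    report <- audit_model(tampered)
    demo_log(logcon, "audit", sprintf("flagged layers: %s",
                                      paste(report$tampered_layer_ids,
                                            collapse = ", ")))
    validation$attack_report <- atk$report
    validation$audit <- report
    if (isTRUE(config$attack$auto_restore %||% TRUE)) {
      res <- restore_model(tampered$base, tampered$llbs, tampered$clb,
                           tampered$suite)
      validation$restored <- res$report
      secured[[1]]$base <- res$model
      demo_log(logcon, "restore", sprintf(
        "restored %d layer(s) in %d iteration(s)",
        length(res$report$tampered_layer_ids), res$report$iterations_used))
    }
  }

  demo_log(logcon, "extract", "extracting features from named layers")
  reg <- feature_layer_registry()
  feats <- lapply(seq_len(3L), function(i)
    extract_features(secured[[i]]$base, reg$layer[i], set$images))

  demo_log(logcon, "fuse", "serial fusion + mode-value ordering")
  fused <- serial_fuse(feats[[1]], feats[[2]], feats[[3]],
                       labels = set$labels)
  fused <- mode_order(fused)

  demo_log(logcon, "select", "genetic-algorithm feature selection")
  gcfg <- do.call(ga_config, c(list(seed = seed), config$ga))
  sel <- ga_select(fused, gcfg)
  demo_log(logcon, "select", sprintf(
    "kept %d / %d features (best fitness %.4f, %d generations)",
    length(sel$selected), ncol(fused$x), sel$best$fitness, sel$generations))

  demo_log(logcon, "classify", config$classifier)
  # selection indices are in original coordinates; classify on the
  # original-order table for interpretability
  orig <- serial_fuse(feats[[1]], feats[[2]], feats[[3]], labels = set$labels)
  metrics <- classify(orig, sel$selected, config$classifier,
                      split = config$split, seed = seed)
  demo_log(logcon, "classify", sprintf(
    "accuracy %.4f precision %.4f recall %.4f f1 %.4f",
    metrics$accuracy, metrics$precision, metrics$recall, metrics$f1))

  provenance <- list(
    package_version = as.character(utils::packageVersion("securecnn")),
    seed = seed,
    config_hash = paste(as.character(openssl::sha256(charToRaw(
      jsonlite::toJSON(unclass(config), auto_unbox = TRUE)))), collapse = ""),
    suite = config$suite)
  results <- list(
    metrics = metrics[c("accuracy", "precision", "recall", "f1",
                        "n_train", "n_test", "classifier")],
    n_selected = length(sel$selected),
    n_features = ncol(fused$x),
    best_fitness = sel$best$fitness,
    generations = sel$generations,
    flagged_layers = validation$audit$tampered_layer_ids %||% integer(0),
    restored = !is.null(validation$restored))
  jsonlite::write_json(results, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  jsonlite::write_json(list(
    flagged = validation$audit$tampered_layer_ids %||% integer(0),
    reasons = as.list(validation$audit$reasons %||% character(0)),
    restored = results$restored),
    file.path(out_dir, "validation.json"), auto_unbox = TRUE)
  invisible(list(metrics = results, validation = validation,
                 selected = sel$selected, provenance = provenance,
                 out_dir = out_dir))
}
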