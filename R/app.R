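# End-to-end orchestration: preprocess -> segment -> match -> decide, plus a
# persistent template store (the "database" of enrolled identities), config
# file round-tripping and model persistence. The CLI script under
# inst/cli/wristvein.R is a thin wrapper over these functions.

#' Application configuration
#'
#' Bundles all stage configurations with path and seed settings. Round-trips
#' losslessly through YAML via [save_app_config()] / [load_app_config()].
#'
#' @param data_root dataset directory.
#' @param model_dir directory for trained model checkpoints.
#' @param template_store directory of enrolled templates.
#' @param preprocess,labeling,unet,cnn,siamese,augment stage configs.
#' @param seed global RNG seed.
#' @return An `app_config` list.
#' @export
app_config <- function(data_root = "data", model_dir = "models",
                       template_store = "templates",
                       preprocess = preprocess_config(),
                       labeling = labeling_config(),
                       unet = unet_config(),
                       cnn = cnn_matcher_config(),
                       siamese = siamese_config(),
                       augment = augment_config(),
                       seed = 1) {
  structure(list(data_root = data_root, model_dir = model_dir,
                 template_store = template_store, preprocess = preprocess,
                 labeling = labeling, unet = unet, cnn = cnn,
                 siamese = siamese, augment = augment, seed = seed),
            class = "app_config")
}

#' Write an application config to YAML
#' @param cfg an [app_config()].
#' @param path output file.
#' @export
save_app_config <- function(cfg, path) {
  yaml::write_yaml(lapply(cfg, function(x) if (is.list(x)) unclass(x) else x),
                   path)
  invisible(path)
}

#' Read an application config from YAML
#' @param path YAML file written by [save_app_config()].
#' @return An `app_config` with all nested configs re-validated through
#'   their constructors.
#' @export
load_app_config <- function(path) {
  y <- yaml::read_yaml(path)
  # constructors re-derive fields they do not take as arguments
  mk <- function(ctor, x) do.call(ctor, x[intersect(names(x), names(formals(ctor)))])
  app_config(
    data_root = y$data_root, model_dir = y$model_dir,
    template_store = y$template_store,
    preprocess = mk(preprocess_config, y$preprocess),
    labeling = mk(labeling_config, y$labeling),
    unet = mk(unet_config, y$unet),
    cnn = mk(cnn_matcher_config, y$cnn),
    siamese = mk(siamese_config, y$siamese),
    augment = mk(augment_config, y$augment),
    seed = y$seed
  )
}

#' Save a model checkpoint with a JSON config sidecar
#' @param model a `unet_model`, `siamese_model` or `cnn_matcher_model`.
#' @param path checkpoint path (`.rds`); `<path>.json` holds the config.
#' @export
save_model <- function(model, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, path)
  jsonlite::write_json(c(list(class = class(model)), unclass(model$cfg)),
                       paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Load a model checkpoint saved by [save_model()]
#' @param path checkpoint path.
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    stop("no model checkpoint at '", path,
         "'; train one with train_unet()/train_siamese()/train_cnn_matcher() ",
         "or the train-unet / train-matcher CLI subcommands")
  readRDS(path)
}

#' Assemble a recognition system from trained models
#'
#' @param unet trained `unet_model`.
#' @param matcher trained `siamese_model` or `cnn_matcher_model`.
#' @param cfg an [app_config()].
#' @return A `vein_system`.
#' @export
vein_system <- function(unet, matcher, cfg = app_config()) {
  if (!inherits(unet, "unet_model")) stop("unet must be a unet_model")
  arch <- if (inherits(matcher, "siamese_model")) "siamese"
          else if (inherits(matcher, "cnn_matcher_model")) "cnn"
          else stop("matcher must be a siamese_model or cnn_matcher_model")
  structure(list(unet = unet, matcher = matcher, arch = arch, cfg = cfg),
            class = "vein_system")
}

# Probe/reference processing shared by enroll/verify/identify.
system_mask <- function(sys, img) {
  if (is.character(img)) img <- read_vein_image(img)
  pre <- preprocess_pipeline(img, sys$cfg$preprocess)
  pre <- resize_image(pre, sys$unet$cfg$input_size)
  segment(sys$unet, pre)
}

template_index <- function(store) {
  files <- list.files(store, pattern = "\\.json$", recursive = TRUE,
                      full.names = TRUE)
  files[basename(files) != "index.json"]
}

#' Enroll a subject into the template store
#'
#' Preprocesses and segments the image; for a Siamese matcher the 128-float
#' embedding is stored, for the CNN matcher the segmented mask itself.
#' Multiple enrollments per subject are kept side by side.
#'
#' @param sys a [vein_system()].
#' @param img image path or intensity matrix.
#' @param subject_id identity to enroll under.
#' @param store template-store directory (default from the config).
#' @return Invisibly, the path of the stored template.
#' @export
enroll <- function(sys, img, subject_id, store = sys$cfg$template_store) {
  mask <- system_mask(sys, img)
  sdir <- file.path(store, subject_id)
  dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
  n <- length(list.files(sdir, pattern = "\\.json$")) + 1
  path <- file.path(sdir, sprintf("template_%03d.json", n))
  tpl <- list(subject_id = subject_id, arch = sys$arch)
  if (sys$arch == "siamese") {
    sz <- sys$matcher$cfg$input_size
    tpl$embedding <- embed_mask(sys$matcher, resize_mask(mask, sz))
  } else {
    mp <- sub("\\.json$", ".png", path)
    write_mask(mask, mp)
    tpl$mask_path <- basename(mp)
  }
  jsonlite::write_json(tpl, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

load_template <- function(path) {
  tpl <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(tpl$mask_path))
    tpl$mask <- read_mask(file.path(dirname(path), tpl$mask_path))
  tpl
}

# Match one probe mask against one stored template; returns a score where
# smaller is better for siamese (distance), larger is better for cnn
# (probability).
template_score <- function(sys, mask, tpl) {
  if (sys$arch == "siamese") {
    sz <- sys$matcher$cfg$input_size
    e <- embed_mask(sys$matcher, resize_mask(mask, sz))
    sqrt(sum((e - tpl$embedding)^2))
  } else {
    match_probability_cnn(sys$matcher, mask, tpl$mask)
  }
}

system_threshold <- function(sys) {
  if (sys$arch == "siamese") {
    tau <- sys$matcher$cfg$decision_threshold
    if (is.null(tau)) stop("siamese decision threshold not calibrated; ",
                           "train with train_siamese() first")
    tau
  } else 0.5
}

#' Verify a probe against a claimed identity (1:1)
#'
#' @param sys a [vein_system()].
#' @param img probe image path or matrix.
#' @param claimed_id enrolled identity being claimed.
#' @param store template-store directory.
#' @return A `match_decision` (best template of the claimed identity).
#' @export
verify <- function(sys, img, claimed_id, store = sys$cfg$template_store) {
  sdir <- file.path(store, claimed_id)
  tpls <- list.files(sdir, pattern = "template_.*\\.json$", full.names = TRUE)
  if (length(tpls) == 0)
    stop("identity '", claimed_id, "' is not enrolled")
  mask <- system_mask(sys, img)
  scores <- vapply(tpls, function(p)
    template_score(sys, mask, load_template(p)), numeric(1))
  tau <- system_threshold(sys)
  if (sys$arch == "siamese") decide(min(scores), tau)
  else structure(list(distance = 1 - max(scores), score = max(scores),
                      threshold = tau, verdict = max(scores) >= tau),
                 class = "match_decision")
}

#' Identify a probe against every enrolled subject (1:N)
#'
#' Subjects are ranked by ascending distance (Siamese) or descending match
#' probability (CNN); the top hit is accepted only if it passes the decision
#' threshold.
#'
#' @param sys a [vein_system()].
#' @param img probe image path or matrix.
#' @param store template-store directory.
#' @return list with `ranking` (data.frame subject_id/score ordered best
#'   first), `top` (best subject), `accepted` (logical).
#' @export
identify <- function(sys, img, store = sys$cfg$template_store) {
  tpls <- template_index(store)
  if (length(tpls) == 0) stop("template store is empty; enroll subjects first")
  mask <- system_mask(sys, img)
  scores <- vapply(tpls, function(p)
    template_score(sys, mask, load_template(p)), numeric(1))
  subj <- basename(dirname(tpls))
  best <- tapply(scores, subj, if (sys$arch == "siamese") min else max)
  ord <- order(best, decreasing = (sys$arch != "siamese"))
  rk <- data.frame(subject_id = names(best)[ord], score = as.numeric(best)[ord],
                   stringsAsFactors = FALSE)
  tau <- system_threshold(sys)
  accepted <- if (sys$arch == "siamese") rk$score[1] <= tau else rk$score[1] >= tau
  list(ranking = rk, top = rk$subject_id[1], accepted = accepted)
}
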