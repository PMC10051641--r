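# Genuine/impostor pair construction and training-time augmentation.
#
# Each wrist (subject x side) is an identity captured in two sessions. The
# session-1 image paired with the same wrist's session-2 image is a genuine
# pair; paired with a random non-matching session-2 image it is an impostor
# pair, so every wrist contributes exactly one of each and the label ratio is
# 1:1. Identities are split into train/test before pairing, so no wrist
# appears in both splits.

#' Augmentation configuration for matcher training
#'
#' Ranges follow the matcher-training protocol: rotation within ±15°, zoom
#' to a scale factor drawn from `zoom_range`, translation within ±10% of the
#' frame in both directions, resampled for every epoch. The default
#' `zoom_range` of `[0.4, 0.6]` is the protocol's literal "zooming between
#' 40% and 60%", which leaves patterns at half scale; `c(0.9, 1.1)` is the
#' recommended override when zoom is meant as a mild scale perturbation.
#'
#' @param rotation_deg max absolute rotation (degrees).
#' @param zoom_range scale-factor interval.
#' @param translate_frac max absolute translation (fraction of frame).
#' @param per_epoch_resample draw fresh augmentations every epoch.
#' @return An `augment_config` list.
#' @export
augment_config <- function(rotation_deg = 15, zoom_range = c(0.40, 0.60),
                           translate_frac = 0.10, per_epoch_resample = TRUE) {
  stopifnot(all(is.finite(c(rotation_deg, zoom_range, translate_frac))))
  structure(list(rotation_deg = rotation_deg, zoom_range = zoom_range,
                 translate_frac = translate_frac,
                 per_epoch_resample = per_epoch_resample),
            class = "augment_config")
}

#' Randomly augment a binary mask
#'
#' Rotation, zoom and translation drawn from `cfg` and composed into a single
#' affine about the image centre; nearest-neighbour resampling keeps the
#' output binary; regions moved out of frame are filled with 0. Draws come
#' from the current R RNG stream.
#'
#' @param mask `{0, 1}` matrix.
#' @param cfg an [augment_config()].
#' @return Augmented `{0, 1}` matrix of the same dimensions.
#' @export
augment <- function(mask, cfg = augment_config()) {
  d <- dim(mask)
  af <- make_affine(
    rotation_deg = stats::runif(1, -cfg$rotation_deg, cfg$rotation_deg),
    translate = stats::runif(2, -cfg$translate_frac, cfg$translate_frac) * d,
    scale = stats::runif(1, cfg$zoom_range[1], cfg$zoom_range[2]),
    center = (d - 1) / 2
  )
  apply_affine(mask, af, "nearest", fill = 0)
}

#' Build genuine/impostor pair sets from a registry
#'
#' Wrist identities are split `split_frac : 1 - split_frac` into train/test
#' first (seeded), then each wrist's session-1 image is paired with its own
#' session-2 image (genuine) and with a uniformly drawn session-2 image of a
#' different wrist within the same split (impostor; sampling is with
#' replacement across probes). `|train| + |test| = 2 x n_wrists`.
#'
#' @param registry data.frame with columns subject_id, wrist, session (as
#'   from [make_registry()]); every wrist needs sessions 1 and 2.
#' @param split_frac train fraction of wrists (0.8). `1.0` puts all pairs in
#'   train.
#' @param seed RNG seed for split and impostor sampling.
#' @return list with `train` and `test` data.frames: wrist_id, row_a, row_b
#'   (registry row indices), wrist_b (impostor partner identity), label
#'   ("genuine"/"impostor").
#' @export
build_pairs <- function(registry, split_frac = 0.8, seed = 1) {
  registry$.row <- seq_len(nrow(registry))
  registry$wrist_id <- paste(registry$subject_id, registry$wrist, sep = "/")
  wrists <- unique(registry$wrist_id)
  if (length(wrists) < 2)
    stop("impostor pairing needs at least two wrists")
  s1 <- registry[registry$session == 1, ]
  s2 <- registry[registry$session == 2, ]
  if (!all(wrists %in% s1$wrist_id) || !all(wrists %in% s2$wrist_id))
    stop("every wrist needs a session-1 and a session-2 image")
  with_seed(seed, {
    n_train <- round(split_frac * length(wrists))
    tr_wr <- sample(wrists, n_train)
    te_wr <- setdiff(wrists, tr_wr)
    pair_up <- function(wr) {
      if (length(wr) == 0)
        return(data.frame(wrist_id = character(), row_a = integer(),
                          row_b = integer(), wrist_b = character(),
                          label = character(), stringsAsFactors = FALSE))
      if (length(wr) == 1)
        stop("a split with a single wrist cannot form impostor pairs; ",
             "adjust split_frac or add wrists")
      rows <- lapply(wr, function(w) {
        a <- s1$.row[s1$wrist_id == w][1]
        b <- s2$.row[s2$wrist_id == w][1]
        pool <- s2[s2$wrist_id %in% setdiff(wr, w), ]
        imp <- pool[sample.int(nrow(pool), 1), ]
        data.frame(wrist_id = w, row_a = c(a, a), row_b = c(b, imp$.row),
                   wrist_b = c(w, imp$wrist_id),
                   label = c("genuine", "impostor"), stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }
    list(train = pair_up(tr_wr), test = pair_up(te_wr))
  })
}
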