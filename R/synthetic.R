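# Synthetic wrist-vein dataset generator.
#
# Emulates the structure of a two-session NIR wrist-vein study: N subjects x
# 2 wrists x S sessions, one image per (wrist, session). Each wrist carries a
# subject-unique tree-like vascular pattern; veins appear as dark ridges on a
# brighter, low-contrast skin background with an illumination gradient,
# point-spread blur and sensor noise. Sessions of the same wrist differ by a
# small random pose/illumination jitter, which is what makes genuine pairs
# harder than identical copies but easier than impostor pairs.

#' Scene-rendering parameters for the synthetic generator
#'
#' Defaults render low-contrast images (vein drop ~45 gray levels on a ~170
#' background before blur) so that contrast enhancement is non-trivially
#' useful, with session jitter inside the augmentation envelope used for
#' matcher training (rotation within ±10°, translation within ±5% of frame,
#' scale 0.95–1.05).
#'
#' @param background_level mean skin intensity (8-bit scale).
#' @param gradient_amp peak-to-centre illumination gradient amplitude.
#' @param vein_contrast intensity drop at the vessel centreline.
#' @param noise_sigma additive Gaussian sensor-noise SD.
#' @param blur_sigma point-spread Gaussian blur SD (pixels).
#' @param jitter list with `rotation_deg`, `translate_frac`, `scale_range`.
#' @return A `scene_params` list.
#' @export
scene_params <- function(background_level = 170, gradient_amp = 25,
                         vein_contrast = 45, noise_sigma = 8, blur_sigma = 1,
                         jitter = list(rotation_deg = 10, translate_frac = 0.05,
                                       scale_range = c(0.95, 1.05))) {
  stopifnot(vein_contrast >= 0, noise_sigma >= 0, blur_sigma >= 0,
            all(is.finite(unlist(jitter))))
  structure(list(background_level = background_level, gradient_amp = gradient_amp,
                 vein_contrast = vein_contrast, noise_sigma = noise_sigma,
                 blur_sigma = blur_sigma, jitter = jitter),
            class = "scene_params")
}

#' Subject specification for tree growth
#'
#' The same (`subject_id`, `wrist`, `seed`) triple always regenerates the same
#' underlying vein tree; different subjects or wrists give independent trees.
#'
#' @param subject_id opaque subject identifier.
#' @param wrist `"left"` or `"right"`.
#' @param seed integer RNG seed for this wrist's tree.
#' @param n_sessions number of imaging sessions (>= 1).
#' @export
subject_spec <- function(subject_id, wrist = c("left", "right"), seed,
                         n_sessions = 2) {
  wrist <- match.arg(wrist)
  stopifnot(n_sessions >= 1)
  structure(list(subject_id = as.character(subject_id), wrist = wrist,
                 seed = as.integer(seed), n_sessions = as.integer(n_sessions)),
            class = "subject_spec")
}

#' Expand a study design into a per-image registry
#'
#' One record per (subject, wrist, session): `n_subjects * 2 * n_sessions`
#' rows. Seeds are derived hierarchically from the root seed by subject and
#' wrist index, so adding subjects never perturbs existing ones.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param n_sessions sessions per wrist (>= 1).
#' @param seed root RNG seed.
#' @return data.frame with columns subject_id, wrist, session, tree_seed,
#'   session_seed.
#' @export
make_registry <- function(n_subjects, n_sessions = 2, seed = 1) {
  if (n_subjects < 1 || n_sessions < 1)
    stop("n_subjects and n_sessions must be positive")
  g <- expand.grid(session = seq_len(n_sessions), wrist = c("left", "right"),
                   subject = seq_len(n_subjects), stringsAsFactors = FALSE)
  g <- g[order(g$subject, g$wrist, g$session), ]
  wrist_idx <- ifelse(g$wrist == "left", 1L, 2L)
  data.frame(
    subject_id = sprintf("S%04d", g$subject),
    wrist = g$wrist,
    session = g$session,
    tree_seed = vapply(seq_len(nrow(g)), function(i)
      derive_seed(seed, g$subject[i], wrist_idx[i]), integer(1)),
    session_seed = vapply(seq_len(nrow(g)), function(i)
      derive_seed(seed, g$subject[i], wrist_idx[i], g$session[i]), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Grow a subject-unique vascular tree
#'
#' A biased branching random walk: one or two trunk vessels enter from the
#' lower frame border and walk upward with angular jitter, splitting into two
#' daughters every few steps over 3 generations (branch angles jittered
#' within about ±30°). Vessel half-widths start at 2–3 px and taper towards
#' the leaves, giving full widths in the 2–6 px range.
#'
#' @param spec a [subject_spec()].
#' @param frame integer (H, W), both >= 64.
#' @return A `vein_tree`: `nodes` (n x 2, 0-based row/col), `edges` (m x 2
#'   parent/child node indices), `radii` (length m, per-edge half-width).
#' @export
grow_vein_tree <- function(spec, frame = c(256, 256)) {
  if (any(frame < 64)) stop("frame must be at least 64 x 64")
  H <- frame[1]; W <- frame[2]
  with_seed(spec$seed, {
    nodes <- matrix(numeric(0), ncol = 2)
    edges <- matrix(integer(0), ncol = 2)
    radii <- numeric(0)
    step <- max(H, W) / 20
    clip <- function(p) pmin(pmax(p, 2), c(H - 3, W - 3))
    add_node <- function(p) {
      nodes <<- rbind(nodes, p)
      nrow(nodes)
    }
    # walk one branch: from node `from` along `angle`, `nsteg` steps, then
    # (unless last generation) split into two daughters
    walk <- function(from, angle, radius, gen) {
      nsteps <- sample(3:5, 1)
      cur <- from
      for (s in seq_len(nsteps)) {
        angle <- angle + stats::runif(1, -0.25, 0.25)
        p <- clip(nodes[cur, ] + step * c(-cos(angle), sin(angle)))
        nxt <- add_node(p)
        edges <<- rbind(edges, c(cur, nxt))
        radii <<- c(radii, radius)
        cur <- nxt
        if (p[1] <= 2 || p[1] >= H - 3 || p[2] <= 2 || p[2] >= W - 3)
          return(invisible(NULL))  # reached the frame border
      }
      if (gen < 3) {
        spread <- stats::runif(1, 0.3, 0.55)  # ~17-31 degrees each side
        for (s in c(-1, 1))
          walk(cur, angle + s * spread * stats::runif(1, 0.7, 1.3),
               max(radius * 0.75, 1), gen + 1)
      }
      invisible(NULL)
    }
    n_trunks <- 2
    for (t in seq_len(n_trunks)) {
      start <- c(H - 3, W * stats::runif(1, 0.2 + 0.4 * (t - 1),
                                         0.4 + 0.4 * (t - 1)))
      root <- add_node(clip(start))
      walk(root, stats::runif(1, -0.5, 0.5), stats::runif(1, 2.1, 3.0), 1)
    }
    structure(list(nodes = unname(nodes), edges = unname(edges), radii = radii,
                   frame = c(H, W)), class = "vein_tree")
  })
}

tree_segments <- function(tree) {
  cbind(tree$nodes[tree$edges[, 1], 1], tree$nodes[tree$edges[, 1], 2],
        tree$nodes[tree$edges[, 2], 1], tree$nodes[tree$edges[, 2], 2],
        tree$radii)
}

#' Total centreline length of a vein tree (pixels)
#' @param tree a `vein_tree`.
#' @export
tree_length <- function(tree) {
  seg <- tree_segments(tree)
  sum(sqrt((seg[, 3] - seg[, 1])^2 + (seg[, 4] - seg[, 2])^2))
}

#' Number of branch points of a vein tree
#' @param tree a `vein_tree`.
#' @export
tree_branch_points <- function(tree) {
  sum(tabulate(tree$edges[, 1], nbins = nrow(tree$nodes)) >= 2)
}

#' Rasterise a vein tree into a binary mask
#' @param tree a `vein_tree`.
#' @return `{0, 1}` matrix of the tree's frame size.
#' @export
rasterize_tree <- function(tree) {
  raster_segments_cpp(tree$frame[1], tree$frame[2], tree_segments(tree)) * 1
}

#' Render one imaging session of a wrist
#'
#' The noiseless scene is `background + illumination gradient - vein profile`
#' (a Gaussian ridge profile of the tree, so every centreline pixel is a
#' local intensity minimum), then Gaussian blur, additive sensor noise, and a
#' session-jitter affine applied identically to image and mask. Intensities
#' are clipped to [0, 255] and rounded.
#'
#' @param tree a `vein_tree`.
#' @param params a [scene_params()].
#' @param session_seed integer seed driving noise, gradient direction and
#'   jitter for this session.
#' @param jitter apply session jitter (disable for canonical-frame renders).
#' @return list with `image` (intensity matrix), `mask` (`{0, 1}` matrix) and
#'   `jitter` (the `affine_map` applied, or NULL).
#' @export
render_session <- function(tree, params = scene_params(), session_seed = 1,
                           jitter = TRUE) {
  H <- tree$frame[1]; W <- tree$frame[2]
  seg <- tree_segments(tree)
  mask <- raster_segments_cpp(H, W, seg) * 1
  nd <- segment_distance_cpp(H, W, seg, 3)
  profile <- params$vein_contrast * exp(-nd^2 / 0.45)
  with_seed(session_seed, {
    phi <- stats::runif(1, 0, 2 * pi)
    ramp <- outer(seq_len(H) - (H + 1) / 2, rep(1, W)) * cos(phi) +
      outer(rep(1, H), seq_len(W) - (W + 1) / 2) * sin(phi)
    ramp <- ramp / max(abs(ramp))
    img <- params$background_level + params$gradient_amp * ramp - profile
    if (params$blur_sigma > 0)
      img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                               sigma = params$blur_sigma))
    if (params$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, params$noise_sigma), H, W)
    af <- NULL
    if (jitter) {
      af <- random_jitter_affine(c(H, W),
                                 rotation_deg = params$jitter$rotation_deg,
                                 translate_frac = params$jitter$translate_frac,
                                 scale_range = params$jitter$scale_range)
      img <- apply_affine(img, af, "bilinear", fill = params$background_level)
      mask <- apply_affine(mask, af, "nearest", fill = 0)
    }
    list(image = round(pmin(pmax(img, 0), 255)), mask = mask, jitter = af)
  })
}

#' Generate a full synthetic wrist-vein dataset
#'
#' Expands the registry, grows one tree per (subject, wrist) and renders every
#' session. With `dir` set, writes images to
#' `<dir>/<subject>/<wrist>/<session>.png`, masks to a `masks/` mirror, and a
#' `registry.csv` with image/mask paths; rasters are 8-bit grayscale PNG.
#'
#' @param n_subjects,n_sessions,seed study design, as in [make_registry()].
#' @param params a [scene_params()].
#' @param dim frame size (H, W).
#' @param dir optional output directory.
#' @return list with `registry` (data.frame), `images`, `masks` (lists in
#'   registry row order).
#' @export
synthesize_dataset <- function(n_subjects, n_sessions = 2, seed = 1,
                               params = scene_params(), dim = c(256, 256),
                               dir = NULL) {
  reg <- make_registry(n_subjects, n_sessions, seed)
  trees <- list()
  images <- vector("list", nrow(reg))
  masks <- vector("list", nrow(reg))
  for (i in seq_len(nrow(reg))) {
    key <- paste(reg$subject_id[i], reg$wrist[i])
    if (is.null(trees[[key]]))
      trees[[key]] <- grow_vein_tree(
        subject_spec(reg$subject_id[i], reg$wrist[i], reg$tree_seed[i]), dim)
    out <- render_session(trees[[key]], params, reg$session_seed[i])
    images[[i]] <- out$image
    masks[[i]] <- out$mask
  }
  if (!is.null(dir)) {
    reg$image_path <- file.path(dir, reg$subject_id, reg$wrist,
                                sprintf("%d.png", reg$session))
    reg$mask_path <- file.path(dir, "masks", reg$subject_id, reg$wrist,
                               sprintf("%d.png", reg$session))
    for (i in seq_len(nrow(reg))) {
      write_vein_image(images[[i]], reg$image_path[i])
      write_mask(masks[[i]], reg$mask_path[i])
    }
    utils::write.csv(reg, file.path(dir, "registry.csv"), row.names = FALSE)
  }
  list(registry = reg, images = images, masks = masks)
}
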