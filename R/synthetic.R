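#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stable derived sub-seed, kept below 2^31
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  as.integer((sum(parts * (1000003^(seq_along(parts) - 1) %% 2147483629)) %% 2147483629) + 1)
}

#' Generate a synthetic tube-like neuron
#'
#' Draws a smooth random centerline through the alignment space (a correlated
#' random walk through a few control points, spline-interpolated and clamped
#' to an interior margin), samples skeleton nodes along it, and rasterizes
#' the skeleton into a volume at the given tube radius. With
#' `bilateral = TRUE` the walk starts near the x midline so the neuron
#' crosses into both hemispheres, emulating midline-crossing cells whose CDMs
#' get a combined-mirror variant in the EM library. Identical seeds give
#' identical output.
#'
#' @param seed Integer seed.
#' @param space An [alignment_space()].
#' @param radius_um Tube radius (um).
#' @param n_control Number of random-walk control points.
#' @param n_nodes Skeleton nodes sampled along the spline.
#' @param bilateral Start near the midline so the cell crosses it.
#' @param margin_um Interior margin the centerline keeps from the walls.
#' @param rasterize Also rasterize the skeleton (set `FALSE` to get just the
#'   skeleton cheaply).
#' @return A list of class `synthetic_neuron`: `skeleton`, `volume` (or
#'   `NULL`), `bilateral`, `seed`.
#' @export
generate_neuron <- function(seed, space = toy_space(), radius_um = 2,
                            n_control = 5L, n_nodes = 60L, bilateral = FALSE,
                            margin_um = NULL, rasterize = TRUE) {
  lim <- space$shape_xyz * space$voxel_size_um
  margin_um <- margin_um %||% (radius_um + 2)
  ctrl <- with_seed(seed, {
    lo <- rep(margin_um, 3); hi <- lim - margin_um
    start <- runif(3, lo + 0.15 * (hi - lo), hi - 0.15 * (hi - lo))
    if (bilateral) start[1] <- space$midline_x_um + runif(1, -0.05, 0.05) * lim[1]
    # correlated random walk: step direction drifts smoothly
    step_len <- runif(1, 0.12, 0.22) * max(lim)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    pts <- matrix(0, n_control, 3)
    pts[1, ] <- start
    for (i in 2:n_control) {
      dir <- dir + rnorm(3, sd = 0.6)
      dir <- dir / sqrt(sum(dir^2))
      pts[i, ] <- pts[i - 1, ] + dir * step_len
    }
    pts
  })
  # spline through control points, clamped inside the space
  tt <- seq_len(nrow(ctrl))
  ss <- seq(1, nrow(ctrl), length.out = n_nodes)
  path <- vapply(1:3, function(j) spline(tt, ctrl[, j], xout = ss)$y,
                 numeric(length(ss)))
  for (j in 1:3) path[, j] <- pmin(pmax(path[, j], margin_um), lim[j] - margin_um)
  if (bilateral) {
    # centre the x extent on the midline so the cell truly spans both sides
    ctr <- (min(path[, 1]) + max(path[, 1])) / 2
    path[, 1] <- path[, 1] + (space$midline_x_um - ctr)
    path[, 1] <- pmin(pmax(path[, 1], margin_um), lim[1] - margin_um)
  }
  nodes <- tibble(node_id = seq_len(n_nodes), type = c(1L, rep(3L, n_nodes - 1L)),
                  x = path[, 1], y = path[, 2], z = path[, 3],
                  radius = radius_um,
                  parent_id = c(-1L, seq_len(n_nodes - 1L)))
  skel <- skeleton(nodes, space)
  vol <- if (rasterize) rasterize_skeleton(skel, space, radius_um) else NULL
  structure(list(skeleton = skel, volume = vol, bilateral = bilateral, seed = seed),
            class = "synthetic_neuron")
}

# reflect a volume's columns about the space midline
mirror_volume <- function(vol) {
  xm <- mirror_x_map(vol$space)
  data <- array(0, dim(vol$data))
  ok <- !is.na(xm)
  data[, xm[ok], ] <- vol$data[, which(ok), ]
  volume3d(data, vol$space, vol$channel_id, vol$bit_depth)
}

#' Simulate a multi-channel LM acquisition
#'
#' Builds each channel as the sum of its assigned neuron volumes (bilateral
#' neurons contribute their mirror image too, emulating symmetric GAL4
#' expression), plus a constant background haze and additive Gaussian noise,
#' clipped to the bit depth. Channel composition is returned as ground
#' truth. Fully reproducible from the seed.
#'
#' @param neurons List of `synthetic_neuron` objects (with volumes).
#' @param channel_assignment List of integer vectors: neurons (indices into
#'   `neurons`) imaged in each channel.
#' @param background_level Constant haze intensity.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed for the noise.
#' @return A list of class `lm_sample`: `channels` (list of [volume3d()]),
#'   `truth` (tibble: channel, neuron index, neuron seed, bilateral).
#' @export
generate_lm_sample <- function(neurons, channel_assignment,
                               background_level = 10, noise_sd = 5, seed = 1L) {
  sp <- neurons[[1]]$skeleton$space
  channels <- with_seed(seed, lapply(seq_along(channel_assignment), function(ci) {
    idx <- channel_assignment[[ci]]
    bd <- 8L
    acc <- array(0, c(sp$shape_xyz[2], sp$shape_xyz[1], sp$shape_xyz[3]))
    for (i in idx) {
      v <- neurons[[i]]$volume
      if (is.null(v)) abort("neuron has no rasterized volume")
      bd <- v$bit_depth
      acc <- acc + v$data
      if (isTRUE(neurons[[i]]$bilateral)) acc <- acc + mirror_volume(v)$data
    }
    acc <- acc + background_level
    if (noise_sd > 0) acc <- acc + rnorm(length(acc), 0, noise_sd)
    maxI <- 2^bd - 1
    acc <- pmin(pmax(acc, 0), maxI)
    volume3d(acc, sp, channel_id = sprintf("ch%d", ci), bit_depth = bd)
  }))
  truth <- purrr::map_dfr(seq_along(channel_assignment), function(ci)
    tibble(channel = ci, neuron = channel_assignment[[ci]],
           neuron_seed = vapply(channel_assignment[[ci]],
                                function(i) neurons[[i]]$seed, numeric(1)),
           bilateral = vapply(channel_assignment[[ci]],
                              function(i) isTRUE(neurons[[i]]$bilateral), logical(1))))
  structure(list(channels = channels, truth = truth), class = "lm_sample")
}

#' Generate a full toy EM/LM dataset with ground truth
#'
#' Builds the complete study fixture: an EM library of `n_em` neurons (a
#' quarter bilateral/midline-crossing, which get combined-mirror CDM
#' variants), a set of LM driver lines each expressing 1-3 of those neurons
#' (one per channel, emulating stochastic multi-color labeling) plus
#' occasional distractor neurons absent from the EM library, imaged with
#' background haze and noise. Every channel is segmented with
#' [dslt_segment()], junk-filtered, and each surviving voxel set becomes one
#' LM library CDM. The truth table maps every LM voxel-set image to the EM
#' neuron(s) whose signal it overlaps.
#'
#' @param n_em Number of EM neurons.
#' @param n_lines Number of LM driver lines.
#' @param samples_per_line Imaged samples per line.
#' @param seed Master seed; all randomness derives from it.
#' @param space An [alignment_space()].
#' @param radius_um Neuron tube radius.
#' @param background_level,noise_sd LM acquisition parameters.
#' @param seg_params [segmentation_params()] for the LM segmentation.
#' @param search_threshold Foreground cutoff used when encoding CDMs.
#' @param bilateral_fraction Fraction of EM neurons that cross the midline.
#' @param distractor_prob Probability a line carries a distractor neuron.
#' @return A list of class `synthetic_dataset`: `em_lib`, `lm_lib`
#'   ([cdm_library()] tibbles), `truth` (tibble: lm image id -> em ids with
#'   overlap fractions), `lut`, `space`, `manifest` (all parameters).
#' @export
generate_dataset <- function(n_em = 50L, n_lines = 20L, samples_per_line = 1L,
                             seed = 7L, space = toy_space(), radius_um = 2,
                             background_level = 10, noise_sd = 5,
                             seg_params = segmentation_params(),
                             search_threshold = 0,
                             bilateral_fraction = 0.25,
                             distractor_prob = 0.3) {
  lut <- build_depth_lut(space$shape_xyz[3])
  nb <- max(0L, round(n_em * bilateral_fraction))
  bilateral <- c(rep(TRUE, nb), rep(FALSE, n_em - nb))

  # EM library: CDM per neuron, + combined-mirror variant for midline crossers
  em_cdms <- list(); em_ids <- character(0)
  em_skels <- vector("list", n_em)
  for (i in seq_len(n_em)) {
    nrn <- generate_neuron(derive_seed(seed, 1, i), space, radius_um,
                           bilateral = bilateral[i])
    body <- sprintf("body_%03d", i)
    cdm <- encode_volume(nrn$volume, lut, source_id = body)
    nrn$volume <- NULL                   # re-rasterized on demand; saves memory
    em_skels[[i]] <- nrn
    em_cdms <- c(em_cdms, list(cdm)); em_ids <- c(em_ids, body)
    if (crosses_midline(nrn$skeleton)) {
      comb <- combine_mirror(cdm)
      em_cdms <- c(em_cdms, list(comb)); em_ids <- c(em_ids, body)
    }
  }
  em_lib <- cdm_library(em_cdms, "EM", em_ids)

  # LM lines: neuron draws and distractors
  draws <- with_seed(derive_seed(seed, 2), lapply(seq_len(n_lines), function(l) {
    k <- sample(1:3, 1)
    list(members = sort(sample(n_em, k)),
         distract = runif(1) < distractor_prob)
  }))

  lm_cdms <- list(); lm_lines <- character(0); lm_samples <- character(0)
  lm_index <- integer(0)
  truth_rows <- list()
  for (l in seq_len(n_lines)) {
    line_id <- sprintf("line_%03d", l)
    members <- draws[[l]]$members
    for (s in seq_len(samples_per_line)) {
      sample_id <- sprintf("%s_s%d", line_id, s)
      neurons <- lapply(members, function(i) {
        nrn <- em_skels[[i]]
        if (is.null(nrn$volume))
          nrn$volume <- rasterize_skeleton(nrn$skeleton, space, radius_um)
        nrn
      })
      assignment <- as.list(seq_along(members))     # one neuron per channel
      member_ids <- sprintf("body_%03d", members)
      if (draws[[l]]$distract) {
        d <- generate_neuron(derive_seed(seed, 3, l, s), space, radius_um)
        neurons <- c(neurons, list(d))
        ch <- 1L + (l %% length(assignment))        # share a channel
        assignment[[ch]] <- c(assignment[[ch]], length(neurons))
        member_ids <- c(member_ids, sprintf("distractor_%03d_%d", l, s))
      }
      smp <- generate_lm_sample(neurons, assignment, background_level, noise_sd,
                                seed = derive_seed(seed, 4, l, s))
      # per-neuron foreground masks for truth attribution
      fg_masks <- lapply(seq_along(neurons), function(i) {
        v <- neurons[[i]]$volume$data > 0
        if (isTRUE(neurons[[i]]$bilateral))
          v <- v | (mirror_volume(neurons[[i]]$volume)$data > 0)
        v
      })
      for (ci in seq_along(smp$channels)) {
        mask <- dslt_segment(smp$channels[[ci]], seg_params)
        sets <- filter_components(
          label_components(mask, space, smp$channels[[ci]],
                           id_prefix = sprintf("%s_ch%d", sample_id, ci)),
          seg_params)
        cdms <- voxelsets_to_cdms(sets, lut, space)
        for (k in seq_along(sets)) {
          vox <- sets[[k]]$voxels
          lin <- cbind(vox$y + 1L, vox$x + 1L, vox$z + 1L)
          ovl <- vapply(seq_along(neurons), function(i)
            sum(fg_masks[[i]][lin]) / nrow(vox), numeric(1))
          best <- which(ovl > 0.1)
          if (length(best) == 0L) next                 # unattributable junk
          lm_cdms <- c(lm_cdms, list(cdms[[k]]))
          lm_lines <- c(lm_lines, line_id)
          lm_samples <- c(lm_samples, sample_id)
          lm_index <- c(lm_index, ci)
          truth_rows <- c(truth_rows, list(tibble(
            lm_id = sets[[k]]$id, line_id = line_id, sample_id = sample_id,
            channel = ci, em_id = member_ids[best], overlap = ovl[best],
            in_em_library = grepl("^body_", member_ids[best]))))
        }
      }
    }
  }
  if (length(lm_cdms) == 0L) abort("no LM voxel sets survived segmentation")
  lm_lib <- cdm_library(lm_cdms, "LM", lm_lines, lm_samples, lm_index)
  truth <- dplyr::bind_rows(truth_rows)
  manifest <- list(n_em = n_em, n_lines = n_lines,
                   samples_per_line = samples_per_line, seed = seed,
                   space = list(name = space$name, shape_xyz = space$shape_xyz,
                                voxel_size_um = space$voxel_size_um,
                                midline_x_um = space$midline_x_um),
                   radius_um = radius_um, background_level = background_level,
                   noise_sd = noise_sd, bilateral_fraction = bilateral_fraction,
                   distractor_prob = distractor_prob,
                   seg_params = unclass(seg_params))
  structure(list(em_lib = em_lib, lm_lib = lm_lib, truth = truth, lut = lut,
                 space = space, manifest = manifest),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d EM images (%d neurons), %d LM voxel-set images, %d lines\n",
              nrow(x$em_lib), length(unique(x$em_lib$neuron_or_line_id)),
              nrow(x$lm_lib), length(unique(x$lm_lib$neuron_or_line_id))))
  invisible(x)
}
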