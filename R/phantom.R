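# Run code under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Aliased frequency under discrete sampling
#'
#' Folds a physiological frequency (e.g. a respiratory rate above the
#' sampling rate) into the observable band `[0, fs/2]`.
#'
#' @param f Frequency in Hz before sampling.
#' @param fs Sampling frequency in Hz (1 / TR_vol).
#' @return Alias frequency in Hz, in `[0, fs/2]`.
#' @export
alias_frequency <- function(f, fs) {
  if (any(f < 0) || fs <= 0) stop("frequencies must be non-negative, fs > 0")
  fm <- f %% fs
  pmin(fm, fs - fm)
}

# Zero-mean, unit-variance courses whose spectrum is confined to [f_lo, f_hi]:
# white noise shaped in the frequency domain.
band_limited_courses <- function(n, n_frames, tr_vol, band) {
  freqs <- (0:(n_frames - 1)) / (n_frames * tr_vol)
  freqs <- pmin(freqs, 1 / tr_vol - freqs)  # two-sided -> folded frequency
  keep <- freqs >= band[1] & freqs <= band[2]
  if (!any(keep)) stop("band contains no Fourier frequencies at this length")
  out <- matrix(0, n_frames, n)
  for (j in seq_len(n)) {
    spec <- stats::fft(stats::rnorm(n_frames))
    spec[!keep] <- 0
    x <- Re(stats::fft(spec, inverse = TRUE)) / n_frames
    x <- x - mean(x)
    out[, j] <- x / stats::sd(x)
  }
  out
}

#' Specification of a synthetic 4D BOLD phantom
#'
#' Defaults reproduce the acquisition geometry the package targets: a
#' 64x64x8 voxel EPI grid, TR_vol = 1.6 s, 370 frames, neural fluctuations
#' confined to 0.01-0.31 Hz, a shared global confound, an aliased
#' respiratory sinusoid, and spatially varying Gaussian thermal noise with
#' a surface-coil (dorsal-bright) sensitivity profile.
#'
#' @param dim Voxel grid, length 3.
#' @param voxdim Voxel sizes in mm.
#' @param tr_vol Volume sampling interval in seconds.
#' @param n_frames Number of frames.
#' @param n_networks Number of planted blob network sources.
#' @param band `(f_lo, f_hi)` in Hz for the neural courses.
#' @param baseline Mean in-brain intensity (arbitrary units).
#' @param network_amp Amplitude (s.d. units of intensity) of each network
#'   course at its map peak.
#' @param global_amp Amplitude of the shared global confound course.
#' @param resp_freq Respiratory frequency in Hz before aliasing.
#' @param resp_amp Amplitude of the (aliased) respiratory sinusoid.
#' @param noise_sigma Thermal-noise s.d. at the dorsal surface.
#' @param coil_slope Relative increase of noise s.d. per unit depth: the
#'   ventral-most slice has s.d. `noise_sigma * (1 + coil_slope)`; 0 gives
#'   a uniform map.
#' @param artifact_amp Amplitude of an optional structured artifact (a
#'   spatial pattern coherently modulated by a sparse spike-train course);
#'   0 disables.
#' @param artifact_type Spatial pattern of the structured artifact:
#'   `"speckle"` (default; a random sparse subset of brain voxels, the
#'   scattered-clusters artifact archetype) or `"sheet"` (a whole slice).
#' @param roi_cor_target Optional ROI x ROI correlation matrix; when given,
#'   planted sources are ROI-wise courses mixed to attain exactly these
#'   correlations (replacing the blob networks).
#' @param n_roi_per_hemi ROIs per hemisphere in the geometric parcellation.
#' @param seed Mandatory integer seed.
#' @param signal_seed Optional separate seed for the planted signal part
#'   (network maps and courses, respiratory confound location): subjects of
#'   one cohort share it so they share the underlying connectivity while
#'   noise and confound amplitudes vary. Defaults to `seed`.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(64, 64, 8), voxdim = c(0.36, 0.36, 1.12),
                         tr_vol = 1.6, n_frames = 370, n_networks = 3,
                         band = c(0.01, 0.31), baseline = 100,
                         network_amp = 1.0, global_amp = 0.5,
                         resp_freq = 1.35, resp_amp = 0.5,
                         noise_sigma = 1.5, coil_slope = 1.0,
                         artifact_amp = 0,
                         artifact_type = c("speckle", "sheet"),
                         roi_cor_target = NULL,
                         n_roi_per_hemi = 14, seed, signal_seed = NULL) {
  artifact_type <- match.arg(artifact_type)
  if (missing(seed)) stop("phantom_spec requires an explicit seed")
  nyq <- 1 / (2 * tr_vol)
  if (!(band[1] >= 0 && band[1] < band[2] && band[2] <= nyq + 1e-12))
    stop("band must satisfy 0 <= f_lo < f_hi <= Nyquist = ", signif(nyq, 4))
  if (any(c(network_amp, global_amp, resp_amp, noise_sigma, artifact_amp) < 0))
    stop("amplitudes must be >= 0")
  if (n_networks >= n_frames) stop("n_networks must be below n_frames")
  structure(list(dim = as.integer(dim), voxdim = voxdim, tr_vol = tr_vol,
                 n_frames = as.integer(n_frames), n_networks = n_networks,
                 band = band, baseline = baseline, network_amp = network_amp,
                 global_amp = global_amp, resp_freq = resp_freq,
                 resp_amp = resp_amp, noise_sigma = noise_sigma,
                 coil_slope = coil_slope, artifact_amp = artifact_amp,
                 artifact_type = artifact_type,
                 roi_cor_target = roi_cor_target,
                 n_roi_per_hemi = as.integer(n_roi_per_hemi),
                 seed = as.integer(seed),
                 signal_seed = as.integer(if (is.null(signal_seed)) seed
                                          else signal_seed)),
            class = "phantom_spec")
}

# Ellipsoidal brain mask centred in the grid.
phantom_mask_array <- function(d) {
  cx <- (d + 1) / 2
  semi <- pmax(d * 0.45, 1)
  ix <- array(0, dim = d)
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  r2 <- ((g$x - cx[1]) / semi[1])^2 + ((g$y - cx[2]) / semi[2])^2 +
    ((g$z - cx[3]) / semi[3])^2
  array(r2 <= 1, dim = d)
}

# Deterministic geometric tiling of the mask into left/right hemispheric
# ROI chunks of near-equal size (sorted by slice, then anterior-posterior,
# so ROIs are contiguous slice slabs within a hemisphere).
phantom_parcellation <- function(mask_arr, n_per_hemi) {
  d <- dim(mask_arr)
  idx <- which(mask_arr)
  co <- arrayInd(idx, d)
  left <- co[, 1] <= d[1] / 2
  lab <- integer(length(idx))
  assign_chunks <- function(sel, offset) {
    sub <- which(sel)
    ord <- sub[order(co[sub, 3], co[sub, 2], co[sub, 1])]
    k <- pmin(n_per_hemi, length(ord))
    chunk <- ceiling(seq_along(ord) / (length(ord) / k))
    lab[ord] <<- offset + pmin(chunk, k)
  }
  assign_chunks(left, 0L)
  assign_chunks(!left, n_per_hemi)
  labels <- array(0L, dim = d)
  labels[idx] <- lab
  ids <- sort(unique(lab))
  data.frame(id = ids,
             name = sprintf("ROI_%s%02d",
                            ifelse(ids <= n_per_hemi, "L", "R"),
                            ifelse(ids <= n_per_hemi, ids, ids - n_per_hemi)),
             hemisphere = ifelse(ids <= n_per_hemi, "L", "R"),
             stringsAsFactors = FALSE) -> table
  list(labels = labels, table = table)
}

# Centres of the eight octants of the grid bounding box (well separated).
octant_centres <- function(d) {
  qs <- function(n) if (n >= 4) c(round(n * 0.3), round(n * 0.7)) else
    c(max(1, round(n * 0.4)), min(n, round(n * 0.6)))
  as.matrix(expand.grid(x = qs(d[1]), y = qs(d[2]), z = qs(d[3])))
}

# Compact 3D Gaussian blob map, peak 1, centred at `centre` with s.d. in voxels.
gaussian_blob <- function(d, centre, sd_vox) {
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  r2 <- ((g$x - centre[1]) / sd_vox[1])^2 + ((g$y - centre[2]) / sd_vox[2])^2 +
    ((g$z - centre[3]) / sd_vox[3])^2
  array(exp(-r2 / 2), dim = d)
}

#' Generate a synthetic 4D BOLD phantom with known ground truth
#'
#' The series is `baseline + sum(maps x courses) + global + respiratory +
#' Gaussian(0, sigma map)` inside an ellipsoidal brain; the parcellation is
#' a deterministic geometric tiling into `n_roi_per_hemi` ROIs per
#' hemisphere. Identical seeds yield bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `series` ([bold_series()]), `mask` ([brain_mask()]),
#'   `labels` ([label_volume()]) and `truth` (planted maps, courses, global
#'   and aliased respiratory courses, sigma map, ROI correlation targets).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    d <- spec$dim
    nt <- spec$n_frames
    grid <- volume_grid(d[1], d[2], d[3], spec$voxdim[1], spec$voxdim[2],
                        spec$voxdim[3])
    mask_arr <- phantom_mask_array(d)
    parc <- phantom_parcellation(mask_arr, spec$n_roi_per_hemi)
    in_idx <- which(mask_arr)

    maps <- list()
    courses <- NULL
    roi_cor <- NULL
    with_seed(spec$signal_seed, {
    if (!is.null(spec$roi_cor_target)) {
      R <- as.matrix(spec$roi_cor_target)
      n_roi <- nrow(parc$table)
      if (!all(dim(R) == n_roi) || any(abs(R - t(R)) > 1e-12) ||
          any(abs(diag(R) - 1) > 1e-12))
        stop("roi_cor_target must be a symmetric ", n_roi, "x", n_roi,
             " correlation matrix")
      raw <- band_limited_courses(n_roi, nt, spec$tr_vol, spec$band)
      q <- qr.Q(qr(scale(raw, scale = FALSE)))
      mixed <- q %*% chol(R)                      # exact sample correlation R
      mixed <- scale(mixed, center = FALSE,
                     scale = apply(mixed, 2, stats::sd) / spec$network_amp)
      courses <- mixed
      for (k in seq_len(n_roi)) {
        m <- array(0, dim = d)
        m[parc$labels == parc$table$id[k]] <- 1
        maps[[k]] <- m
      }
      roi_cor <- R
    } else if (spec$n_networks > 0) {
      courses <- band_limited_courses(spec$n_networks, nt, spec$tr_vol,
                                      spec$band) * spec$network_amp
      # low-overlap placement: distinct octants of the brain, so the
      # planted networks are spatially separable sources
      oct <- octant_centres(d)
      pick <- sample(nrow(oct))
      for (k in seq_len(spec$n_networks)) {
        ctr <- oct[pick[(k - 1) %% nrow(oct) + 1], ]
        maps[[k]] <- gaussian_blob(d, ctr,
                                   pmax(d / 8, c(2, 2, 1.2))) * mask_arr
      }
    }
    # respiratory confound: an RSN-like blob (placed away from the planted
    # networks) whose aliased sinusoid falls inside the analyzed band - the
    # FIX-resistant physiological component that motivates global-signal
    # adjustment
    resp_centre <- if (spec$n_networks > 0 && is.null(spec$roi_cor_target)) {
      oct[pick[spec$n_networks %% nrow(oct) + 1], ]
    } else {
      arrayInd(in_idx[sample.int(length(in_idx), 1)], d)
    }
    })

    resp_w <- gaussian_blob(d, resp_centre, pmax(d / 5, 1.5)) * mask_arr

    tvec <- (seq_len(nt) - 1) * spec$tr_vol
    gcourse <- if (spec$global_amp > 0)
      band_limited_courses(1, nt, spec$tr_vol, spec$band)[, 1] * spec$global_amp
    else numeric(nt)
    f_alias <- alias_frequency(spec$resp_freq, 1 / spec$tr_vol)
    rphase <- stats::runif(1, 0, 2 * pi)
    rcourse <- if (spec$resp_amp > 0)
      sin(2 * pi * f_alias * tvec + rphase) * spec$resp_amp else numeric(nt)
    rcourse <- rcourse - mean(rcourse)

    # surface-coil noise profile: s.d. grows with depth from the dorsal
    # (high-z) surface
    depth <- if (d[3] > 1) (d[3] - seq_len(d[3])) / (d[3] - 1) else rep(0, d[3])
    sigma_prof <- 1 + spec$coil_slope * depth
    sigma_map <- array(rep(sigma_prof, each = d[1] * d[2]), dim = d) *
      spec$noise_sigma

    art_map <- NULL
    art_course <- NULL
    if (spec$artifact_amp > 0) {
      art_map <- array(0, dim = d)
      if (identical(spec$artifact_type, "sheet")) {
        # place the sheet on a well-populated slice so its energy does
        # not vanish at the ellipsoid tips
        per_slice <- apply(mask_arr, 3, sum)
        zslice <- sample(which(per_slice >= 0.6 * max(per_slice)), 1)
        art_map[, , zslice] <- 1
      } else {
        # scattered speckle: a sparse subset of brain voxels modulated
        # coherently (coil/interference-like). Sampling density varies by
        # ROI so the artifact loads regions unevenly - a structured
        # contaminant that a single global regressor cannot absorb.
        w_roi <- stats::runif(nrow(parc$table), 0.02, 1)
        prob <- w_roi[match(parc$labels[in_idx], parc$table$id)]
        pick <- sample(length(in_idx), max(2L, round(0.15 * length(in_idx))),
                       prob = prob)
        art_map[in_idx[pick]] <- 1
      }
      art_map <- art_map * mask_arr
      # sparse transient spikes (scanner/motion-like): temporally
      # super-Gaussian, broadband, and robust to sub-TR resampling
      n_spikes <- max(6L, nt %/% 30L)
      spikes <- numeric(nt)
      spikes[sample.int(nt, n_spikes)] <- sample(c(-1, 1), n_spikes,
                                                 replace = TRUE)
      kern <- stats::dnorm(-4:4, sd = 1.2)
      art_course <- stats::filter(spikes, kern, sides = 2)
      art_course[is.na(art_course)] <- 0
      art_course <- art_course - mean(art_course)
      art_course <- art_course / stats::sd(art_course) * spec$artifact_amp
    }

    flat <- matrix(0, prod(d), nt)
    for (k in seq_along(maps))
      flat[in_idx, ] <- flat[in_idx, ] +
        as.numeric(maps[[k]])[in_idx] %o% courses[, k]
    flat[in_idx, ] <- flat[in_idx, ] + spec$baseline +
      rep(1, length(in_idx)) %o% gcourse +
      as.numeric(resp_w)[in_idx] %o% rcourse
    if (!is.null(art_map))
      flat[in_idx, ] <- flat[in_idx, ] +
        as.numeric(art_map)[in_idx] %o% art_course

    noiseless_roi <- roi_mean_courses(flat, parc$labels, parc$table$id)
    if (is.null(roi_cor) && nrow(noiseless_roi) > 1) {
      sds <- apply(noiseless_roi, 1, stats::sd)
      roi_cor <- if (all(sds > 0)) stats::cor(t(noiseless_roi)) else NULL
    }

    if (spec$noise_sigma > 0)
      flat <- flat + matrix(stats::rnorm(prod(d) * nt), prod(d), nt) *
        as.numeric(sigma_map)

    series <- bold_series(array(flat, dim = c(d, nt)), grid, spec$tr_vol)
    truth <- list(maps = maps, courses = courses, global_course = gcourse,
                  resp_course = rcourse, resp_alias_freq = f_alias,
                  sigma_map = sigma_map, roi_cor = roi_cor,
                  artifact_map = art_map, artifact_course = art_course,
                  noiseless_roi_courses = noiseless_roi)
    list(series = series,
         mask = brain_mask(mask_arr, grid),
         labels = label_volume(parc$labels, grid, parc$table),
         truth = truth)
  })
}

# ROI-mean courses from a flat voxel x time matrix.
roi_mean_courses <- function(flat, labels, ids) {
  out <- matrix(0, length(ids), ncol(flat))
  for (i in seq_along(ids)) {
    v <- which(labels == ids[i])
    out[i, ] <- colMeans(flat[v, , drop = FALSE])
  }
  rownames(out) <- as.character(ids)
  out
}

#' Specification of a synthetic two-group FC study
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param n_roi Number of ROIs (default 28).
#' @param effect_edges Two-column matrix of ROI index pairs carrying the
#'   planted group effect (off-diagonal).
#' @param delta_z Effect size added to group B on those edges, Fisher-z units.
#' @param within_sd Within-group s.d. of each edge's z value.
#' @param seed Mandatory integer seed.
#' @return A list of class `group_study_spec`.
#' @export
group_study_spec <- function(n_per_group = 8, n_roi = 28,
                             effect_edges = NULL, delta_z = 0,
                             within_sd = 0.1, seed) {
  if (missing(seed)) stop("group_study_spec requires an explicit seed")
  if (n_per_group < 2) stop("need >= 2 subjects per group")
  if (!is.null(effect_edges)) {
    effect_edges <- matrix(as.integer(effect_edges), ncol = 2)
    if (any(effect_edges < 1) || any(effect_edges > n_roi))
      stop("effect edges reference ROIs outside 1..", n_roi)
    if (any(effect_edges[, 1] == effect_edges[, 2]))
      stop("planted effects must lie on off-diagonal edges")
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 n_roi = as.integer(n_roi), effect_edges = effect_edges,
                 delta_z = delta_z, within_sd = within_sd,
                 seed = as.integer(seed)),
            class = "group_study_spec")
}

#' Generate per-subject Fisher-z FC matrices for a two-group study
#'
#' Group A matrices are `base + noise`; group B adds `delta_z` on the
#' planted edges only. All matrices are symmetric with zero diagonal.
#'
#' @param spec A [group_study_spec()].
#' @return List with `z` (list of matrices), `group` (factor A/B), `base`
#'   (shared mean matrix) and `effect_edges`.
#' @export
generate_group_study <- function(spec) {
  stopifnot(inherits(spec, "group_study_spec"))
  with_seed(spec$seed, {
    p <- spec$n_roi
    base <- matrix(0, p, p)
    ut <- upper.tri(base)
    base[ut] <- stats::rnorm(sum(ut), mean = 0.3, sd = 0.2)
    base <- base + t(base)
    effect <- matrix(0, p, p)
    if (!is.null(spec$effect_edges) && spec$delta_z != 0) {
      for (r in seq_len(nrow(spec$effect_edges))) {
        i <- spec$effect_edges[r, 1]; j <- spec$effect_edges[r, 2]
        effect[i, j] <- effect[j, i] <- spec$delta_z
      }
    }
    n <- spec$n_per_group
    group <- factor(rep(c("A", "B"), each = n))
    z <- vector("list", 2 * n)
    for (s in seq_len(2 * n)) {
      noise <- matrix(0, p, p)
      noise[ut] <- stats::rnorm(sum(ut), sd = spec$within_sd)
      noise <- noise + t(noise)
      m <- base + noise + if (group[s] == "B") effect else 0
      diag(m) <- 0
      z[[s]] <- m
    }
    list(z = z, group = group, base = base, effect_edges = spec$effect_edges)
  })
}

#' Generate a labeled corpus of signal / artifact ICA-like components
#'
#' Signal exemplars are a few compact clusters with band-limited
#' (0.01-0.1 Hz) time courses; artifact exemplars are slice-covering
#' sheets, scattered speckle, brain-rim patterns, or compact maps with
#' near-Nyquist courses. Features are computed with [extract_features()]
#' on each exemplar, and ground-truth labels are attached.
#'
#' @param n_signal,n_artifact Exemplar counts (>= 1).
#' @param seed Integer seed.
#' @param dim Grid used for the exemplar maps.
#' @param n_frames,tr_vol Course length and sampling interval.
#' @return List with `features` (data.frame), `labels` (factor
#'   signal/artifact), `maps`, `courses`, and the `mask` used.
#' @export
generate_labeled_components <- function(n_signal, n_artifact, seed,
                                        dim = c(24, 24, 6), n_frames = 240,
                                        tr_vol = 1.6) {
  if (n_signal < 1 || n_artifact < 1) stop("counts must be >= 1")
  with_seed(seed, {
    d <- as.integer(dim)
    grid <- volume_grid(d[1], d[2], d[3])
    mask_arr <- phantom_mask_array(d)
    mask <- brain_mask(mask_arr, grid)
    in_idx <- which(mask_arr)
    co <- arrayInd(in_idx, d)
    n <- n_signal + n_artifact
    labels <- factor(rep(c("signal", "artifact"), c(n_signal, n_artifact)),
                     levels = c("signal", "artifact"))
    maps <- vector("list", n)
    courses <- matrix(0, n_frames, n)
    tvec <- (seq_len(n_frames) - 1) * tr_vol

    zmap <- function(v) {                      # standardize over the mask
      v[in_idx] <- (v[in_idx] - mean(v[in_idx])) / stats::sd(v[in_idx])
      v[-in_idx] <- 0
      v
    }
    nyq <- 1 / (2 * tr_vol)
    # course spectra overlap between classes (real ICA courses are mixtures,
    # and spatial maps are the more reliable cue): every course is a blend
    # of an in-band neural part and a broadband high-frequency part, with
    # the blend weight drawn from class-dependent but overlapping ranges.
    blend_course <- function(w_high) {
      lo <- band_limited_courses(1, n_frames, tr_vol, c(0.01, 0.1))[, 1]
      hi <- band_limited_courses(1, n_frames, tr_vol, c(0.5 * nyq, nyq))[, 1]
      sqrt(1 - w_high^2) * lo + w_high * hi
    }
    for (i in seq_len(n)) {
      base <- array(0, dim = d)
      base[in_idx] <- stats::rnorm(length(in_idx), sd = 0.5)
      if (labels[i] == "signal") {
        nb <- sample(1:3, 1)
        for (b in seq_len(nb)) {
          ctr <- co[sample(nrow(co), 1), ]
          base <- base + 7 * gaussian_blob(d, ctr, pmax(d / 8, 1.2)) * mask_arr
        }
        courses[, i] <- blend_course(stats::runif(1, 0, 0.8))
      } else {
        kind <- sample(c("sheet", "speckle", "rim", "highfreq"), 1)
        if (kind == "sheet") {
          zs <- sample(seq_len(d[3]), 1)
          sl <- array(0, dim = d); sl[, , zs] <- 1
          base <- base + 7 * sl * mask_arr
          courses[, i] <- blend_course(stats::runif(1, 0.3, 1))
        } else if (kind == "speckle") {
          pick <- sample(length(in_idx), min(60, length(in_idx) %/% 4))
          base[in_idx[pick]] <- base[in_idx[pick]] +
            sample(c(-8, 8), length(pick), replace = TRUE)
          courses[, i] <- blend_course(stats::runif(1, 0.3, 1))
        } else if (kind == "rim") {
          rim <- mask_boundary(mask_arr)
          base <- base + 7 * rim
          courses[, i] <- blend_course(stats::runif(1, 0.3, 1))
        } else {
          ctr <- co[sample(nrow(co), 1), ]
          base <- base + 7 * gaussian_blob(d, ctr, pmax(d / 10, 1.2)) * mask_arr
          courses[, i] <- blend_course(stats::runif(1, 0.9, 1))
        }
      }
      maps[[i]] <- zmap(base)
    }
    courses <- scale(courses)
    cs <- component_set(maps, courses, mask, explained_variance = 1)
    features <- extract_features(cs, mask)
    list(features = features, labels = labels, maps = maps,
         courses = courses, mask = mask, tr_vol = tr_vol)
  })
}

# Mask voxels with at least one 6-neighbour outside the mask (or the volume).
mask_boundary <- function(mask_arr) {
  d <- dim(mask_arr)
  pad <- array(FALSE, dim = d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask_arr
  inner <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  mask_arr & !inner
}

#' Generate a cohort of subject scans with planted structured artifacts
#'
#' Every subject is a phantom sharing one planted connectivity structure
#' (common `signal_seed`) while thermal noise and two structured
#' contaminants vary per subject: a slice-sheet artifact with an
#' out-of-band course, local to a few slice-slab ROIs, which ICA-based
#' cleaning can remove but global-signal adjustment cannot; and a shared
#' global confound of subject-varying amplitude, which global-signal
#' partial correlation removes but cleaning keeps (it is physiological,
#' signal-like to the classifier). Amplitudes are drawn uniformly from the
#' given ranges. This is the harness input for comparing processing
#' variants.
#'
#' @param n_subjects Number of subjects (all labelled CTL).
#' @param spec A [phantom_spec()] template; its `global_amp` /
#'   `artifact_amp` are overridden per subject and its `seed` supplies the
#'   shared signal.
#' @param global_range,artifact_range Ranges of per-subject amplitudes.
#' @param seed Integer seed.
#' @return List of [subject_scan()] plus the shared `mask` / `labels` and
#'   per-subject `truths`.
#' @export
generate_artifact_cohort <- function(n_subjects, spec,
                                     global_range = c(1, 4),
                                     artifact_range = c(1, 4), seed) {
  stopifnot(inherits(spec, "phantom_spec"), n_subjects >= 2)
  with_seed(seed, {
    sub_seeds <- sample.int(2^31 - 2, n_subjects)
    gl <- stats::runif(n_subjects, global_range[1], global_range[2])
    ar <- stats::runif(n_subjects, artifact_range[1], artifact_range[2])
    scans <- vector("list", n_subjects)
    truths <- vector("list", n_subjects)
    shared <- NULL
    for (s in seq_len(n_subjects)) {
      sp <- spec
      sp$signal_seed <- spec$seed
      sp$seed <- sub_seeds[s]
      sp$global_amp <- gl[s]
      sp$artifact_amp <- ar[s]
      ph <- generate_phantom(sp)
      if (is.null(shared)) shared <- ph
      scans[[s]] <- subject_scan(sprintf("sub%02d", s), "CTL",
                                 timepoint = 2, run = 1, series = ph$series)
      truths[[s]] <- ph$truth
    }
    list(scans = scans, mask = shared$mask, labels = shared$labels,
         truths = truths)
  })
}

#' Label ICA components of a phantom by ground-truth correlation
#'
#' Mirrors manual FIX training labels on data with known sources. Since
#' ICA components can be mixtures, each course is scored by the multiple
#' R of a joint regression on all planted signal courses (networks,
#' global and respiratory confound) and by its correlation with the
#' structured artifact course; a component is an artifact only when it is
#' positively matched to the artifact more strongly than to the signal
#' set.
#'
#' @param cs A [component_set()].
#' @param truth The `truth` element of [generate_phantom()].
#' @param r_min Minimum artifact correlation to count as a match
#'   (default 0.4).
#' @return Factor with levels `signal` / `artifact`, one per component.
#' @export
label_components_by_truth <- function(cs, truth, r_min = 0.4) {
  stopifnot(inherits(cs, "component_set"))
  sig_courses <- cbind(truth$courses, truth$global_course, truth$resp_course)
  sig_courses <- sig_courses[, apply(sig_courses, 2, stats::sd) > 0,
                             drop = FALSE]
  art_courses <- truth$artifact_course
  n <- cs$n_components
  lab <- character(n)
  for (k in seq_len(n)) {
    x <- cs$courses[, k]
    s_sig <- if (is.null(sig_courses) || ncol(sig_courses) == 0) 0 else
      sqrt(suppressWarnings(summary(stats::lm(x ~ sig_courses)))$r.squared)
    s_art <- if (is.null(art_courses)) 0 else
      abs(stats::cor(x, art_courses))
    lab[k] <- if (s_art >= r_min && s_art > s_sig) "artifact" else "signal"
  }
  factor(lab, levels = c("signal", "artifact"))
}

#' Train a classifier on ICA components of a labelled training cohort
#'
#' The synthetic analogue of FIX training on hand-labelled sessions: each
#' training subject is denoised and preprocessed, decomposed with
#' [spatial_ica()], its components labelled against the planted ground
#' truth, and a classifier is trained on the pooled features.
#'
#' @param cohort A [generate_artifact_cohort()] result.
#' @param cfg A [pipeline_config()] supplying stage parameters
#'   (`n_components`, seeds, kernel, filters).
#' @param seed Seed for classifier training.
#' @return A list with `classifier` ([train_classifier()] model),
#'   `features`, `labels`.
#' @export
train_on_cohort <- function(cohort, cfg, seed) {
  feats <- list()
  labs <- list()
  for (s in seq_along(cohort$scans)) {
    pp <- highpass(smooth_series(slice_timing_correct(
      mppca_denoise(cohort$scans[[s]]$series, cohort$mask,
                    cfg$kernel)$denoised,
      cfg$slice_order, cfg$ref_slice), cfg$fwhm), cfg$cutoff)
    cs <- spatial_ica(pp, cohort$mask,
                      n_components = min(cfg$n_components,
                                         pp$n_frames - 1L),
                      seed = cfg$seed + s)
    feats[[s]] <- extract_features(cs, cohort$mask, tr_vol = pp$tr_vol)
    labs[[s]] <- label_components_by_truth(cs, cohort$truths[[s]])
  }
  features <- do.call(rbind, feats)
  labels <- factor(unlist(lapply(labs, as.character)),
                   levels = c("signal", "artifact"))
  list(classifier = train_classifier(features, labels, seed = seed),
       features = features, labels = labels)
}
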