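# Optional image-level forward model: render traces as synthetic TIRF image
# stacks (Gaussian point-spread spots on a noisy background) and recover
# molecule positions and traces from such stacks.

#' Render a trace set as synthetic image stacks
#'
#' Each frame is `background + Gaussian spots + noise`: molecule `i`
#' contributes a 2-D Gaussian of total integrated intensity equal to its
#' trace intensity above background at that frame, centred at
#' `molecule_positions[i, ]` with SD `psf_sigma` pixels.
#'
#' @param traces A `trace_set`.
#' @param psf_sigma PSF standard deviation, pixels.
#' @param image_size `c(nx, ny)` in pixels.
#' @param molecule_positions Matrix `n x 2` of (x, y) pixel positions, one
#'   row per molecule in `traces` (must lie within the image).
#' @param seed Optional RNG seed for the pixel noise.
#' @param background Camera background level per pixel.
#' @param noise_sd Gaussian pixel noise SD.
#' @return A list per channel of arrays `nx x ny x n_frames`, with attributes
#'   `positions`, `schedule` and `crowded` (logical per molecule: nearer than
#'   `2 * psf_sigma` to another molecule).
#' @export
render_movie <- function(traces, psf_sigma, image_size, molecule_positions,
                         seed = NULL, background = 100, noise_sd = 2) {
  if (!is.null(seed)) set.seed(seed)
  schedule <- attr(traces, "schedule")
  df <- as.data.frame(traces)
  mols <- sort(unique(df$molecule_id))
  pos <- as.matrix(molecule_positions)
  if (nrow(pos) != length(mols))
    stop("need one position per molecule")
  if (any(pos[, 1] < 1 | pos[, 1] > image_size[1] |
          pos[, 2] < 1 | pos[, 2] > image_size[2]))
    stop("molecule positions outside the image")
  dd <- as.matrix(stats::dist(pos))
  diag(dd) <- Inf
  crowded <- apply(dd, 1, min) < 2 * psf_sigma
  channels <- sort(unique(df$channel))
  nf <- max(df$frame)
  # per-molecule local PSF footprint (truncated at 4 sigma)
  r <- ceiling(4 * psf_sigma)
  stacks <- lapply(channels, function(ch) {
    arr <- array(stats::rnorm(image_size[1] * image_size[2] * nf,
                              background, noise_sd),
                 dim = c(image_size[1], image_size[2], nf))
    dch <- df[df$channel == ch, ]
    base <- stats::median(dch$intensity)
    for (m in seq_along(mols)) {
      dm <- dch[dch$molecule_id == mols[m], ]
      amp <- dm$intensity[order(dm$frame)] - base
      amp[amp < 0] <- 0
      if (!any(amp > 0)) next
      cx <- pos[m, 1]; cy <- pos[m, 2]
      xs <- max(1, round(cx) - r):min(image_size[1], round(cx) + r)
      ys <- max(1, round(cy) - r):min(image_size[2], round(cy) + r)
      gx <- stats::dnorm(xs, cx, psf_sigma)
      gy <- stats::dnorm(ys, cy, psf_sigma)
      psf <- outer(gx, gy)          # integrates to ~1 over the footprint
      on <- which(amp > 0)
      for (f in on)
        arr[xs, ys, f] <- arr[xs, ys, f] + amp[f] * psf
    }
    arr
  })
  names(stacks) <- paste0("channel", channels)
  structure(stacks, positions = pos, schedule = schedule, crowded = crowded,
            psf_sigma = psf_sigma, background = background,
            class = "movie_set")
}

#' Detect spots in an image stack and extract traces
#'
#' Works on the time-summed image: local maxima above a robust threshold
#' become candidate spots, refined to sub-pixel positions by intensity
#' centroid over the PSF footprint. Candidates closer than
#' `exclusion_radius` pixels are merged (never double-counted). Traces are
#' extracted by fixed-aperture summation around each position.
#'
#' @param stack A 3-D array `nx x ny x n_frames` (one channel).
#' @param psf_sigma Expected PSF SD, pixels.
#' @param threshold_sd Detection threshold in robust-SD units of the summed
#'   image (default 5).
#' @param exclusion_radius Minimum spot separation, pixels (default
#'   `2 * psf_sigma`).
#' @param aperture Radius of the summation aperture, pixels (default
#'   `ceiling(2 * psf_sigma)`).
#' @return list with `positions` (matrix n x 2) and `traces` (matrix
#'   n_spots x n_frames of aperture-summed, background-subtracted
#'   intensities).
#' @export
detect_spots <- function(stack, psf_sigma, threshold_sd = 5,
                         exclusion_radius = 2 * psf_sigma,
                         aperture = ceiling(2 * psf_sigma)) {
  d <- dim(stack)
  if (length(d) != 3 || any(d == 0))
    return(list(positions = matrix(numeric(0), 0, 2),
                traces = matrix(numeric(0), 0, 0)))
  avg <- apply(stack, c(1, 2), mean)
  med <- stats::median(avg)
  s <- stats::mad(avg)
  if (s == 0) s <- stats::sd(avg)
  if (is.na(s) || s == 0)
    return(list(positions = matrix(numeric(0), 0, 2),
                traces = matrix(numeric(0), 0, 0)))
  thr <- med + threshold_sd * s
  cand <- which(avg > thr, arr.ind = TRUE)
  # keep only local maxima in a 3x3 neighbourhood
  is_max <- vapply(seq_len(nrow(cand)), function(i) {
    x <- cand[i, 1]; y <- cand[i, 2]
    xs <- max(1, x - 1):min(d[1], x + 1)
    ys <- max(1, y - 1):min(d[2], y + 1)
    avg[x, y] >= max(avg[xs, ys])
  }, TRUE)
  cand <- cand[is_max, , drop = FALSE]
  if (!nrow(cand))
    return(list(positions = matrix(numeric(0), 0, 2),
                traces = matrix(numeric(0), 0, 0)))
  # merge candidates within the exclusion radius (brightest wins)
  o <- order(avg[cand], decreasing = TRUE)
  cand <- cand[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      later <- (i + 1):nrow(cand)
      dd <- sqrt((cand[later, 1] - cand[i, 1])^2 +
                 (cand[later, 2] - cand[i, 2])^2)
      keep[later][dd < exclusion_radius] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  # centroid refinement over the PSF footprint
  r <- ceiling(2 * psf_sigma)
  pos <- t(vapply(seq_len(nrow(cand)), function(i) {
    xs <- max(1, cand[i, 1] - r):min(d[1], cand[i, 1] + r)
    ys <- max(1, cand[i, 2] - r):min(d[2], cand[i, 2] + r)
    w <- pmax(avg[xs, ys] - med, 0)
    if (sum(w) == 0) return(as.numeric(cand[i, ]))
    c(sum(outer(xs, rep(1, length(ys))) * w) / sum(w),
      sum(outer(rep(1, length(xs)), ys) * w) / sum(w))
  }, numeric(2)))
  # aperture-summed traces
  traces <- t(vapply(seq_len(nrow(pos)), function(i) {
    xs <- max(1, round(pos[i, 1]) - aperture):min(d[1], round(pos[i, 1]) + aperture)
    ys <- max(1, round(pos[i, 2]) - aperture):min(d[2], round(pos[i, 2]) + aperture)
    colSums(apply(stack[xs, ys, , drop = FALSE], 3, identity)) -
      med * length(xs) * length(ys)
  }, numeric(d[3])))
  list(positions = pos, traces = traces)
}

#' Write a movie set to multi-page TIFF files (one per channel)
#'
#' Requires the `tiff` package. Intensities are scaled to [0, 1] 16-bit.
#' @param movie A `movie_set` from [render_movie()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @export
write_movie_tiff <- function(movie, dir, prefix = "stack") {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF stacks")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(movie)) {
    arr <- movie[[nm]]
    arr <- arr / max(arr)
    pages <- lapply(seq_len(dim(arr)[3]), function(f) t(arr[, , f]))
    tiff::writeTIFF(pages, file.path(dir, paste0(prefix, "_", nm, ".tif")),
                    bits.per.sample = 16L)
  }
  invisible(dir)
}
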