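# Synthetic lung-phantom generator and split machinery. A phantom is a
# grayscale image with two lobe-shaped regions on a textured background plus
# a matched binary mask; it reproduces the structural assumptions of the
# segmentation pipeline (two disjoint single-component lung fields, smooth
# but noisy boundaries, rib-like stripes, pixel noise) without any clinical
# data. Lungs are rendered darker than the surrounding tissue, mimicking
# radiograph polarity; `polarity = "light"` inverts this.

#' Specify a lung phantom
#'
#' @param size Integer (H, W) image size (default 128 x 128).
#' @param lobe_area_range Per-lobe area fraction range (default
#'   c(0.08, 0.22)); with two lobes the total lung fraction stays inside
#'   0.15-0.45.
#' @param eccentricity_range Lobe height/width ratio range (lungs are taller
#'   than wide; default c(1.4, 2.2)).
#' @param boundary_amplitude Relative amplitude of the smooth radial boundary
#'   perturbation (default 0.08).
#' @param rib_contrast Peak amplitude, in gray levels, of the periodic
#'   rib-like stripes (default 12).
#' @param noise_sd Standard deviation of the additive Gaussian pixel noise in
#'   gray levels (default 8).
#' @param lung_level,tissue_level Mean gray level inside/outside the lungs
#'   (defaults 80 and 170).
#' @param polarity `"dark"` (default; lungs darker than tissue) or
#'   `"light"`.
#' @param seed Integer seed; the phantom is a deterministic function of the
#'   spec including the seed.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(size = c(128L, 128L), lobe_area_range = c(0.08, 0.22),
                         eccentricity_range = c(1.4, 2.2),
                         boundary_amplitude = 0.08, rib_contrast = 12,
                         noise_sd = 8, lung_level = 80, tissue_level = 170,
                         polarity = c("dark", "light"), seed = 1L) {
  polarity <- match.arg(polarity)
  size <- as.integer(rep(size, length.out = 2L))
  stopifnot(all(size >= 32L), lobe_area_range[1] > 0, lobe_area_range[2] < 0.25,
            boundary_amplitude >= 0, boundary_amplitude < 0.3)
  structure(list(size = size, lobe_area_range = lobe_area_range,
                 eccentricity_range = eccentricity_range,
                 boundary_amplitude = boundary_amplitude,
                 rib_contrast = rib_contrast, noise_sd = noise_sd,
                 lung_level = lung_level, tissue_level = tissue_level,
                 polarity = polarity, seed = as.integer(seed)),
            class = "phantom_spec")
}

# rasterize one star-shaped lobe: inside iff the normalized elliptical radius
# is below 1 + a smooth periodic perturbation of the polar angle
rasterize_lobe <- function(H, W, cx, cy, rx, ry, amp_coefs, phases) {
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), times = W), H, W)
  dx <- (X - cx) / rx
  dy <- (Y - cy) / ry
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  bound <- 1
  for (k in seq_along(amp_coefs)) {
    bound <- bound + amp_coefs[k] * cos((k + 1) * theta + phases[k])
  }
  (rho <= bound) + 0L
}

# smooth low-frequency background field: coarse Gaussian grid, bilinearly
# up-sampled to full resolution
smooth_field <- function(H, W, coarse = 8L, sd = 1) {
  g <- matrix(stats::rnorm(coarse * coarse, sd = sd), coarse, coarse)
  rows <- seq(1, coarse, length.out = H)
  cols <- seq(1, coarse, length.out = W)
  r0 <- pmin(floor(rows), coarse - 1L); fr <- rows - r0
  c0 <- pmin(floor(cols), coarse - 1L); fc <- cols - c0
  a <- g[r0, c0] * outer(1 - fr, 1 - fc) + g[r0 + 1L, c0] * outer(fr, 1 - fc) +
    g[r0, c0 + 1L] * outer(1 - fr, fc) + g[r0 + 1L, c0 + 1L] * outer(fr, fc)
  a
}

#' Generate a lung phantom image and mask
#'
#' Draws two non-overlapping, star-shaped lung lobes (perturbed ellipses, so
#' each lobe is one connected component by construction), renders them
#' against a smoothly textured background with periodic rib-like stripes,
#' and adds Gaussian pixel noise clipped to the 8-bit range. Reproducible:
#' the same spec (including its seed) yields a bit-identical pair.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (H x W matrix, 0-255) and `mask` (H x W binary
#'   matrix with exactly two 8-connected components).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$size[1]; W <- spec$size[2]
  withr::with_seed(spec$seed, {
    mask <- NULL
    for (attempt in 1:25) {
      m <- matrix(0L, H, W)
      ok <- TRUE
      for (side in c(-1, 1)) {
        a <- stats::runif(1, spec$lobe_area_range[1], spec$lobe_area_range[2])
        ecc <- stats::runif(1, spec$eccentricity_range[1], spec$eccentricity_range[2])
        rx <- sqrt(a * H * W / (pi * ecc))
        ry <- ecc * rx
        # keep each lobe inside its half with a margin for the perturbation
        rx <- min(rx, 0.20 * W)
        ry <- min(ry, 0.42 * H)
        cx <- (0.5 + side * 0.24) * W + stats::rnorm(1, sd = 0.015 * W)
        cy <- 0.5 * H + stats::rnorm(1, sd = 0.03 * H)
        nharm <- 4L
        amps <- stats::rnorm(nharm, sd = spec$boundary_amplitude / seq_len(nharm))
        amps <- pmin(pmax(amps, -0.25), 0.25)
        phases <- stats::runif(nharm, 0, 2 * pi)
        lobe <- rasterize_lobe(H, W, cx, cy, rx, ry, amps, phases)
        if (any(lobe & m)) { ok <- FALSE; break }
        m <- m + lobe
      }
      if (!ok) next
      frac <- mean(m)
      ncomp <- max(label_components(m, 8L))
      if (ncomp == 2L && frac >= 0.15 && frac <= 0.45) { mask <- m; break }
    }
    if (is.null(mask)) {
      stop("could not place two disjoint lobes within the geometry bounds")
    }
    base <- ifelse(mask == 1L, spec$lung_level, spec$tissue_level)
    if (spec$polarity == "light") {
      base <- ifelse(mask == 1L, spec$tissue_level, spec$lung_level)
    }
    tex <- smooth_field(H, W, coarse = 8L, sd = 1) * 10
    ribs_phase <- stats::runif(1, 0, 2 * pi)
    ribs_tilt <- stats::runif(1, -0.15, 0.15)
    Y <- matrix(rep(seq_len(H), times = W), H, W)
    X <- matrix(rep(seq_len(W), each = H), H, W)
    ribs <- spec$rib_contrast * sin(2 * pi * (Y + ribs_tilt * X) / (H / 7) + ribs_phase)
    noise <- matrix(stats::rnorm(H * W, sd = spec$noise_sd), H, W)
    img <- base + tex + ribs + noise
    img <- round(pmin(pmax(img, 0), 255))
    list(image = matrix(as.integer(img), H, W), mask = mask)
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` image/mask PNG pairs and a CSV manifest with columns `id`,
#' `image_path`, `mask_path` (paths relative to the manifest location).
#' Deterministic for a given `base_seed`: item i uses seed
#' `(base_seed + 7919 * i) mod (2^31 - 1)`.
#'
#' @param n Number of phantoms.
#' @param base_seed Integer seed for the whole dataset.
#' @param out_dir Output directory (created if missing).
#' @param size Integer (H, W) phantom size.
#' @param ... Further arguments passed to [phantom_spec()].
#' @return The manifest data frame, invisibly; the manifest is written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_dataset <- function(n, base_seed, out_dir, size = c(128L, 128L), ...) {
  stopifnot(n >= 1L)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- as.integer((as.double(base_seed) + 7919 * i) %% (2^31 - 1))
    ph <- generate_phantom(phantom_spec(size = size, seed = seed_i, ...))
    id <- sprintf("ph%04d", i)
    img_rel <- paste0(id, "_img.png")
    msk_rel <- paste0(id, "_mask.png")
    write_gray_image(ph$image, file.path(out_dir, img_rel))
    write_mask(ph$mask, file.path(out_dir, msk_rel))
    rows[[i]] <- data.frame(id = id, image_path = img_rel, mask_path = msk_rel,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset manifest
#'
#' @param path Path to a manifest CSV (columns `id`, `image_path`,
#'   `mask_path`; relative paths are resolved against the manifest
#'   directory).
#' @return Data frame with absolute `image_path`/`mask_path`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "image_path", "mask_path")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  m$image_path <- fix(m$image_path)
  m$mask_path <- fix(m$mask_path)
  m
}

#' Five-fold cross-validation split plans
#'
#' Shuffles the ids once, partitions them into five disjoint, exhaustive 20%
#' test folds, and for each fold splits the remaining 80% into training (70%
#' of the total) and validation (10% of the total). Sizes use
#' largest-remainder rounding with the test size fixed first.
#'
#' @param ids Character or integer vector of at least 10 ids.
#' @param seed Integer seed for the shuffle.
#' @return List of five plans, each with `fold`, `train`, `validation`,
#'   `test`.
#' @export
make_splits <- function(ids, seed = 1L) {
  n <- length(ids)
  if (n < 10L) stop("need at least 10 ids, got ", n)
  if (anyDuplicated(ids)) stop("ids must be unique")
  shuffled <- withr::with_seed(as.integer(seed), sample(ids))
  # five test folds of near-equal size (largest remainder)
  sizes <- rep(n %/% 5L, 5L)
  extra <- n %% 5L
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bounds <- cumsum(c(0L, sizes))
  n_val <- max(1L, round(0.1 * n))
  lapply(1:5, function(f) {
    test <- shuffled[(bounds[f] + 1L):bounds[f + 1L]]
    rest <- setdiff(shuffled, test)
    val <- rest[seq_len(n_val)]
    train <- rest[(n_val + 1L):length(rest)]
    list(fold = f, train = train, validation = val, test = test)
  })
}
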