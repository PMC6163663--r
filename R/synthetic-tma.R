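# Synthetic H-DAB TMA core generator.
#
# Images are rendered from a three-class model (background glass,
# hematoxylin-only tissue, DAB-positive tissue). Each class has a mean
# grayscale intensity; colour comes from fixed per-class hue templates
# whose channel weights average to 1, so the unweighted RGB mean of a
# noise-free pixel reproduces the class intensity exactly. DAB-positive
# pixels are spatially clustered by taking the top-k pixels of a smooth
# random field inside the tissue disc, which fixes the realised area
# fraction to the target up to one pixel.

# per-class hue templates; rows R,G,B weights averaging 1
.hue_templates <- list(
  background  = c(1.01, 1.00, 0.99),  # near-neutral warm white
  hematoxylin = c(0.83, 0.88, 1.29),  # blue-purple
  dab         = c(1.25, 1.00, 0.75)   # brown
)

logit <- function(p) log(p / (1 - p))

# run code under a temporary RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# smooth Gaussian noise field via bilinear upsampling of a coarse grid;
# `scale` is the approximate blob length scale in pixels
smooth_noise_field <- function(side, scale = 16) {
  m <- max(2L, as.integer(ceiling(side / scale)) + 1L)
  g <- matrix(stats::rnorm(m * m), m, m)
  pos <- seq(1, m, length.out = side)
  i0 <- pmin(floor(pos), m - 1L)
  fr <- pos - i0
  wy <- matrix(fr, side, side)
  wx <- matrix(fr, side, side, byrow = TRUE)
  g00 <- g[i0, i0]
  g01 <- g[i0, i0 + 1L]
  g10 <- g[i0 + 1L, i0]
  g11 <- g[i0 + 1L, i0 + 1L]
  (1 - wy) * (1 - wx) * g00 + (1 - wy) * wx * g01 +
    wy * (1 - wx) * g10 + wy * wx * g11
}

#' Render one synthetic TMA core image
#'
#' Draws a disc of tissue texture on a bright background. A spatially
#' clustered subset of tissue pixels with target area fraction
#' `meta$true_dab_fraction` is rendered in DAB-brown, the rest in
#' hematoxylin-blue, with per-pixel Gaussian intensity noise at the
#' class standard deviations from `config`, clipped to \[0, 255\].
#'
#' @param meta A one-row data frame (or list) of core metadata; must
#'   carry `true_dab_fraction` and `core_id`.
#' @param config A [cohort_config()].
#' @param seed Integer seed for this core; required — the generator
#'   refuses to run on an ambient RNG state.
#' @return A `core_image`: list with `pixels` (side x side x 3 integer
#'   array, 0-255) and `meta`; attributes `n_tissue` and `n_dab` record
#'   the generator's own class masks before rendering.
#' @export
generate_core_image <- function(meta, config, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("generate_core_image() requires an explicit seed ",
         "(reproducibility contract)", call. = FALSE)
  }
  frac <- meta$true_dab_fraction
  if (is.null(frac) || is.na(frac)) {
    stop("metadata must carry true_dab_fraction", call. = FALSE)
  }
  validate_cohort_config(config)
  side <- config$image_side
  r <- config$core_diameter / 2

  ctr <- (side + 1) / 2
  ax <- seq_len(side) - ctr
  dist2 <- outer(ax^2, ax^2, `+`)
  tissue_mask <- dist2 <= r^2
  n_tissue <- sum(tissue_mask)

  with_seed(seed, {
    field <- smooth_noise_field(side, scale = max(4, side / 16))
    k <- round(frac * n_tissue)
    dab_mask <- matrix(FALSE, side, side)
    if (k > 0) {
      vals <- field[tissue_mask]
      idx <- which(tissue_mask)
      dab_mask[idx[order(vals, decreasing = TRUE)[seq_len(k)]]] <- TRUE
    }

    intensity <- matrix(
      config$background_mean + stats::rnorm(side * side, 0, config$background_sd),
      side, side
    )
    hema_mask <- tissue_mask & !dab_mask
    intensity[hema_mask] <- config$tissue_mean +
      stats::rnorm(sum(hema_mask), 0, config$tissue_sd)
    intensity[dab_mask] <- config$dab_mean +
      stats::rnorm(k, 0, config$dab_sd)

    pixels <- array(0L, dim = c(side, side, 3L))
    for (ch in 1:3) {
      hue <- ifelse(dab_mask, .hue_templates$dab[ch],
                    ifelse(tissue_mask, .hue_templates$hematoxylin[ch],
                           .hue_templates$background[ch]))
      pixels[, , ch] <- as.integer(pmax(0, pmin(255, round(intensity * hue))))
    }

    structure(
      list(pixels = pixels, meta = as.list(meta)),
      class = "core_image",
      n_tissue = n_tissue, n_dab = k
    )
  })
}

#' Simulate a full TMA cohort
#'
#' Builds the matched-pair cohort metadata (one HR and one LR patient per
#' pair, sharing a simulated Gleason sum), draws per-core true DAB
#' fractions from the hierarchical logit-normal model, and renders every
#' core image. Fully deterministic given `config` (including its seed).
#'
#' @param config A [cohort_config()].
#' @return A list of class `tma_cohort`: `images` (named list of
#'   `core_image` keyed by core_id), `metadata` (tibble: core_id,
#'   patient_id, pair_id, group, tissue_type, gleason_sum) and `truth`
#'   (tibble: core_id, true_dab_fraction — the generator ground truth,
#'   kept out of `metadata` so inference stages never see it).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_pairs = 2, cores_per_patient = 2,
#'                                         image_side = 48, core_diameter = 40))
#' nrow(cohort$metadata)  # 2 pairs x 2 groups x 2 cores = 8
generate_cohort <- function(config) {
  validate_cohort_config(config)
  np <- config$n_pairs
  cpp <- config$cores_per_patient

  meta <- with_seed(config$seed, {
    gleason <- sample(6:9, np, replace = TRUE,
                      prob = c(0.10, 0.78, 0.08, 0.04))
    rows <- list()
    mu <- c(HR = logit_or_inf(config$dab_fraction_hr),
            LR = logit_or_inf(config$dab_fraction_lr))
    for (i in seq_len(np)) {
      for (grp in c("HR", "LR")) {
        patient_id <- sprintf("PT%03d%s", i, grp)
        patient_logit <- mu[[grp]] + stats::rnorm(1, 0, config$patient_sd)
        core_logit <- patient_logit + stats::rnorm(cpp, 0, config$core_sd)
        frac <- stats::plogis(core_logit)
        # degenerate group means 0/1 stay exactly at the boundary
        if (!is.finite(mu[[grp]])) frac <- rep(stats::plogis(mu[[grp]]), cpp)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          core_id = sprintf("%s_C%d", patient_id, seq_len(cpp)),
          patient_id = patient_id,
          pair_id = sprintf("PAIR%03d", i),
          group = grp,
          tissue_type = "tumour",
          gleason_sum = gleason[i],
          true_dab_fraction = frac
        )
      }
    }
    do.call(rbind, rows)
  })

  core_seeds <- (config$seed %% 100000L) * 10000L + seq_len(nrow(meta))
  images <- lapply(seq_len(nrow(meta)), function(i) {
    generate_core_image(meta[i, ], config, seed = core_seeds[i])
  })
  names(images) <- meta$core_id

  structure(list(
    images = images,
    metadata = meta[, setdiff(names(meta), "true_dab_fraction")],
    truth = meta[, c("core_id", "true_dab_fraction")]
  ), class = "tma_cohort")
}

# logit that tolerates the degenerate boundaries 0 and 1
logit_or_inf <- function(p) {
  if (p <= 0) return(-Inf)
  if (p >= 1) return(Inf)
  logit(p)
}

#' Write a cohort to disk
#'
#' Writes one lossless image file per core plus `cores.csv` (metadata,
#' with an `image_path` column) and `truth.csv` (generator ground truth,
#' kept in its own file).
#'
#' @param cohort A `tma_cohort` from [generate_cohort()], or a list with
#'   `images` and `metadata` (and optionally `truth`).
#' @param out_dir Output directory; created if absent. An existing
#'   non-empty directory is refused unless `overwrite = TRUE`.
#' @param format `"png"` (default) or `"tiff"`.
#' @param overwrite Allow writing into a non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(cohort, out_dir, format = c("png", "tiff"),
                          overwrite = FALSE) {
  format <- match.arg(format)
  images <- cohort$images
  meta <- cohort$metadata
  if (length(images) != nrow(meta)) {
    stop(sprintf("metadata has %d rows but %d images were supplied",
                 nrow(meta), length(images)), call. = FALSE)
  }
  if (dir.exists(out_dir) && length(dir(out_dir, all.files = FALSE)) > 0 &&
      !overwrite) {
    stop(sprintf("output directory '%s' is not empty; set overwrite = TRUE",
                 out_dir), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ext <- if (format == "png") "png" else "tif"
  paths <- file.path(out_dir, paste0(meta$core_id, ".", ext))
  for (i in seq_along(images)) {
    write_core_image(images[[i]], paths[i], format)
  }
  meta_out <- meta
  meta_out$image_path <- basename(paths)
  utils::write.csv(meta_out, file.path(out_dir, "cores.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$truth)) {
    utils::write.csv(cohort$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}

write_core_image <- function(image, path, format = c("png", "tiff")) {
  format <- match.arg(format)
  arr <- image$pixels / 255
  if (format == "png") {
    png::writePNG(arr, path)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required for TIFF output", call. = FALSE)
    }
    tiff::writeTIFF(arr, path)
  }
  invisible(path)
}

#' Read one core image from disk
#'
#' @param path A PNG or TIFF file written by [write_dataset()] (or any
#'   8-bit RGB image in those formats).
#' @param meta Optional metadata to attach.
#' @return A `core_image` with integer pixels on 0-255.
#' @export
read_core_image <- function(path, meta = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("the 'tiff' package is required to read TIFF", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop(sprintf("unsupported image format '%s' for %s", ext, path),
         call. = FALSE)
  )
  if (length(dim(arr)) == 3 && dim(arr)[3] >= 3) arr <- arr[, , 1:3]
  else stop(sprintf("expected an RGB image, got dims %s for %s",
                    paste(dim(arr), collapse = "x"), path), call. = FALSE)
  pixels <- array(as.integer(round(arr * 255)), dim = dim(arr))
  structure(list(pixels = pixels, meta = meta), class = "core_image")
}

#' Read a cohort directory written by [write_dataset()]
#'
#' @param dir Directory containing `cores.csv` and the image files it
#'   references.
#' @return A `tma_cohort` (the `truth` element is included only if
#'   `truth.csv` is present).
#' @export
read_cohort <- function(dir) {
  csv <- file.path(dir, "cores.csv")
  if (!file.exists(csv)) {
    stop(sprintf("no cores.csv in '%s'", dir), call. = FALSE)
  }
  meta <- tibble::as_tibble(utils::read.csv(csv, stringsAsFactors = FALSE))
  paths <- file.path(dir, meta$image_path)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing image files for cores: ",
         paste(meta$core_id[missing], collapse = ", "), call. = FALSE)
  }
  images <- lapply(seq_len(nrow(meta)), function(i) {
    read_core_image(paths[i], meta = as.list(meta[i, ]))
  })
  names(images) <- meta$core_id
  truth <- NULL
  tf <- file.path(dir, "truth.csv")
  if (file.exists(tf)) {
    truth <- tibble::as_tibble(utils::read.csv(tf, stringsAsFactors = FALSE))
  }
  structure(list(images = images,
                 metadata = meta[, setdiff(names(meta), "image_path")],
                 truth = truth),
            class = "tma_cohort")
}
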