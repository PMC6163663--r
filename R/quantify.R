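# Two-threshold DAB quantification.
#
# Chromogenic slides have a bright background, so "tissue" means pixels
# strictly darker than the tissue cutoff and "signal" pixels strictly
# darker than the (lower) signal cutoff: AmtT = #{I < t_tissue},
# AmtS = #{I < t_signal}, expression statistic = AmtS / AmtT. Because
# t_signal <= t_tissue the signal mask nests inside the tissue mask by
# construction.

round_half_up <- function(x) floor(x + 0.5)

#' A pair of pixel-value thresholds
#'
#' @param t_tissue Intensity cutoff below which a pixel counts as tissue.
#' @param t_signal Intensity cutoff below which a pixel counts as DAB
#'   signal; must satisfy `0 <= t_signal <= t_tissue <= 255`.
#' @return A `threshold_pair`.
#' @export
threshold_pair <- function(t_tissue, t_signal) {
  if (!(t_signal >= 0 && t_signal <= t_tissue && t_tissue <= 255)) {
    stop("invalid thresholds: need 0 <= t_signal <= t_tissue <= 255 ",
         sprintf("(got t_tissue=%s, t_signal=%s)", t_tissue, t_signal),
         call. = FALSE)
  }
  structure(list(t_tissue = t_tissue, t_signal = t_signal),
            class = "threshold_pair")
}

#' Convert an RGB core image to an 8-bit intensity map
#'
#' @param image A `core_image` or a height x width x 3 RGB array on the
#'   0-255 scale.
#' @param mode `"mean_rgb"` (default): the unweighted channel mean,
#'   rounded half-up — the convention of ImageJ's plain 8-bit
#'   conversion of RGB stacks; `"luma"`: ITU-R BT.601 weights
#'   0.299/0.587/0.114, rounded half-up.
#' @return An integer matrix of per-pixel intensities in \[0, 255\].
#' @export
to_intensity <- function(image, mode = c("mean_rgb", "luma")) {
  mode <- match.arg(mode)
  px <- if (inherits(image, "core_image")) image$pixels else image
  if (length(dim(px)) != 3 || dim(px)[3] != 3) {
    stop("expected an RGB image: a height x width x 3 array ",
         "(or a core_image)", call. = FALSE)
  }
  w <- if (mode == "mean_rgb") c(1, 1, 1) / 3 else c(0.299, 0.587, 0.114)
  out <- round_half_up(px[, , 1, drop = TRUE] * w[1] +
                         px[, , 2, drop = TRUE] * w[2] +
                         px[, , 3, drop = TRUE] * w[3])
  dim(out) <- dim(px)[1:2]
  storage.mode(out) <- "integer"
  out
}

#' Measure one core at fixed thresholds
#'
#' Counts tissue pixels (intensity strictly below `t_tissue`) and signal
#' pixels (strictly below `t_signal`) and forms the expression ratio
#' AmtS/AmtT. A core with no tissue pixels is flagged invalid rather than
#' given a silent zero ratio.
#'
#' @param intensity An intensity matrix from [to_intensity()].
#' @param thresholds A [threshold_pair()].
#' @param core_id Optional identifier carried into the result.
#' @return A `core_quantification`: list with `core_id`, `amt_t`,
#'   `amt_s`, `ratio` (NA when invalid) and `valid`.
#' @export
measure_core <- function(intensity, thresholds, core_id = NA_character_) {
  stopifnot(inherits(thresholds, "threshold_pair"))
  amt_t <- sum(intensity < thresholds$t_tissue)
  amt_s <- sum(intensity < thresholds$t_signal)
  valid <- amt_t > 0L
  structure(list(
    core_id = core_id,
    amt_t = amt_t,
    amt_s = amt_s,
    ratio = if (valid) amt_s / amt_t else NA_real_,
    valid = valid
  ), class = "core_quantification")
}

# cumulative intensity histogram: cc[v + 1] = #pixels <= v, v = 0..255,
# so #pixels < t (integer t in 1..255) = cc[t]; t <= 0 gives 0
intensity_cumhist <- function(intensity) {
  cumsum(tabulate(as.integer(intensity) + 1L, nbins = 256L))
}

amt_below <- function(cumhist, t) {
  t <- as.integer(t)
  if (t <= 0L) 0L else cumhist[min(t, 256L)]
}

#' Train the threshold pair on a labelled subset
#'
#' Exhaustive grid search over `(t_tissue, t_signal)` with
#' `t_signal <= t_tissue` at the given step. Each candidate pair yields
#' every training core's AmtS/AmtT ratio, which is regressed by ordinary
#' least squares on the binary group indicator; the pair maximising the
#' regression slope — the between-group difference of mean ratio, in
#' ratio units — is returned, and its coefficient of determination
#' R-squared on the training cores is reported as the fit score. Exact
#' score ties are broken toward the lowest `t_signal`, then the lowest
#' `t_tissue`.
#'
#' Selecting on the slope rather than on R-squared is deliberate:
#' R-squared is scale-free, so candidate pairs whose two cutoffs fall
#' inside a single intensity population produce near-constant ratios
#' whose pure sampling noise can out-score the genuinely informative
#' pairs when the grid is searched exhaustively against a small training
#' set. The slope is measured in ratio units, which makes such
#' degenerate candidates score near zero. For the same reason candidate
#' pairs are subject to a tissue-validity floor: a pair is excluded when
#' any training core's tissue count falls below `min_tissue_fraction` of
#' its pixels (cores with no tissue pixels at all are always excluded).
#'
#' @param images Named list of `core_image` (or intensity matrices) for
#'   the training cores.
#' @param groups Character vector of group labels ("HR"/"LR"), parallel
#'   to `images`; both groups must be present with at least 2 cores each.
#' @param grid_step Grid resolution in intensity units (default 5).
#' @param mode Grayscale conversion mode, see [to_intensity()].
#' @param min_tissue_fraction Minimum share of a training core's pixels
#'   that a candidate `t_tissue` must classify as tissue (default 0.05;
#'   0 keeps every pair with non-zero tissue counts).
#' @return A `threshold_training` result: `best` ([threshold_pair()]),
#'   `fit_score` (R-squared on the training cores), `slope` (the
#'   selected pair's between-group mean ratio difference), `grid_step`,
#'   `n_train_hr`, `n_train_lr`, `mode`.
#' @export
train_thresholds <- function(images, groups, grid_step = 5,
                             mode = c("mean_rgb", "luma"),
                             min_tissue_fraction = 0.05) {
  mode <- match.arg(mode)
  groups <- as.character(groups)
  stopifnot(length(images) == length(groups))
  n_hr <- sum(groups == "HR")
  n_lr <- sum(groups == "LR")
  if (n_hr < 2 || n_lr < 2) {
    stop("threshold training requires both groups ",
         sprintf("(>= 2 cores each; got %d HR, %d LR)", n_hr, n_lr),
         call. = FALSE)
  }

  cumhists <- lapply(images, function(im) {
    intensity_cumhist(to_intensity(im, mode))
  })
  n_px <- vapply(cumhists, function(cc) cc[256L], integer(1))
  floor_px <- pmax(1L, as.integer(ceiling(min_tissue_fraction * n_px)))
  grid <- unique(c(seq(0L, 255L, by = as.integer(grid_step)), 255L))
  # amt matrix: cores x grid values
  amt <- vapply(grid, function(t) {
    vapply(cumhists, amt_below, integer(1), t = t)
  }, integer(length(cumhists)))

  hr <- groups == "HR"
  best_slope <- -Inf
  best <- NULL
  tol <- 1e-9
  for (is in seq_along(grid)) {        # t_signal ascending (primary tie-break)
    for (it in is:length(grid)) {      # t_tissue ascending (secondary)
      at <- amt[, it]
      if (any(at < floor_px)) next
      ratio <- amt[, is] / at
      slope <- mean(ratio[hr]) - mean(ratio[!hr])
      if (slope > best_slope + tol) {
        best_slope <- slope
        best <- c(grid[it], grid[is])
      }
    }
  }
  if (is.null(best)) {
    stop("threshold grid exhausted: every candidate pair left at least ",
         "one training core below the tissue-validity floor",
         call. = FALSE)
  }
  ratio_best <- amt[, match(best[2], grid)] / amt[, match(best[1], grid)]
  fit_score <- if (stats::sd(ratio_best) == 0) 0 else
    stats::cor(ratio_best, as.numeric(hr))^2
  structure(list(
    best = threshold_pair(best[1], best[2]),
    fit_score = fit_score,
    slope = best_slope,
    grid_step = grid_step,
    n_train_hr = n_hr,
    n_train_lr = n_lr,
    mode = mode
  ), class = "threshold_training")
}

#' Draw a seeded random training subset
#'
#' @param metadata Cohort metadata with `core_id` and `group`.
#' @param n_hr,n_lr Cores to draw per group (default 10 + 10).
#' @param seed Integer seed.
#' @return Character vector of selected core_ids.
#' @export
sample_training_set <- function(metadata, n_hr = 10, n_lr = 10, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  hr <- metadata$core_id[metadata$group == "HR"]
  lr <- metadata$core_id[metadata$group == "LR"]
  if (length(hr) < n_hr || length(lr) < n_lr) {
    stop(sprintf("cohort too small for a %d HR + %d LR training set", n_hr,
                 n_lr), call. = FALSE)
  }
  with_seed(seed, c(sample(hr, n_hr), sample(lr, n_lr)))
}

#' Quantify every core of a cohort at fixed thresholds
#'
#' Applies one trained [threshold_pair()] to all cores of a marker, as
#' the study design requires (one pair per antibody), and joins the
#' measurements to the metadata. Invalid cores (no tissue pixels) are
#' flagged and retained; downstream statistics exclude them.
#'
#' @param images Named list of `core_image` keyed by core_id, or `NULL`
#'   to read each image from `image_dir`/`metadata$image_path`.
#' @param metadata Cohort metadata (core_id, patient_id, pair_id, group,
#'   and `image_path` when reading from disk).
#' @param thresholds A [threshold_pair()].
#' @param mode Grayscale conversion mode.
#' @param image_dir Directory for on-disk images when `images` is NULL.
#' @return A tibble with columns core_id, patient_id, pair_id, group,
#'   amt_t, amt_s, ratio, valid.
#' @export
quantify_cohort <- function(images, metadata, thresholds,
                            mode = c("mean_rgb", "luma"),
                            image_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(thresholds, "threshold_pair"))
  ids <- metadata$core_id
  if (anyDuplicated(ids)) {
    stop("duplicate core_id in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(images)) {
    if (is.null(image_dir) || is.null(metadata$image_path)) {
      stop("either in-memory images or image_dir + metadata$image_path ",
           "must be supplied", call. = FALSE)
    }
    paths <- file.path(image_dir, metadata$image_path)
    missing <- !file.exists(paths)
    if (any(missing)) {
      stop("missing image files for cores: ",
           paste(ids[missing], collapse = ", "), call. = FALSE)
    }
    images <- lapply(paths, read_core_image)
    names(images) <- ids
  } else {
    absent <- setdiff(ids, names(images))
    if (length(absent)) {
      stop("no image supplied for cores: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  rows <- lapply(ids, function(id) {
    q <- measure_core(to_intensity(images[[id]], mode), thresholds, id)
    tibble::tibble(core_id = id, amt_t = q$amt_t, amt_s = q$amt_s,
                   ratio = q$ratio, valid = q$valid)
  })
  q <- do.call(rbind, rows)
  keep <- intersect(c("core_id", "patient_id", "pair_id", "group"),
                    names(metadata))
  out <- merge(as.data.frame(metadata[, keep]), as.data.frame(q),
               by = "core_id", sort = FALSE)
  tibble::as_tibble(out[match(ids, out$core_id), ])
}

#' Persist / restore a trained threshold pair as JSON
#'
#' @param training A `threshold_training` (or a bare [threshold_pair()]).
#' @param path Output JSON file.
#' @return `path` invisibly; `read_thresholds()` returns a list with a
#'   `best` threshold_pair plus the training annotations present.
#' @export
write_thresholds <- function(training, path) {
  doc <- if (inherits(training, "threshold_pair")) {
    list(t_tissue = training$t_tissue, t_signal = training$t_signal)
  } else {
    list(t_tissue = training$best$t_tissue,
         t_signal = training$best$t_signal,
         mode = training$mode, grid_step = training$grid_step,
         fit_score = training$fit_score, slope = training$slope,
         n_train_hr = training$n_train_hr, n_train_lr = training$n_train_lr)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$best <- threshold_pair(doc$t_tissue, doc$t_signal)
  doc
}
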