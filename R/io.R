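#' Write a volume set as a 4D NIfTI file
#'
#' One 4D NIfTI per subject/condition: volume `t` holds trial `t`'s response
#' map on the full grid (0 outside the mask). A mask NIfTI on the same grid
#' can be written alongside with [write_mask()].
#'
#' @param vset a `volume_set`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm physical voxel size recorded in the header.
#' @return `path`, invisibly.
#' @export
write_volume_set <- function(vset, path, voxel_size_mm = c(2, 2, 2)) {
  stopifnot(inherits(vset, "volume_set"))
  dims <- dim(vset$mask)
  arr <- array(0, dim = c(dims, nrow(vset$data)))
  flat <- which(vset$mask)
  nv <- prod(dims)
  for (t in seq_len(nrow(vset$data))) {
    arr[flat + (t - 1L) * nv] <- vset$data[t, ]
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(voxel_size_mm, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_set
#' @param mask logical 3D array.
#' @export
write_mask <- function(mask, path, voxel_size_mm = c(2, 2, 2)) {
  img <- RNifti::asNifti(array(as.numeric(mask > 0), dim = dim(mask)))
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI into a volume set
#'
#' Reads trial volumes and a mask sharing the same grid; the two images'
#' affines must agree within `tol`, otherwise a data error reporting both
#' affines is raised (inputs are assumed already registered to one space).
#'
#' @param path 4D NIfTI of trial response volumes.
#' @param mask_path binary mask NIfTI on the same grid.
#' @param subject subject identifier to record.
#' @param trials optional trial table aligned with the 4th dimension.
#' @param tol maximum absolute affine discrepancy tolerated.
#' @return a `volume_set`.
#' @export
read_volumes <- function(path, mask_path, subject = NA, trials = NULL,
                         tol = 1e-4) {
  if (!file.exists(path)) abort_data("no such file: %s", path)
  if (!file.exists(mask_path)) abort_data("no such file: %s", mask_path)
  img <- RNifti::readNifti(path)
  mimg <- RNifti::readNifti(mask_path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 4L) abort_data("%s is not a 3D/4D image", path)
  mask <- as.array(mimg) > 0
  if (!all(dim(arr)[1:3] == dim(mask))) {
    abort_data("grid mismatch: volumes %s vs mask %s",
               paste(dim(arr)[1:3], collapse = "x"),
               paste(dim(mask), collapse = "x"))
  }
  xa <- unclass(RNifti::xform(img))[1:3, ]
  xm <- unclass(RNifti::xform(mimg))[1:3, ]
  if (max(abs(xa - xm)) > tol) {
    abort_data("affine mismatch between %s and %s:\n%s\nvs\n%s", path,
               mask_path, paste(capture_matrix(xa), collapse = "\n"),
               paste(capture_matrix(xm), collapse = "\n"))
  }
  flat <- which(mask)
  nv <- prod(dim(mask))
  n_tr <- dim(arr)[4]
  data <- matrix(0, n_tr, length(flat))
  for (t in seq_len(n_tr)) {
    data[t, ] <- arr[flat + (t - 1L) * nv]
  }
  volume_set(data, mask, subject = subject, trials = trials)
}

capture_matrix <- function(m) apply(round(m, 6), 1, paste, collapse = " ")

#' Write / read a trial event table (tab-separated, BIDS-events-like)
#'
#' Plain TSV with a header row and the columns of a trial table. Reading
#' validates the header, the awareness and category vocabularies, and reports
#' the first unparseable row by line number.
#'
#' @param trials a trial table.
#' @param path file path.
#' @return `read_events` returns a validated `trial_table`; `write_events`
#'   the path, invisibly.
#' @export
write_events <- function(trials, path) {
  validate_trial_table(trials)
  write.table(trials, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort_data("no such file: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_trial_table(df)
  for (col in c("subject", "session", "block", "trial", "item_id")) {
    val <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(val) & !is.na(df[[col]]))
    if (length(bad)) {
      abort_data("unparseable '%s' value at line %d of %s", col, bad[1] + 1L, path)
    }
    df[[col]] <- val
  }
  df$correct <- as.logical(df$correct)
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Write / read an item feature matrix (tab-separated)
#'
#' Numeric table with an `item_id` index column and one column per feature
#' dimension.
#'
#' @param features numeric matrix with item-id row names.
#' @param path file path.
#' @return `read_features` returns the matrix; `write_features` the path,
#'   invisibly.
#' @export
write_features <- function(features, path) {
  ids <- rownames(features) %||% as.character(seq_len(nrow(features)))
  df <- data.frame(item_id = ids, features, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) abort_data("no such file: %s", path)
  df <- read.delim(path, check.names = FALSE)
  if (!"item_id" %in% names(df)) abort_data("%s lacks an item_id column", path)
  m <- as.matrix(df[, setdiff(names(df), "item_id"), drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) abort_data("non-numeric feature values in %s", path)
  rownames(m) <- as.character(df$item_id)
  m
}

#' Write a statistic map (plus validity sidecar) as NIfTI
#'
#' Unevaluated centers are stored as `fill` in the main image; a companion
#' `<path minus extension>_validity.nii.gz` records which voxels hold real
#' statistic values.
#'
#' @param map a `stat_map`.
#' @param path output path (`.nii.gz`).
#' @param fill value stored at unevaluated/out-of-mask voxels.
#' @param voxel_size_mm header voxel size.
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(map, path, fill = 0, voxel_size_mm = c(2, 2, 2)) {
  stopifnot(inherits(map, "stat_map"))
  vol <- map$values
  vol[!map$validity] <- fill
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  vimg <- RNifti::asNifti(array(as.numeric(map$validity), dim = dim(vol)))
  RNifti::pixdim(vimg) <- voxel_size_mm
  RNifti::writeNifti(vimg, validity_path(path))
  invisible(path)
}

validity_path <- function(path) {
  sub("(\\.nii(\\.gz)?)$", "_validity\\1", path)
}

#' @rdname write_stat_map
#' @param statistic_name label for the reconstructed map.
#' @export
read_stat_map <- function(path, statistic_name = "statistic") {
  if (!file.exists(path)) abort_data("no such file: %s", path)
  vol <- as.array(RNifti::readNifti(path))
  vp <- validity_path(path)
  validity <- if (file.exists(vp)) as.array(RNifti::readNifti(vp)) > 0 else
    array(TRUE, dim = dim(vol))
  vol[!validity] <- NA_real_
  stat_map(vol, validity, statistic_name, validity = validity)
}

#' Write / read a stack of per-pair maps with a manifest
#'
#' Each map goes to `pair_<train>_<test>.nii.gz` inside `dir`;
#' `manifest.tsv` lists pair-to-filename assignments together with the
#' statistic name and null value, sufficient to reload the stack.
#'
#' @param stack a `stat_map_stack`.
#' @param dir output directory (created if needed).
#' @param voxel_size_mm header voxel size.
#' @return `read_stat_map_stack` returns the stack; `write_stat_map_stack`
#'   the directory, invisibly.
#' @export
write_stat_map_stack <- function(stack, dir, voxel_size_mm = c(2, 2, 2)) {
  stopifnot(inherits(stack, "stat_map_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("pair_%s_%s.nii.gz", stack$pairs$train, stack$pairs$test)
  for (k in seq_along(stack$maps)) {
    write_stat_map(stack$maps[[k]], file.path(dir, files[k]),
                   voxel_size_mm = voxel_size_mm)
  }
  manifest <- data.frame(train = stack$pairs$train, test = stack$pairs$test,
                         file = files,
                         statistic = stack$statistic_name,
                         null_value = stack$null_value)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_stat_map_stack
#' @export
read_stat_map_stack <- function(dir) {
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) abort_data("no manifest.tsv in %s", dir)
  manifest <- read.delim(mf, stringsAsFactors = FALSE)
  maps <- lapply(seq_len(nrow(manifest)), function(k) {
    read_stat_map(file.path(dir, manifest$file[k]),
                  statistic_name = manifest$statistic[k])
  })
  stat_map_stack(maps, manifest[, c("train", "test")],
                 statistic_name = manifest$statistic[1],
                 null_value = manifest$null_value[1])
}

## JSON run manifest: config echo + seed + package version + input digests
write_run_manifest <- function(path, config, seed, inputs = character()) {
  digests <- vapply(inputs, function(f) {
    if (file.exists(f)) as.character(tools::md5sum(f)) else NA_character_
  }, character(1))
  manifest <- list(
    package = "crosslight",
    version = as.character(utils::packageVersion("crosslight")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_digests = as.list(digests)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
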