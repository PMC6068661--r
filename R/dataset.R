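# Labeled tile dataset construction: the augmentation recipe (three exact
# 90-degree rotations, then slight perspective deformations), the mapping of
# the three source classes (animal / shadow / background) onto the
# classifier's two output classes, and a seeded stratified train/test split.

TILE_LABELS <- c("background", "target")
TILE_PROVENANCE <- c("animal", "shadow", "background")

#' Rotation augmentation
#'
#' Expands a list of square images to four times its length: each original
#' followed by its 90, 180 and 270 degree rotations, in stable order. The
#' rotations are pure pixel permutations, so rotating four times reproduces
#' the original exactly.
#'
#' @param images Non-empty list of square `H x H x 3` arrays.
#' @return A list of `4 * length(images)` arrays.
#' @export
augment_rotations <- function(images) {
  if (!is.list(images) || length(images) == 0L)
    stop("`images` must be a non-empty list", call. = FALSE)
  out <- vector("list", 4L * length(images))
  j <- 0L
  for (img in images) {
    img <- as_image_frame(img)
    if (dim(img)[1L] != dim(img)[2L])
      stop("rotation augmentation requires square images", call. = FALSE)
    out[[j + 1L]] <- img
    out[[j + 2L]] <- rotate90(img, 1L)
    out[[j + 3L]] <- rotate90(img, 2L)
    out[[j + 4L]] <- rotate90(img, 3L)
    j <- j + 4L
  }
  out
}

#' Perspective augmentation
#'
#' Expands a list of images to `(1 + n_deform)` times its length: each
#' original followed by `n_deform` independent slight perspective
#' deformations. A deformation jitters the four source corners by up to
#' `max_shift` of the side length and resamples under the resulting
#' homography back to the input size.
#'
#' @param images Non-empty list of `H x W x 3` arrays.
#' @param n_deform Number of deformed variants per image (non-negative).
#' @param seed Integer seed; fixed `(images, n_deform, seed)` give identical
#'   outputs.
#' @param max_shift Maximum corner displacement as a fraction of the side.
#' @return A list of `(1 + n_deform) * length(images)` arrays. With
#'   `n_deform = 0` the input list is returned unchanged.
#' @export
augment_perspective <- function(images, n_deform = 2L, seed = 1L,
                                max_shift = 0.1) {
  if (!is.list(images) || length(images) == 0L)
    stop("`images` must be a non-empty list", call. = FALSE)
  if (!is_count(n_deform))
    stop("`n_deform` must be a non-negative integer", call. = FALSE)
  if (n_deform == 0L) return(images)
  with_seed(seed, {
    out <- vector("list", (1L + n_deform) * length(images))
    j <- 0L
    for (img in images) {
      img <- as_image_frame(img)
      out[[j + 1L]] <- img
      for (k in seq_len(n_deform))
        out[[j + 1L + k]] <- perspective_jitter(img, max_shift)
      j <- j + 1L + n_deform
    }
    out
  })
}

#' Construct a tile dataset
#'
#' @param x Either an `N x S x S x 3` array or a list of `S x S x 3` arrays.
#' @param label Character or factor of `"target"` / `"background"`, length N.
#' @param provenance Character or factor of `"animal"` / `"shadow"` /
#'   `"background"`, length N. Animal provenance must coincide with the
#'   target label.
#' @param aug Character vector of augmentation tags, length N (optional).
#' @return A `tile_dataset` object.
#' @export
tile_dataset <- function(x, label, provenance, aug = NULL) {
  if (is.list(x)) {
    stacked <- simplify2array(lapply(x, as_image_frame))
    x <- aperm(stacked, c(4L, 1L, 2L, 3L))
  }
  if (!is.array(x) || length(dim(x)) != 4L || dim(x)[4L] != 3L)
    stop("`x` must be an N x S x S x 3 array", call. = FALSE)
  n <- dim(x)[1L]
  label <- factor(as.character(label), levels = TILE_LABELS)
  provenance <- factor(as.character(provenance), levels = TILE_PROVENANCE)
  if (length(label) != n || length(provenance) != n || anyNA(label) || anyNA(provenance))
    stop("`label` and `provenance` must match the number of tiles", call. = FALSE)
  if (any((provenance == "animal") != (label == "target")))
    stop("animal provenance must coincide with the target label", call. = FALSE)
  if (is.null(aug)) aug <- rep("orig", n)
  structure(list(x = x, label = label, provenance = provenance,
                 aug = as.character(aug)),
            class = "tile_dataset")
}

#' Number of tiles in a dataset
#' @param ds A `tile_dataset`.
#' @return Integer count.
#' @export
n_tiles <- function(ds) dim(ds$x)[1L]

#' Per-class tile counts
#' @param ds A `tile_dataset`.
#' @return A table of counts by label.
#' @export
class_counts <- function(ds) table(ds$label)

#' @export
print.tile_dataset <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf("Tile dataset: %d tiles of %d x %d px (%d target, %d background)\n",
              n_tiles(x), dim(x$x)[2L], dim(x$x)[3L],
              cc[["target"]], cc[["background"]]))
  print(table(x$provenance))
  invisible(x)
}

#' @export
`[.tile_dataset` <- function(x, i) {
  tile_dataset(x$x[i, , , , drop = FALSE], x$label[i], x$provenance[i], x$aug[i])
}

#' Build the labeled tile dataset from a sprite bank
#'
#' Runs every source image through [augment_rotations()] then
#' [augment_perspective()], labels animal-provenance tiles as `target` and
#' shadow/background tiles as `background` (shadows act as hard negatives),
#' and resamples everything to `tile_px`. With the defaults each class of
#' `n` source images yields `n * 4 * (1 + n_deform)` tiles.
#'
#' @param bank A [render_sprite_bank()] result.
#' @param n_deform Perspective deformations per rotated image (default 2,
#'   so 4n rotations become 12n tiles per class).
#' @param seed Integer seed for the perspective jitter.
#' @param max_shift Corner jitter bound (fraction of side length).
#' @param tile_px Output tile side in pixels.
#' @return A `tile_dataset`.
#' @export
build_tile_dataset <- function(bank, n_deform = 2L, seed = 1L,
                               max_shift = 0.1, tile_px = 64L) {
  if (!inherits(bank, "sprite_bank"))
    stop("`bank` must be a sprite_bank", call. = FALSE)
  if (bank$n_per_class < 1L) stop("empty sprite bank", call. = FALSE)
  parts <- list()
  prov_of <- c(animals = "animal", shadows = "shadow", backgrounds = "background")
  for (cls_i in seq_along(prov_of)) {
    cls <- names(prov_of)[cls_i]
    imgs <- lapply(bank[[cls]], `[[`, "image")
    rot <- augment_rotations(imgs)
    rot_tags <- paste0("src", rep(seq_along(imgs), each = 4L), ".",
                       rep(c("rot0", "rot90", "rot180", "rot270"), length(imgs)))
    per <- augment_perspective(rot, n_deform = n_deform,
                               seed = sub_seed(seed, cls_i),
                               max_shift = max_shift)
    per_tags <- paste0(rep(rot_tags, each = 1L + n_deform), ".",
                       rep(c("orig", if (n_deform > 0L) paste0("persp", seq_len(n_deform))),
                           length(rot_tags)))
    if (dim(per[[1L]])[1L] != tile_px)
      per <- lapply(per, resize_bilinear, out_h = tile_px, out_w = tile_px)
    prov <- prov_of[[cls]]
    lab <- if (prov == "animal") "target" else "background"
    parts[[cls]] <- list(imgs = per, tags = per_tags,
                         label = rep(lab, length(per)),
                         prov = rep(prov, length(per)))
  }
  tile_dataset(do.call(c, lapply(parts, `[[`, "imgs")),
               unlist(lapply(parts, `[[`, "label"), use.names = FALSE),
               unlist(lapply(parts, `[[`, "prov"), use.names = FALSE),
               unlist(lapply(parts, `[[`, "tags"), use.names = FALSE))
}

#' Stratified train/test split
#'
#' Shuffles and splits a tile dataset, stratified by label. The overall
#' training size is `round(ratio * n)`; stratum sizes are allocated by the
#' largest-remainder rule so each stratum's proportion is within one tile
#' of `ratio`. Train and test are disjoint and exhaustive.
#'
#' @param ds A `tile_dataset` with at least two tiles.
#' @param ratio Training fraction, strictly between 0 and 1 (default 0.8).
#' @param seed Integer seed for the shuffle.
#' @return A `tile_split`: list with `train`, `test` (tile datasets),
#'   `train_idx`, `test_idx`, `ratio` and `seed`.
#' @export
split_dataset <- function(ds, ratio = 0.8, seed = 1L) {
  if (!inherits(ds, "tile_dataset")) stop("`ds` must be a tile_dataset", call. = FALSE)
  if (!is_number(ratio) || ratio <= 0 || ratio >= 1)
    stop("`ratio` must be strictly between 0 and 1", call. = FALSE)
  n <- n_tiles(ds)
  if (n < 2L) stop("dataset must contain at least two tiles", call. = FALSE)
  lab <- ds$label
  strata <- split(seq_len(n), lab, drop = TRUE)
  target_total <- round(ratio * n)
  sizes <- vapply(strata, length, integer(1L))
  base <- floor(ratio * sizes)
  rem <- target_total - sum(base)
  frac <- ratio * sizes - base
  if (rem > 0L) {
    give <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[give] <- base[give] + 1L
  } else if (rem < 0L) {
    take <- order(frac, decreasing = FALSE)[seq_len(-rem)]
    base[take] <- base[take] - 1L
  }
  train_idx <- with_seed(seed, {
    unlist(lapply(seq_along(strata), function(i) {
      idx <- strata[[i]]
      idx[sample.int(length(idx))][seq_len(base[i])]
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  structure(list(train = ds[train_idx], test = ds[test_idx],
                 train_idx = train_idx, test_idx = test_idx,
                 ratio = ratio, seed = as.integer(seed)),
            class = "tile_split")
}

#' @export
print.tile_split <- function(x, ...) {
  cat(sprintf("Tile split: %d train / %d test (ratio %.2f, seed %d)\n",
              n_tiles(x$train), n_tiles(x$test), x$ratio, x$seed))
  invisible(x)
}

#' Serialize a tile dataset to PNGs plus a CSV manifest
#'
#' Writes one PNG per tile and a manifest CSV with columns `filename`,
#' `label`, `provenance`, `augmentation_tag`.
#'
#' @param ds A `tile_dataset`.
#' @param dir Output directory (created if needed).
#' @param write_pngs Write the tile images as well as the manifest.
#' @return The manifest path, invisibly.
#' @export
write_tile_dataset <- function(ds, dir, write_pngs = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_tiles(ds)
  fn <- sprintf("tile_%05d.png", seq_len(n))
  if (write_pngs) {
    for (i in seq_len(n)) {
      img <- ds$x[i, , , , drop = TRUE]
      write_frame_png(array(img, dim(ds$x)[2:4]), file.path(dir, fn[i]))
    }
  }
  man <- data.frame(filename = fn, label = as.character(ds$label),
                    provenance = as.character(ds$provenance),
                    augmentation_tag = ds$aug, stringsAsFactors = FALSE)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Read a tile dataset written by [write_tile_dataset()]
#'
#' @param dir Directory containing `manifest.csv` and the tile PNGs.
#' @return A `tile_dataset`.
#' @export
read_tile_dataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  imgs <- lapply(file.path(dir, man$filename), read_frame_png)
  tile_dataset(imgs, man$label, man$provenance, man$augmentation_tag)
}
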