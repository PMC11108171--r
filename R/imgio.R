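# Raster, annotation and clinical-table IO plus the coordinate conventions
# every downstream stage relies on.
#
# Conventions (used package-wide):
#   * pixels are addressed 0-based as (row, col); windows are half-open
#     [origin, origin + size);
#   * polygon coordinates are (x, y) = (col, row) in level-0 pixel units;
#   * the center of pixel (r, c) at level L sits at level-L coordinates
#     (c + 0.5, r + 0.5), i.e. level-0 (c + 0.5) * downsample etc.;
#   * physical scale is carried as micrometers per pixel (spacing_um at
#     level 0) and every cross-resolution operation converts explicitly;
#   * out-of-bounds reads pad with white (255), matching H&E background.

# ---- SlideImage -----------------------------------------------------------

#' Construct a multiresolution slide image
#'
#' @param levels a single H x W x 3 array or a list of such arrays (level 0
#'   first, strictly decreasing in size), 8-bit values 0..255.
#' @param spacing_um micrometers per pixel at level 0 (> 0).
#' @param downsamples per-level downsample factors; derived from the level
#'   dimensions when omitted.
#' @return a `SlideImage` object.
#' @export
slide_image <- function(levels, spacing_um, downsamples = NULL) {
  if (!is.list(levels)) levels <- list(levels)
  stopifnot(length(levels) >= 1)
  for (lv in levels) {
    if (length(dim(lv)) != 3 || dim(lv)[3] != 3)
      stop("slide_image: each level must be an H x W x 3 array")
  }
  if (!is.numeric(spacing_um) || length(spacing_um) != 1 || spacing_um <= 0)
    stop("slide_image: spacing_um must be a single positive number")
  dims <- t(vapply(levels, function(a) dim(a)[1:2], integer(2)))
  if (is.null(downsamples))
    downsamples <- round(dims[1, 1] / dims[, 1], 6)
  if (length(downsamples) != length(levels))
    stop("slide_image: one downsample per level required")
  if (downsamples[1] != 1 || any(diff(downsamples) < 0) || any(downsamples < 1))
    stop("slide_image: downsamples must start at 1 and be non-decreasing")
  for (l in seq_along(levels)) {
    expect <- floor(dims[1, ] / downsamples[l])
    if (any(abs(dims[l, ] - expect) > 1))
      stop("slide_image: level ", l - 1, " dimensions inconsistent with downsample")
  }
  structure(list(levels = lapply(levels, function(a) {
    storage.mode(a) <- "integer"; a
  }),
  spacing_um = spacing_um, downsamples = as.numeric(downsamples),
  dims = dims), class = "SlideImage")
}

#' @export
print.SlideImage <- function(x, ...) {
  cat(sprintf("SlideImage: %d level(s), %.3g um/px at level 0\n",
              length(x$levels), x$spacing_um))
  for (l in seq_along(x$levels))
    cat(sprintf("  level %d: %d x %d (downsample %g)\n", l - 1,
                x$dims[l, 1], x$dims[l, 2], x$downsamples[l]))
  invisible(x)
}

#' Number of pyramid levels
#' @param slide a `SlideImage`.
#' @export
n_levels <- function(slide) length(slide$levels)

#' Raster dimensions (h, w) of a pyramid level
#' @param slide a `SlideImage`.
#' @param level 0-based level index.
#' @export
slide_dims <- function(slide, level = 0) slide$dims[level + 1, ]

#' Micrometers per pixel at a pyramid level
#' @param slide a `SlideImage`.
#' @param level 0-based level index.
#' @export
spacing_at <- function(slide, level = 0) slide$spacing_um * slide$downsamples[level + 1]

#' Build an image pyramid from a level-0 raster by block averaging
#'
#' @param level0 H x W x 3 array.
#' @param n_levels number of levels.
#' @param factor per-step integer downsample factor.
#' @param spacing_um level-0 spacing.
#' @export
build_pyramid <- function(level0, n_levels = 1, factor = 2, spacing_um = 1.0) {
  levels <- list(level0)
  cur <- level0
  for (l in seq_len(n_levels - 1)) {
    nxt <- array(0L, c(floor(dim(cur)[1] / factor), floor(dim(cur)[2] / factor), 3))
    for (k in 1:3) nxt[, , k] <- as.integer(round(cpp_block_mean(cur[, , k], factor)))
    levels[[l + 1]] <- nxt
    cur <- nxt
  }
  slide_image(levels, spacing_um, downsamples = factor^(seq_len(n_levels) - 1))
}

#' Read a slide raster
#'
#' Accepts a single-level PNG (spacing from a `<path>.json` sidecar or the
#' `spacing_um` argument) or a pyramid directory written by [write_slide()]
#' containing `manifest.json` plus one PNG per level.
#'
#' @param path file or directory path.
#' @param spacing_um explicit spacing override (required when no sidecar).
#' @return a `SlideImage`.
#' @export
read_slide <- function(path, spacing_um = NULL) {
  if (!file.exists(path)) stop("read_slide: no such file: ", path)
  if (dir.exists(path)) {
    mf <- file.path(path, "manifest.json")
    if (!file.exists(mf)) stop("read_slide: pyramid directory lacks manifest.json")
    man <- jsonlite::read_json(mf, simplifyVector = TRUE)
    levels <- lapply(man$levels, function(f) read_png(file.path(path, f)))
    return(slide_image(levels, spacing_um %||% man$spacing_um,
                       downsamples = man$downsamples))
  }
  img <- read_png(path)
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
  sidecar <- paste0(path, ".json")
  if (is.null(spacing_um)) {
    if (!file.exists(sidecar))
      stop("read_slide: spacing unknown; provide spacing_um or a ", sidecar,
           " sidecar with a spacing_um field")
    spacing_um <- jsonlite::read_json(sidecar)$spacing_um
    if (is.null(spacing_um)) stop("read_slide: sidecar lacks spacing_um")
  }
  slide_image(img, spacing_um)
}

#' Write a slide raster
#'
#' Single-level slides given a `.png` path are written as PNG + JSON spacing
#' sidecar; otherwise a pyramid directory (manifest.json + level PNGs).
#'
#' @param slide a `SlideImage`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path) {
  if (grepl("\\.png$", path) && n_levels(slide) == 1) {
    write_png(slide$levels[[1]], path)
    jsonlite::write_json(list(spacing_um = slide$spacing_um),
                         paste0(path, ".json"), auto_unbox = TRUE)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("level_%02d.png", seq_along(slide$levels) - 1)
  for (l in seq_along(slide$levels)) write_png(slide$levels[[l]], file.path(path, files[l]))
  jsonlite::write_json(list(spacing_um = slide$spacing_um,
                            downsamples = slide$downsamples, levels = files),
                       file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rectangular region from a slide level
#'
#' Coordinates are 0-based (row, col) on the requested level; the window is
#' half-open. Out-of-bounds area is padded with white (255,255,255).
#'
#' @param slide a `SlideImage`.
#' @param level 0-based level index.
#' @param origin integer (row, col) of the window's top-left corner.
#' @param size integer (h, w) window size.
#' @return an h x w x 3 integer array.
#' @export
read_region <- function(slide, level, origin, size) {
  if (any(size < 0)) stop("read_region: negative size")
  h <- size[1]; w <- size[2]
  out <- array(255L, c(h, w, 3))
  if (h == 0 || w == 0) return(out)
  lv <- slide$levels[[level + 1]]
  H <- dim(lv)[1]; W <- dim(lv)[2]
  r0 <- max(origin[1], 0); r1 <- min(origin[1] + h, H)
  c0 <- max(origin[2], 0); c1 <- min(origin[2] + w, W)
  if (r1 > r0 && c1 > c0)
    out[(r0 - origin[1] + 1):(r1 - origin[1]), (c0 - origin[2] + 1):(c1 - origin[2]), ] <-
      lv[(r0 + 1):r1, (c0 + 1):c1, , drop = FALSE]
  out
}

# ---- LabelMask ------------------------------------------------------------

#' Construct a label mask
#'
#' @param data integer matrix of class codes.
#' @param spacing_um micrometers per pixel of the raster.
#' @param classes named integer vector mapping semantic names to codes; every
#'   value present in `data` must appear in it.
#' @return a `LabelMask`.
#' @export
label_mask <- function(data, spacing_um,
                       classes = c(background = 0L, foreground = 1L)) {
  storage.mode(data) <- "integer"
  vals <- sort(unique(as.vector(data)))
  if (!all(vals %in% classes))
    stop("label_mask: raster contains codes absent from the class table: ",
         paste(setdiff(vals, classes), collapse = ", "))
  structure(list(data = data, spacing_um = spacing_um,
                 classes = vapply(classes, as.integer, integer(1))),
            class = "LabelMask")
}

#' @export
print.LabelMask <- function(x, ...) {
  cat(sprintf("LabelMask: %d x %d at %.3g um/px; classes: %s\n",
              nrow(x$data), ncol(x$data), x$spacing_um,
              paste(sprintf("%s=%d", names(x$classes), x$classes), collapse = ", ")))
  invisible(x)
}

#' Write a label mask as grayscale PNG + JSON sidecar
#' @param mask a `LabelMask`.
#' @param path output `.png` path.
#' @export
write_mask <- function(mask, path) {
  write_png(mask$data, path)
  jsonlite::write_json(list(spacing_um = mask$spacing_um,
                            classes = as.list(mask$classes)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a label mask written by [write_mask()]
#' @param path `.png` path with `<path>.json` sidecar.
#' @export
read_mask <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  label_mask(read_png(path), side$spacing_um,
             classes = unlist(side$classes))
}

#' Raster data of a mask
#'
#' Accessor used throughout the pipeline: returns the integer matrix of a
#' `LabelMask`, or the input unchanged when it is already a matrix.
#'
#' @param m a `LabelMask` or matrix.
#' @export
mask_data <- function(m) if (inherits(m, "LabelMask")) m$data else m

# ---- AnnotationSet --------------------------------------------------------

#' Construct an annotation set
#'
#' @param features list of features, each `list(name=, role=, rings=)` with
#'   `role` one of `"tumor_bulk"`, `"roi"`, `"other"` and `rings` a list of
#'   N x 2 (x, y) matrices in level-0 pixel coordinates (unclosed).
#' @return an `AnnotationSet`.
#' @export
annotation_set <- function(features) {
  for (f in features) {
    stopifnot(!is.null(f$name), !is.null(f$role), length(f$rings) >= 1)
    if (!f$role %in% c("tumor_bulk", "roi", "other"))
      stop("annotation_set: unknown role: ", f$role)
    for (rg in f$rings) {
      if (nrow(rg) < 3) stop("annotation_set: ring with < 3 vertices")
      if (abs(ring_area(rg)) < 1e-12) stop("annotation_set: zero-area ring")
    }
  }
  structure(list(features = features), class = "AnnotationSet")
}

ring_area <- function(rg) {
  x <- rg[, 1]; y <- rg[, 2]
  n <- nrow(rg)
  0.5 * sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet: %d feature(s)\n", length(x$features)))
  for (f in x$features)
    cat(sprintf("  %s [%s]: %d ring(s)\n", f$name, f$role, length(f$rings)))
  invisible(x)
}

#' Write annotations as a GeoJSON FeatureCollection
#'
#' Rings are explicitly closed on write; coordinates are level-0 pixels.
#'
#' @param ann an `AnnotationSet`.
#' @param path output `.geojson` path.
#' @export
write_annotations <- function(ann, path) {
  feats <- lapply(ann$features, function(f) {
    coords <- lapply(f$rings, function(rg) {
      closed <- rbind(rg, rg[1, , drop = FALSE])
      lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1], closed[i, 2]))
    })
    list(type = "Feature",
         properties = list(name = f$name, role = f$role),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection written by [write_annotations()]
#' @param path `.geojson` path.
#' @export
read_annotations <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- lapply(g$features, function(f) {
    rings <- lapply(f$geometry$coordinates, function(cr) {
      m <- do.call(rbind, lapply(cr, function(p) c(p[[1]], p[[2]])))
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      m
    })
    list(name = f$properties$name, role = f$properties$role, rings = rings)
  })
  annotation_set(feats)
}

#' Rasterize polygon annotations to a binary mask
#'
#' Pixel membership is decided by the pixel-center point-in-polygon rule
#' (even-odd); a center exactly on an edge counts as inside. Coordinates are
#' scaled from level 0 by the level downsample.
#'
#' @param ann an `AnnotationSet`.
#' @param slide the `SlideImage` the annotations refer to.
#' @param level 0-based target level.
#' @param roles optional character vector of roles to select (default: all).
#' @return a binary `LabelMask` aligned to the level.
#' @export
polygons_to_mask <- function(ann, slide, level = 0, roles = NULL) {
  dm <- slide_dims(slide, level)
  ds <- slide$downsamples[level + 1]
  out <- matrix(0L, dm[1], dm[2])
  for (f in ann$features) {
    if (!is.null(roles) && !f$role %in% roles) next
    rings <- lapply(f$rings, function(rg) rg / ds)
    out <- pmax(out, cpp_rasterize_rings(rings, dm[1], dm[2]))
  }
  label_mask(out, spacing_at(slide, level))
}

#' Trace a binary mask back to rectilinear polygons
#'
#' Boundaries follow pixel edges, so re-rasterizing the result with the
#' pixel-center rule reproduces the mask exactly.
#'
#' @param mask binary matrix or `LabelMask`.
#' @param downsample factor mapping mask pixels to level-0 coordinates.
#' @return list of N x 2 (x, y) rings in level-0 coordinates (outer rings
#'   counter-clockwise in image coordinates, holes clockwise).
#' @export
mask_to_polygons <- function(mask, downsample = 1) {
  m <- mask_data(mask)
  h <- nrow(m); w <- ncol(m)
  at <- function(r, c) if (r < 0 || c < 0 || r >= h || c >= w) 0L else m[r + 1, c + 1]
  # directed boundary edges, interior on the left (y down)
  edges <- new.env(hash = TRUE)
  add_edge <- function(x1, y1, x2, y2) {
    key <- paste(x1, y1, sep = ",")
    cur <- edges[[key]]
    edges[[key]] <- c(cur, list(c(x2, y2)))
  }
  idx <- which(m != 0, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1] - 1L; c <- idx[i, 2] - 1L
    if (at(r - 1, c) == 0) add_edge(c, r, c + 1, r)
    if (at(r, c + 1) == 0) add_edge(c + 1, r, c + 1, r + 1)
    if (at(r + 1, c) == 0) add_edge(c + 1, r + 1, c, r + 1)
    if (at(r, c - 1) == 0) add_edge(c, r + 1, c, r)
  }
  rings <- list()
  keys <- ls(edges)
  for (k in keys) {
    repeat {
      outs <- edges[[k]]
      if (is.null(outs) || length(outs) == 0) break
      # walk one ring starting here
      start <- as.numeric(strsplit(k, ",")[[1]])
      ring <- list(start)
      cur <- start
      prev_dir <- NULL
      repeat {
        key <- paste(cur[1], cur[2], sep = ",")
        cands <- edges[[key]]
        if (is.null(cands) || length(cands) == 0) break
        if (length(cands) == 1 || is.null(prev_dir)) pick <- 1L
        else {
          # prefer the sharpest left turn (keeps touching corners separate)
          turn <- vapply(cands, function(p) {
            d <- c(p[1] - cur[1], p[2] - cur[2])
            atan2(prev_dir[1] * d[2] - prev_dir[2] * d[1],
                  prev_dir[1] * d[1] + prev_dir[2] * d[2])
          }, numeric(1))
          pick <- which.max(turn)
        }
        nxt <- cands[[pick]]
        edges[[key]] <- cands[-pick]
        prev_dir <- c(nxt[1] - cur[1], nxt[2] - cur[2])
        cur <- nxt
        if (all(cur == start)) break
        ring[[length(ring) + 1]] <- cur
      }
      if (length(ring) >= 3) {
        rg <- do.call(rbind, ring)
        # drop collinear intermediate vertices
        keep <- rep(TRUE, nrow(rg))
        n <- nrow(rg)
        for (i in seq_len(n)) {
          p <- rg[if (i == 1) n else i - 1, ]; q <- rg[i, ]; s <- rg[if (i == n) 1 else i + 1, ]
          if ((q[1] - p[1]) * (s[2] - q[2]) == (q[2] - p[2]) * (s[1] - q[1])) keep[i] <- FALSE
        }
        rings[[length(rings) + 1]] <- rg[keep, , drop = FALSE] * downsample
      }
    }
  }
  rings
}

# ---- clinical table -------------------------------------------------------

#' Read a clinical table
#'
#' Expected columns: `patient_id`, `age`, `gender`, `vital_status`
#' (`"dead"`/`"alive"`), and either `survival_days` or the pair
#' `days_to_death` / `days_to_last_follow_up`. Optional categoricals
#' (`origin`, `primary_diagnosis`, `prior_malignancy`) are preserved, with
#' missing values mapped to the distinct level `"unknown"`.
#'
#' @param path CSV path.
#' @return a data.frame, one row per patient, with a populated
#'   `survival_days` column (days-to-death for the dead, days-to-last-
#'   follow-up otherwise) and integer `event` (1 = dead).
#' @export
read_clinical <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "age", "gender", "vital_status")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("read_clinical: missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("read_clinical: duplicate patient_id: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", "))
  if (!all(df$vital_status %in% c("dead", "alive")))
    stop("read_clinical: vital_status must be 'dead' or 'alive'")
  if (!"survival_days" %in% names(df)) {
    if (!all(c("days_to_death", "days_to_last_follow_up") %in% names(df)))
      stop("read_clinical: need survival_days or days_to_death + days_to_last_follow_up")
    df$survival_days <- ifelse(df$vital_status == "dead",
                               df$days_to_death, df$days_to_last_follow_up)
  }
  if (anyNA(df$survival_days) || any(df$survival_days < 0))
    stop("read_clinical: survival_days missing or negative")
  df$survival_days <- as.integer(df$survival_days)
  df$event <- as.integer(df$vital_status == "dead")
  for (col in intersect(c("gender", "origin", "primary_diagnosis", "prior_malignancy"),
                        names(df))) {
    v <- as.character(df[[col]])
    v[is.na(v) | v == ""] <- "unknown"
    df[[col]] <- v
  }
  df
}

#' Write a clinical table
#' @param df data.frame as returned by [read_clinical()].
#' @param path CSV path.
#' @export
write_clinical <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
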