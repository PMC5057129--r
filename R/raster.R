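# Raster-stack ingestion and per-pixel dispatch of the fitter. Rasters use
# the plain-text ESRI ASCII grid format; georeferencing is carried as grid
# metadata (lower-left corner, cell size). Pixel indices are 1-based
# row-major (row 1 = northernmost); map coordinates refer to cell centers.

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file path.
#' @return A numeric matrix with attributes `xll`, `yll`, `cellsize`,
#'   `nodata` (nodata cells are `NA`).
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  nh <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      nh <- nh + 1L
    } else break
  }
  ncols <- as.integer(hdr$ncols)
  nrows <- as.integer(hdr$nrows)
  vals <- scan(text = paste(lines[-seq_len(nh)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != ncols * nrows) stop("ASCII grid size mismatch")
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA_real_
  structure(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
            cellsize = hdr$cellsize, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param m Numeric matrix (`NA` written as the nodata value).
#' @param path Output path.
#' @param xll,yll Lower-left corner coordinates.
#' @param cellsize Cell size in map units.
#' @param nodata Nodata value.
#' @return `path`, invisibly.
#' @export
write_asc <- function(m, path, xll = attr(m, "xll"), yll = attr(m, "yll"),
                      cellsize = attr(m, "cellsize"),
                      nodata = attr(m, "nodata")) {
  if (is.null(xll)) xll <- 0
  if (is.null(yll)) yll <- 0
  if (is.null(cellsize)) cellsize <- 30
  if (is.null(nodata)) nodata <- -9999
  out <- m
  out[is.na(out)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
               sprintf("xllcorner %.10g", xll), sprintf("yllcorner %.10g", yll),
               sprintf("cellsize %.10g", cellsize),
               sprintf("NODATA_value %.10g", nodata)), con)
  writeLines(apply(out, 1, function(r) paste(format(r, trim = TRUE,
                                                    digits = 15),
                                             collapse = " ")), con)
  invisible(path)
}

#' Cloud-mask code policy
#'
#' Maps integer mask codes to valid/invalid. The default follows the common
#' fmask convention: 0 (clear) and 1 (water) valid; 2 (shadow), 3 (snow),
#' 4 (cloud) and 255 (fill) invalid.
#'
#' @param valid_codes Codes treated as valid observations.
#' @return An object of class `mask_policy`.
#' @export
mask_policy <- function(valid_codes = c(0L, 1L)) {
  structure(list(valid_codes = as.integer(valid_codes)),
            class = "mask_policy")
}

#' Parse an acquisition date from a Landsat scene identifier
#'
#' Supports collection-style ids (`LT05_L1TP_103063_19870615_...`, third
#' underscore field onward holds `YYYYMMDD`) and legacy ids
#' (`LT51030631987166...`, year + day-of-year). A sidecar CSV
#' (`scene_id, date`) can override parsing for synthetic fixtures via
#' [load_stack()].
#'
#' @param scene_id Character scene identifier(s).
#' @return Integer ordinal days.
#' @export
parse_scene_date <- function(scene_id) {
  vapply(scene_id, function(id) {
    m <- regmatches(id, regexpr("_(19|20)[0-9]{6}", id))
    if (length(m) == 1L) {
      return(as.integer(as.Date(substring(m, 2L), format = "%Y%m%d")))
    }
    m <- regmatches(id, regexpr("^L[A-Z][0-9][0-9]{6}[0-9]{7}", id))
    if (length(m) == 1L) {
      yr <- as.integer(substring(m, 10L, 13L))
      doy <- as.integer(substring(m, 14L, 16L))
      return(as.integer(as.Date(doy - 1L,
                                origin = sprintf("%d-01-01", yr))))
    }
    stop(sprintf("cannot parse a date from scene id '%s'", id))
  }, integer(1), USE.NAMES = FALSE)
}

#' Load a multi-date two-band raster stack
#'
#' Reads per-scene red/NIR reflectance and mask grids (ASCII grid format),
#' applies the mask policy, and assembles a `scene_stack`. All grids must
#' share shape and georeferencing; dates come from the scene ids (or an
#' explicit `day` vector / sidecar data frame) and must be unique (scenes
#' are sorted by date).
#'
#' @param red_paths,nir_paths,mask_paths Equal-length file path vectors;
#'   `mask_paths` may be `NULL` (all observations valid).
#' @param scene_ids Scene identifiers (default: red file base names).
#' @param day Optional explicit ordinal days, or a sidecar data frame with
#'   `scene_id` and `date` columns overriding id parsing.
#' @param policy A [mask_policy()].
#' @return An object of class `scene_stack`: `day`, 3-D arrays `red`,
#'   `nir`, logical `valid` (rows x cols x dates), and grid metadata.
#' @export
load_stack <- function(red_paths, nir_paths, mask_paths = NULL,
                       scene_ids = NULL, day = NULL,
                       policy = mask_policy()) {
  nsc <- length(red_paths)
  stopifnot(length(nir_paths) == nsc,
            is.null(mask_paths) || length(mask_paths) == nsc)
  if (is.null(scene_ids))
    scene_ids <- sub("\\.[^.]*$", "", basename(red_paths))
  if (is.data.frame(day)) {
    i <- match(scene_ids, day$scene_id)
    if (anyNA(i)) stop("sidecar is missing some scene ids")
    dd <- day$date[i]
    day <- if (inherits(dd, "Date")) as.integer(dd)
           else as.integer(as.Date(dd))
  }
  if (is.null(day)) day <- parse_scene_date(scene_ids)
  if (anyDuplicated(day)) stop("scene dates must be unique")
  red1 <- read_asc(red_paths[1])
  dims <- dim(red1)
  meta <- attributes(red1)[c("xll", "yll", "cellsize")]
  red <- array(NA_real_, c(dims, nsc))
  nir <- array(NA_real_, c(dims, nsc))
  valid <- array(TRUE, c(dims, nsc))
  for (k in seq_len(nsc)) {
    r <- if (k == 1L) red1 else read_asc(red_paths[k])
    nb <- read_asc(nir_paths[k])
    if (!identical(dim(r), dims) || !identical(dim(nb), dims))
      stop("raster grids do not match")
    for (a in c("xll", "yll", "cellsize")) {
      if (!isTRUE(all.equal(attr(r, a), meta[[a]])) ||
          !isTRUE(all.equal(attr(nb, a), meta[[a]])))
        stop("raster georeferencing does not match")
    }
    red[, , k] <- r
    nir[, , k] <- nb
    v <- !is.na(r) & !is.na(nb)
    if (!is.null(mask_paths)) {
      mk <- read_asc(mask_paths[k])
      if (!identical(dim(mk), dims)) stop("mask grid does not match")
      v <- v & !is.na(mk) & (mk %in% policy$valid_codes)
    }
    valid[, , k] <- v
  }
  o <- order(day)
  structure(list(day = as.integer(day[o]), red = red[, , o, drop = FALSE],
                 nir = nir[, , o, drop = FALSE],
                 valid = valid[, , o, drop = FALSE],
                 xll = meta$xll, yll = meta$yll, cellsize = meta$cellsize),
            class = "scene_stack")
}

#' @export
print.scene_stack <- function(x, ...) {
  cat(sprintf("scene_stack: %d x %d pixels, %d dates (%s to %s)\n",
              dim(x$red)[1], dim(x$red)[2], length(x$day),
              as.Date(min(x$day), origin = "1970-01-01"),
              as.Date(max(x$day), origin = "1970-01-01")))
  invisible(x)
}

#' Extract one pixel's NDVI time series from a stack
#'
#' @param stack A `scene_stack`.
#' @param row,col 1-based pixel indices.
#' @return A `pixel_series` of per-date NDVI with mask-derived validity
#'   (dates with an undefined NDVI are invalid).
#' @export
extract_series <- function(stack, row, col) {
  dims <- dim(stack$red)
  stopifnot(row >= 1, row <= dims[1], col >= 1, col <= dims[2])
  red <- stack$red[row, col, ]
  nir <- stack$nir[row, col, ]
  v <- stack$valid[row, col, ]
  ndvi <- rep(NA_real_, length(red))
  ok <- v & is.finite(red) & is.finite(nir) & red >= 0 & nir >= 0
  ndvi[ok] <- compute_ndvi(red[ok], nir[ok])
  pixel_series(stack$day, ndvi, valid = ok & !is.na(ndvi))
}

#' Fit every pixel of a stack and map the results
#'
#' Runs [nita_fit()] and [classify_trajectory()] on each pixel
#' independently (no spatial coupling; deterministic iteration order).
#' Pixels with fewer than 2 valid dates, or whose fit fails, yield nodata.
#'
#' @param stack A `scene_stack`.
#' @param params A [nita_params()] object.
#' @param thresholds A [nita_thresholds()] object.
#' @param verbose Log per-row progress to stderr.
#' @return A list of matrices: `date_of_disturbance` (ordinal day, `NA`
#'   where none), `segments`, `event_class` (0 none / 1 disturbance /
#'   2 decline / 3 no declining run classified). Each carries the stack's
#'   grid metadata for [write_asc()].
#' @export
fit_image <- function(stack, params = nita_params(),
                      thresholds = nita_thresholds(), verbose = FALSE) {
  dims <- dim(stack$red)[1:2]
  dod <- matrix(NA_integer_, dims[1], dims[2])
  segs <- matrix(NA_integer_, dims[1], dims[2])
  cls <- matrix(NA_integer_, dims[1], dims[2])
  for (r in seq_len(dims[1])) {
    if (verbose) message(sprintf("fit_image: row %d/%d", r, dims[1]))
    for (cc in seq_len(dims[2])) {
      s <- extract_series(stack, r, cc)
      if (n_valid(s) < 2L) next
      fit <- tryCatch(nita_fit(s, params), error = function(e) NULL)
      if (is.null(fit)) next
      segs[r, cc] <- fit$segments
      rec <- classify_trajectory(fit, thresholds)
      dod[r, cc] <- date_of_disturbance(rec)
      cls[r, cc] <- if (any(rec$event_class == "disturbance")) 1L
                    else if (any(rec$event_class == "decline")) 2L
                    else if (nrow(rec) > 0L) 3L else 0L
    }
  }
  meta <- function(m) structure(m, xll = stack$xll, yll = stack$yll,
                                cellsize = stack$cellsize, nodata = 0)
  list(date_of_disturbance = meta(dod), segments = meta(segs),
       event_class = meta(cls))
}

#' Sample a raster at map coordinates (nearest cell)
#'
#' @param m Matrix from [read_asc()] (row 1 = northernmost).
#' @param x,y Map coordinates.
#' @return Sampled values (`NA` outside the grid or at nodata cells).
#' @export
sample_raster <- function(m, x, y) {
  cs <- attr(m, "cellsize")
  xll <- attr(m, "xll")
  yll <- attr(m, "yll")
  col <- floor((x - xll) / cs) + 1L
  row <- nrow(m) - floor((y - yll) / cs)
  ok <- col >= 1L & col <= ncol(m) & row >= 1L & row <= nrow(m)
  out <- rep(NA_real_, length(x))
  out[ok] <- m[cbind(row[ok], col[ok])]
  out
}

#' Build an SPM sample matrix from red-reflectance rasters
#'
#' Samples each per-date red-reflectance grid at the transect points and
#' converts to SPM; reflectances at or above the model saturation (or
#' nodata cells) become invalid samples.
#'
#' @param red_paths Per-date red-reflectance ASCII grids.
#' @param day Ordinal days (or `Date`s), one per grid.
#' @param transect A [build_trident()] object or `points` data frame.
#' @param params A [spm_params()] object.
#' @param outlet Outlet label.
#' @return An [spm_samples()] object.
#' @export
sample_spm_stack <- function(red_paths, day, transect,
                             params = spm_params(), outlet = "outlet") {
  pts <- if (inherits(transect, "trident")) transect$points else transect
  vals <- t(vapply(red_paths, function(p) {
    rho <- sample_raster(read_asc(p), pts$x, pts$y)
    spm_from_reflectance(pmax(rho, 0), params)
  }, numeric(nrow(pts))))
  spm_samples(vals, day, outlet = outlet)
}
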