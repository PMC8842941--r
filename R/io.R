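## File formats: annotations as GeoJSON FeatureCollections (x = column,
## y = row, pixel units, properties class/rank/source), patch grids as CSV
## of positive cell indices, images as TIFF/PNG, rating tables and feature
## tables as CSV, pipeline configs as YAML.

#' Write annotations as GeoJSON
#'
#' Objects become Polygon features with coordinates in pixel units
#' (`x = column`, `y = row`, 0-based) and properties `class`, `rank`
#' (rank name, omitted for background) and `source`. Slide dimensions are
#' stored as foreign members `height`/`width` of the FeatureCollection.
#'
#' @param annotations an [AnnotationSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAnnotationsGeoJSON <- function(annotations, path) {
  df <- annotations@objects
  features <- lapply(seq_len(nrow(df)), function(i) {
    g <- df$geometry[[i]]
    ring <- cbind(g[, 2], g[, 1])                  # (x, y) = (col, row)
    if (nrow(ring) < 1L) stop("empty geometry")
    if (any(ring[1L, ] != ring[nrow(ring), ]))
      ring <- rbind(ring, ring[1L, , drop = FALSE])
    props <- list(class = df$class[i], source = df$source[i])
    if (!is.na(df$rank[i])) props$rank <- names(.RANKS)[df$rank[i]]
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(r) ring[r, ]))),
         properties = props)
  })
  fc <- list(type = "FeatureCollection", height = annotations@height,
             width = annotations@width, features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read annotations from GeoJSON
#'
#' @param path a GeoJSON file written by [writeAnnotationsGeoJSON()] (or
#'   any FeatureCollection of Polygon features with `class`/`rank`
#'   properties and `height`/`width` members).
#' @return An [AnnotationSet-class].
#' @export
readAnnotationsGeoJSON <- function(path) {
  fc <- jsonlite::read_json(path)
  stopIfNot(identical(fc$type, "FeatureCollection"),
            "not a GeoJSON FeatureCollection")
  geoms <- list(); classes <- character(); ranks <- integer()
  sources <- character()
  for (f in fc$features) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) unlist(p)))
    ## drop the closing vertex; store as (row, col)
    if (nrow(ring) > 1L &&
        all(ring[1L, ] == ring[nrow(ring), ]))
      ring <- ring[-nrow(ring), , drop = FALSE]
    geoms[[length(geoms) + 1L]] <- cbind(ring[, 2], ring[, 1])
    classes <- c(classes, f$properties$class)
    ranks <- c(ranks, if (is.null(f$properties$rank)) NA_integer_
               else .RANKS[[f$properties$rank]])
    sources <- c(sources, if (is.null(f$properties$source)) "human"
                 else f$properties$source)
  }
  AnnotationSet(geometry = geoms, class = classes, rank = ranks,
                height = fc$height, width = fc$width, source = sources)
}

#' Write a PatchGrid as CSV of positive cells
#'
#' Columns `row`, `col` (0-based cell indices); slide geometry is kept in a
#' leading comment line so the grid round-trips.
#'
#' @param grid a [PatchGrid-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePatchGridCSV <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# slideHeight=%d slideWidth=%d cellSize=%d",
                     grid@slideHeight, grid@slideWidth, grid@cellSize), con)
  write.csv(as.data.frame(positiveCells(grid)), con, row.names = FALSE)
  invisible(path)
}

#' Read a PatchGrid from CSV
#'
#' @param path file written by [writePatchGridCSV()].
#' @return A [PatchGrid-class].
#' @export
readPatchGridCSV <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, gregexpr("[0-9]+", hdr))[[1]]
  stopIfNot(length(m) == 3L, "malformed patch-grid header")
  cells <- read.csv(path, comment.char = "#")
  PatchGrid(as.matrix(cells), slideHeight = as.integer(m[1]),
            slideWidth = as.integer(m[2]), cellSize = as.integer(m[3]))
}

#' Write an RGB or single-channel image
#'
#' Intensity arrays in `(0, 255]` are scaled to `[0, 1]`; single-channel
#' float maps (e.g. probability masks or stain channels) are written as-is
#' after clipping to `[0, 1]` unless `normalize = TRUE`.
#'
#' @param image `h x w x 3` intensity array or `h x w` matrix.
#' @param path output path ending in `.tif`/`.tiff` or `.png`.
#' @param normalize rescale a matrix to `[0, 1]` by its range.
#' @return `path`, invisibly.
#' @export
writeImage <- function(image, path, normalize = FALSE) {
  if (is.matrix(image)) {
    if (normalize && diff(range(image)) > 0)
      image <- (image - min(image)) / diff(range(image))
    img01 <- pmin(pmax(image, 0), 1)
  } else {
    img01 <- pmin(pmax(image / 255, 0), 1)
  }
  if (grepl("\\.png$", path, ignore.case = TRUE))
    png::writePNG(img01, path)
  else
    tiff::writeTIFF(img01, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an image written by [writeImage()]
#'
#' @param path `.tif`/`.tiff` or `.png` file.
#' @param intensity rescale channels back to `(0, 255]` (default TRUE for
#'   RGB arrays).
#' @return numeric array or matrix.
#' @export
readImage <- function(path, intensity = TRUE) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path)
  if (intensity && length(dim(img)) == 3L) img <- img * 255
  img
}

#' Write / read a RatingTable as CSV
#'
#' Rows are items, columns raters.
#'
#' @param table a [RatingTable-class].
#' @param path CSV file.
#' @return `path` (write) or a [RatingTable-class] (read).
#' @export
writeRatingTableCSV <- function(table, path) {
  write.csv(as.data.frame(table@ratings), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRatingTableCSV
#' @param categories optional category set for the read table.
#' @export
readRatingTableCSV <- function(path, categories = NULL) {
  RatingTable(read.csv(path, colClasses = "character"),
              categories = categories)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of [runPipeline()] settings.
#' @return named list.
#' @export
readPipelineConfig <- function(path) {
  yaml::read_yaml(path)
}
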