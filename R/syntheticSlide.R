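## Synthetic brightfield slide generation.
##
## A slide is rendered through the physical brightfield model
##   I_c = I0_c * 10^(-OD_c),  OD = c_H * v_H + c_D * v_D,
## where c_H is a smooth tissue counterstain field and c_D is elevated along
## curvilinear neurite-like strokes (foreground LTS objects; definite and
## probable ranks) and small dot/blob structures (possible-rank dots and
## background granules). Every painted object is returned with its exact
## geometry, class and confidence rank, so the generator doubles as ground
## truth for the detector, the stain round trip, and the feature pipeline.

#' Specification of one synthetic slide
#'
#' @slot height,width slide size in pixels (each at least 302, i.e. two
#'   patch widths).
#' @slot nDefinite,nProbable,nPossible foreground LTS object counts per
#'   confidence rank.
#' @slot nBackground count of non-LTS immunopositive background objects.
#' @slot spatialClustering dispersion parameter, >= 0; 0 places foreground
#'   objects uniformly, larger values use a tighter parent-offspring
#'   (Thomas-type) process.
#' @slot dabRange positive interval, per-object DAB amplitude (OD units).
#' @slot noiseSd Gaussian intensity noise SD (grey levels), >= 0.
#' @slot seed RNG seed; all output is a pure function of (spec, seed).
#' @export
setClass("SlideSpec",
  representation(height = "integer", width = "integer",
                 nDefinite = "integer", nProbable = "integer",
                 nPossible = "integer", nBackground = "integer",
                 spatialClustering = "numeric", dabRange = "numeric",
                 noiseSd = "numeric", seed = "integer"))

setValidity("SlideSpec", function(object) {
  msg <- character()
  if (object@height < 302L || object@width < 302L)
    msg <- c(msg, "slide must be at least 302 x 302 px (two patch widths)")
  if (min(object@nDefinite, object@nProbable, object@nPossible,
          object@nBackground) < 0L)
    msg <- c(msg, "object counts must be non-negative")
  if (object@spatialClustering < 0)
    msg <- c(msg, "spatialClustering must be >= 0")
  if (length(object@dabRange) != 2L || any(object@dabRange <= 0) ||
      diff(object@dabRange) < 0)
    msg <- c(msg, "dabRange must be a positive interval (lo, hi)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a SlideSpec
#'
#' @param height,width slide size in pixels, minimum 302.
#' @param nDefinite,nProbable,nPossible foreground object counts by rank.
#' @param nBackground background object count.
#' @param spatialClustering >= 0; 0 = uniform placement, larger = tighter
#'   parent-offspring clustering of foreground objects.
#' @param dabRange per-object DAB amplitude interval in OD units.
#' @param noiseSd Gaussian intensity noise SD in grey levels.
#' @param seed RNG seed.
#' @return a validated [SlideSpec-class].
#' @export
slideSpec <- function(height = 604L, width = 604L, nDefinite = 5L,
                      nProbable = 4L, nPossible = 3L, nBackground = 8L,
                      spatialClustering = 1, dabRange = c(0.4, 0.9),
                      noiseSd = 0, seed = 1L) {
  obj <- new("SlideSpec", height = as.integer(height),
             width = as.integer(width), nDefinite = as.integer(nDefinite),
             nProbable = as.integer(nProbable),
             nPossible = as.integer(nPossible),
             nBackground = as.integer(nBackground),
             spatialClustering = as.numeric(spatialClustering),
             dabRange = as.numeric(dabRange), noiseSd = as.numeric(noiseSd),
             seed = as.integer(seed))
  validObject(obj)
  obj
}

setMethod("show", "SlideSpec", function(object) {
  cat(sprintf(paste0("SlideSpec: %d x %d px, LTS %d/%d/%d (def/prob/poss), ",
                     "%d background, clustering %g, seed %d\n"),
              object@height, object@width, object@nDefinite,
              object@nProbable, object@nPossible, object@nBackground,
              object@spatialClustering, object@seed))
})

#' Rendered synthetic slide
#'
#' @slot image RGB intensity array `h x w x 3` in `(0, 255]`, or a
#'   0-extent array when rendered with `render = FALSE`.
#' @slot annotations the exact [AnnotationSet-class] painted on the slide.
#' @slot hematoxylinField,dabField the generator's ground-truth stain
#'   concentration fields (OD units), used by round-trip tests (0-extent
#'   when rendered with `render = FALSE`).
#' @slot tissue logical ground-truth tissue mask (0-extent without
#'   rendering).
#' @slot spec the [SlideSpec-class] that produced the slide.
#' @export
setClass("SyntheticSlide",
  representation(image = "array", annotations = "AnnotationSet",
                 hematoxylinField = "matrix", dabField = "matrix",
                 tissue = "matrix", spec = "SlideSpec"))

setMethod("show", "SyntheticSlide", function(object) {
  cat(sprintf("SyntheticSlide: %d x %d px (%s)\n", object@spec@height,
              object@spec@width,
              if (length(object@image)) "rendered" else "annotations only"))
  show(object@annotations)
})

## --- geometry helpers ------------------------------------------------------

## Random-walk polyline of a neurite-like stroke; (row, col), 0-based.
.randomWalkPolyline <- function(center, nSegments, step, turnSd) {
  theta <- runif(1, 0, 2 * pi)
  pts <- matrix(0, nSegments + 1L, 2L)
  pts[1L, ] <- center
  for (i in seq_len(nSegments)) {
    theta <- theta + rnorm(1, 0, turnSd)
    pts[i + 1L, ] <- pts[i, ] + step * c(sin(theta), cos(theta))
  }
  ## recenter so the stroke's centroid is the requested center
  pts <- pts + rep(center - colMeans(pts), each = nrow(pts))
  pts
}

## Buffer a polyline into a simple polygon at half-width hw.
.bufferPolyline <- function(pts, hw) {
  np <- nrow(pts)
  d <- diff(pts)
  len <- sqrt(rowSums(d^2))
  len[len == 0] <- 1e-9
  segn <- cbind(-d[, 2], d[, 1]) / len      # unit normal per segment
  vn <- matrix(0, np, 2L)                   # vertex normals (averaged)
  vn[1L, ] <- segn[1L, ]
  vn[np, ] <- segn[np - 1L, ]
  if (np > 2L)
    vn[2:(np - 1L), ] <- (segn[1:(np - 2L), , drop = FALSE] +
                          segn[2:(np - 1L), , drop = FALSE]) / 2
  nn <- sqrt(rowSums(vn^2)); nn[nn == 0] <- 1
  vn <- vn / nn
  rbind(pts + hw * vn, (pts - hw * vn)[np:1, , drop = FALSE])
}

.discPolygon <- function(center, radius, k = 16L) {
  ang <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  cbind(center[1] + radius * sin(ang), center[2] + radius * cos(ang))
}

.clampGeometry <- function(g, height, width) {
  g[, 1] <- pmin(pmax(g[, 1], 0), height - 1L)
  g[, 2] <- pmin(pmax(g[, 2], 0), width - 1L)
  g
}

## Paint a smooth DAB bump along a polyline into field (in place, returned).
## Amplitude amp at the spine, Gaussian falloff with scale hw, truncated at
## 3*hw; field accumulates (overlaps add) and the caller caps the total.
.paintStroke <- function(field, pts, hw, amp) {
  h <- nrow(field); w <- ncol(field)
  reach <- ceiling(3 * hw)
  r0 <- max(1L, floor(min(pts[, 1])) - reach + 1L)
  r1 <- min(h, ceiling(max(pts[, 1])) + reach + 1L)
  c0 <- max(1L, floor(min(pts[, 2])) - reach + 1L)
  c1 <- min(w, ceiling(max(pts[, 2])) + reach + 1L)
  if (r0 > r1 || c0 > c1) return(field)
  rows <- (r0:r1) - 1L; cols <- (c0:c1) - 1L
  R <- matrix(rows, length(rows), length(cols))
  C <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  dmin <- matrix(Inf, length(rows), length(cols))
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    ab <- b - a; ab2 <- sum(ab^2)
    if (ab2 == 0) {
      d2 <- (R - a[1])^2 + (C - a[2])^2
    } else {
      t <- ((R - a[1]) * ab[1] + (C - a[2]) * ab[2]) / ab2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (R - (a[1] + t * ab[1]))^2 + (C - (a[2] + t * ab[2]))^2
    }
    dmin <- pmin(dmin, d2)
  }
  bump <- amp * exp(-dmin / (2 * (hw / 1.6)^2))
  bump[dmin > (3 * hw)^2] <- 0
  field[r0:r1, c0:c1] <- field[r0:r1, c0:c1] + bump
  field
}

## --- placement -------------------------------------------------------------

## Thomas-type parent-offspring placement of n points inside a margin-inset
## rectangle. clustering = 0 gives uniform placement.
.placeCenters <- function(n, height, width, clustering, margin = 30,
                          offspringSd = 30) {
  if (n == 0L) return(matrix(numeric(), 0L, 2L))
  lo <- c(margin, margin); hi <- c(height - 1 - margin, width - 1 - margin)
  if (clustering <= 0) {
    return(cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2])))
  }
  nParents <- max(1L, ceiling(n / (1 + 3 * clustering)))
  parents <- cbind(runif(nParents, lo[1], hi[1]), runif(nParents, lo[2], hi[2]))
  assign <- sample.int(nParents, n, replace = TRUE)
  off <- parents[assign, , drop = FALSE] +
    matrix(rnorm(2 * n, 0, offspringSd / sqrt(clustering)), n, 2L)
  off[, 1] <- pmin(pmax(off[, 1], lo[1]), hi[1])
  off[, 2] <- pmin(pmax(off[, 2], lo[2]), hi[2])
  off
}

## --- main generator --------------------------------------------------------

#' Generate a synthetic stained slide with exact ground truth
#'
#' Renders an H-DAB brightfield image through the physical model
#' `I_c = I0_c * 10^(-OD_c)` with `OD = c_H v_H + c_D v_D`: the hematoxylin
#' concentration `c_H` is a smooth random tissue field supported on a
#' super-elliptical tissue region, and the DAB concentration `c_D` is painted
#' along neurite-like random-walk strokes (definite/probable foreground LTS),
#' small discs (possible-rank dots) and blob artifacts (background objects).
#' Foreground objects are placed by a Thomas-type parent-offspring process
#' controlled by `spec@spatialClustering`. All randomness is governed by
#' `spec@seed`; two calls with the same spec produce identical output.
#'
#' @param spec a [SlideSpec-class].
#' @param model a [StainModel-class]; defaults to the standard H-DAB basis.
#' @param render if `FALSE`, skip image synthesis and return annotations and
#'   ground-truth fields only (the annotations are identical to the rendered
#'   call with the same spec).
#' @return A [SyntheticSlide-class].
#' @examples
#' sl <- generateSlide(slideSpec(nDefinite = 2, nProbable = 0, nPossible = 0,
#'                               nBackground = 0, seed = 7))
#' nObjects(sl@annotations)
#' @export
generateSlide <- function(spec, model = hdabStainModel(), render = TRUE) {
  stopIfNot(is(spec, "SlideSpec"), "'spec' must be a SlideSpec")
  validObject(spec)
  h <- spec@height; w <- spec@width
  withSeed(spec@seed, {
    ## counterstain bump parameters are always drawn so the RNG stream (and
    ## hence the annotations) is identical whether or not we render
    bumps <- lapply(seq_len(6L), function(b)
      list(ctr = c(runif(1, 0, h - 1), runif(1, 0, w - 1)),
           sig = runif(1, h / 8, h / 3), amp = runif(1, -0.08, 0.08)))
    tissue <- matrix(logical(), 0L, 0L)
    cH <- matrix(numeric(), 0L, 0L)
    if (render) {
      ## tissue support: super-ellipse covering most of the slide
      rr <- (seq_len(h) - 1 - (h - 1) / 2) / (0.48 * h)
      cc <- (seq_len(w) - 1 - (w - 1) / 2) / (0.48 * w)
      tissue <- outer(rr^4, cc^4, "+") <= 1
      ## smooth counterstain field: base level plus low-frequency bumps
      cH <- matrix(0.25, h, w)
      for (b in bumps) {
        cH <- cH + b$amp *
          outer(exp(-((seq_len(h) - 1 - b$ctr[1])^2) / (2 * b$sig^2)),
                exp(-((seq_len(w) - 1 - b$ctr[2])^2) / (2 * b$sig^2)))
      }
      cH <- pmax(cH, 0.08) * tissue
    }

    nFg <- spec@nDefinite + spec@nProbable + spec@nPossible
    fgCenters <- .placeCenters(nFg, h, w, spec@spatialClustering)
    bgCenters <- .placeCenters(spec@nBackground, h, w, 0)
    ranks <- c(rep(3L, spec@nDefinite), rep(2L, spec@nProbable),
               rep(1L, spec@nPossible))

    cD <- if (render) matrix(0, h, w) else matrix(numeric(), 0L, 0L)
    geoms <- vector("list", nFg + spec@nBackground)
    classes <- c(rep("foreground", nFg), rep("background", spec@nBackground))
    rankCol <- c(ranks, rep(NA_integer_, spec@nBackground))

    for (i in seq_len(nFg)) {
      amp <- runif(1, spec@dabRange[1], spec@dabRange[2])
      if (ranks[i] == 3L) {            # definite: long linear neurite
        pts <- .randomWalkPolyline(fgCenters[i, ], 8L, 7, 0.45)
        hw <- 2.5
      } else if (ranks[i] == 2L) {     # probable: shorter, fainter neurite
        pts <- .randomWalkPolyline(fgCenters[i, ], 5L, 6, 0.6)
        hw <- 2
        amp <- amp * 0.8
      } else {                         # possible: dot-like cross-section
        pts <- matrix(rep(fgCenters[i, ], 2), 2L, 2L, byrow = TRUE)
        hw <- runif(1, 1.5, 3)
        amp <- amp * 0.7
      }
      pts <- .clampGeometry(pts, h, w)
      if (render) cD <- .paintStroke(cD, pts, hw, amp)
      poly <- if (ranks[i] == 1L) .discPolygon(fgCenters[i, ], hw)
              else .bufferPolyline(pts, hw)
      geoms[[i]] <- .clampGeometry(poly, h, w)
    }
    for (j in seq_len(spec@nBackground)) {
      amp <- runif(1, spec@dabRange[1], spec@dabRange[2]) * 0.9
      rad <- runif(1, 3.5, 7)
      ctr <- bgCenters[j, ]
      pts <- matrix(rep(ctr, 2), 2L, 2L, byrow = TRUE)
      if (render) cD <- .paintStroke(cD, pts, rad, amp)
      geoms[[nFg + j]] <- .clampGeometry(.discPolygon(ctr, rad), h, w)
    }
    if (render)
      cD <- pmin(cD, 1.5) # cap so intensities stay well above the clamp floor

    ann <- AnnotationSet(geometry = geoms, class = classes, rank = rankCol,
                         height = h, width = w)

    img <- array(numeric(), c(0L, 0L, 0L))
    if (render) {
      img <- array(0, c(h, w, 3L))
      for (c in 1:3) {
        od <- cH * model@hematoxylin[c] + cD * model@dab[c]
        img[, , c] <- model@background[c] * 10^(-od)
      }
      if (spec@noiseSd > 0) {
        img <- img + array(rnorm(length(img), 0, spec@noiseSd), dim(img))
        img <- pmin(pmax(img, 1), array(rep(model@background, each = h * w),
                                        c(h, w, 3L)))
      }
    }
    new("SyntheticSlide", image = img, annotations = ann,
        hematoxylinField = cH, dabField = cD,
        tissue = if (length(tissue)) tissue else matrix(logical(), 0L, 0L),
        spec = spec)
  })
}
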