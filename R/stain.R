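#' Optical-density transform
#'
#' Converts brightfield RGB intensities to optical density per channel,
#' `OD_c = -log10(I_c / I0_c)`. Zero (or negative) intensities are clamped to
#' 1 before the log; the number of clamped entries is attached as the
#' `"clamped"` attribute.
#'
#' @param image numeric array `h x w x 3` of intensities in `(0, I0]`.
#' @param I0 background intensity per channel (length 1 or 3), default 255.
#' @return numeric array `h x w x 3` of optical densities, attribute
#'   `clamped` = number of clamped entries.
#' @examples
#' img <- array(255, c(2, 2, 3))
#' range(odTransform(img))  # all zero
#' @export
odTransform <- function(image, I0 = c(255, 255, 255)) {
  stopIfNot(length(dim(image)) == 3L && dim(image)[3] == 3L,
            "'image' must be an h x w x 3 array")
  I0 <- rep(I0, length.out = 3L)
  nclamp <- sum(image < 1)
  image[image < 1] <- 1
  od <- image
  for (c in 1:3) od[, , c] <- -log10(image[, , c] / I0[c])
  attr(od, "clamped") <- nclamp
  od
}

#' Inverse optical-density transform
#'
#' @param od optical-density array `h x w x 3`.
#' @param I0 background intensity per channel.
#' @return intensity array, `I_c = I0_c * 10^(-OD_c)`.
#' @export
odInverse <- function(od, I0 = c(255, 255, 255)) {
  I0 <- rep(I0, length.out = 3L)
  out <- od
  for (c in 1:3) out[, , c] <- I0[c] * 10^(-od[, , c])
  out
}

#' Colour deconvolution into stain channels
#'
#' Solves, for every pixel, the linear system `OD = c_H v_H + c_D v_D +
#' c_R v_R` against the stain basis of `model` (the residual direction is the
#' normalised cross product of the two stain vectors, so the 3 x 3 system is
#' exactly determined and the solve is the least-squares solution). Negative
#' concentrations are clamped to zero and counted.
#'
#' @param od optical-density array `h x w x 3` (see [odTransform()]).
#' @param model a [StainModel-class].
#' @param clamp clamp negative concentrations at zero (default TRUE; the
#'   linearity property of the deconvolution holds exactly with
#'   `clamp = FALSE`).
#' @return A [StainChannels-class] with hematoxylin, DAB and residual maps.
#' @examples
#' m <- hdabStainModel()
#' od <- array(0.7 * m@hematoxylin + 0.3 * m@dab, c(1, 1, 3))
#' ch <- deconvolveStains(od, m)
#' c(ch@hematoxylin, ch@dab)  # 0.7 0.3
#' @export
deconvolveStains <- function(od, model, clamp = TRUE) {
  stopIfNot(is(model, "StainModel"), "'model' must be a StainModel")
  validObject(model)
  stopIfNot(length(dim(od)) == 3L && dim(od)[3] == 3L,
            "'od' must be an h x w x 3 array")
  d <- dim(od)
  M <- cbind(model@hematoxylin, model@dab, model@residual)
  Minv <- solve(M)
  odm <- matrix(od, ncol = 3L)          # pixels x channels
  conc <- odm %*% t(Minv)               # pixels x stains
  nneg <- 0L
  if (clamp) {
    nneg <- sum(conc < 0)
    conc[conc < 0] <- 0
  }
  new("StainChannels",
      hematoxylin = matrix(conc[, 1], d[1], d[2]),
      dab = matrix(conc[, 2], d[1], d[2]),
      residual = matrix(conc[, 3], d[1], d[2]),
      negativeClamped = as.integer(nneg))
}

#' Stain statistics inside detector-positive patches
#'
#' Pools all pixels lying inside the positive 40 x 40 cells of `grid` and
#' returns the sum, mean, median and (population) standard deviation of the
#' hematoxylin and DAB concentration maps over that pool. With
#' `perPatch = TRUE` the mean/median/sd are instead computed per positive cell
#' and averaged (the sum is always the pooled sum).
#'
#' @param channels a [StainChannels-class].
#' @param grid a [PatchGrid-class] aligned to the channel maps.
#' @param perPatch average per-cell statistics instead of pooling pixels.
#' @return named numeric vector
#'   `h_sum, h_mean, h_median, h_sd, dab_sum, dab_mean, dab_median, dab_sd`;
#'   all `NA` when the grid has no positive cell.
#' @export
stainStatistics <- function(channels, grid, perPatch = FALSE) {
  stopIfNot(is(channels, "StainChannels"), "'channels' must be StainChannels")
  stopIfNot(is(grid, "PatchGrid"), "'grid' must be a PatchGrid")
  if (nrow(channels@hematoxylin) != grid@slideHeight ||
      ncol(channels@hematoxylin) != grid@slideWidth)
    stop("channel maps and grid refer to different slide dimensions",
         call. = FALSE)
  nm <- c("h_sum", "h_mean", "h_median", "h_sd",
          "dab_sum", "dab_mean", "dab_median", "dab_sd")
  pc <- positiveCells(grid)
  if (!nrow(pc)) {
    out <- rep(NA_real_, 8L); names(out) <- nm
    return(out)
  }
  cs <- grid@cellSize
  cellPixels <- function(map, i, j) {
    rows <- (i * cs + 1L):min((i + 1L) * cs, nrow(map))
    cols <- (j * cs + 1L):min((j + 1L) * cs, ncol(map))
    as.vector(map[rows, cols])
  }
  stats4 <- function(v) c(sum(v), mean(v), median(v), popSd(v))
  perChannel <- function(map) {
    px <- lapply(seq_len(nrow(pc)),
                 function(k) cellPixels(map, pc[k, 1], pc[k, 2]))
    if (perPatch) {
      m <- vapply(px, stats4, numeric(4))
      c(sum(unlist(px)), mean(m[2, ]), mean(m[3, ]), mean(m[4, ]))
    } else {
      stats4(unlist(px))
    }
  }
  out <- c(perChannel(channels@hematoxylin), perChannel(channels@dab))
  names(out) <- nm
  out
}

#' Tissue mask by optical-density magnitude
#'
#' A pixel is called tissue when the Euclidean norm of its OD vector,
#' after 3 x 3 median smoothing, reaches `threshold`. White (background glass)
#' pixels have OD ~ 0 and are excluded.
#'
#' @param image RGB intensity array `h x w x 3`.
#' @param model a [StainModel-class] (supplies the background intensity I0).
#' @param threshold minimum smoothed OD magnitude, default 0.05.
#' @param smooth apply the median filter (default TRUE).
#' @return logical matrix `h x w`; attribute `count` = number of tissue
#'   pixels.
#' @export
tissueMask <- function(image, model = hdabStainModel(), threshold = 0.05,
                       smooth = TRUE) {
  od <- odTransform(image, model@background)
  mag <- sqrt(od[, , 1]^2 + od[, , 2]^2 + od[, , 3]^2)
  if (smooth) mag <- medianFilter3(mag)
  mask <- mag >= threshold
  attr(mask, "count") <- sum(mask)
  mask
}
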