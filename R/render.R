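#' Render configuration
#'
#' Collects every knob of a rendering run in one validated list so runs are
#' reproducible from their logged configuration alone.
#'
#' @param viewDir numeric(3) view direction (orthographic camera).
#' @param width,height output image size in pixels.
#' @param pixelPitch mm between adjacent rays; \code{NULL} (default) picks
#'   the smallest pitch whose image covers the whole box diagonal.
#' @param step sampling distance delta along each ray in mm (default 0.3).
#' @param sampler \code{"traditional"} (trilinear) or \code{"plane"}
#'   (plane-cluster).
#' @param axis plane-cluster axis: \code{"auto"} (dominant component) or an
#'   explicit \code{"x"}, \code{"y"}, \code{"z"} override.
#' @param classify \code{"pre"} (optical properties assigned to all vertexes,
#'   then interpolated -- the default) or \code{"post"} (gray interpolated,
#'   then classified). The two commute on linear transfer segments.
#' @param earlyTermination logical, stop compositing at accumulated
#'   transparency < 1e-4 (default FALSE).
#' @param backToFront logical, reverse sample order before compositing
#'   (experimentation flag; default FALSE keeps the viewer-nearest sample
#'   first, matching the compositing sum literally).
#' @return A named list with class \code{"renderConfig"}.
#' @export
renderConfig <- function(viewDir = c(0, 1, 0), width = 64L, height = 64L,
                         pixelPitch = NULL, step = 0.3,
                         sampler = c("plane", "traditional"),
                         axis = "auto", classify = c("pre", "post"),
                         earlyTermination = FALSE, backToFront = FALSE) {
  sampler <- match.arg(sampler)
  classify <- match.arg(classify)
  stopifnot(width >= 1, height >= 1, step > 0)
  if (!identical(axis, "auto")) .axisIndex(axis)
  structure(list(viewDir = as.numeric(viewDir), width = as.integer(width),
                 height = as.integer(height), pixelPitch = pixelPitch,
                 step = step, sampler = sampler, axis = axis,
                 classify = classify, earlyTermination = earlyTermination,
                 backToFront = backToFront),
            class = "renderConfig")
}

#' Render a volume by ray casting
#'
#' The full pipeline, per output pixel: build the orthographic ray, clip it
#' to the volume box, enumerate regular sample positions, sample optical
#' properties with the chosen backend (trilinear or plane-cluster), and
#' composite front to back. With pre-classification (the default) the
#' transfer function is applied once to every grid vertex and the resulting
#' color and opacity fields are interpolated; with post-classification the
#' gray field is interpolated and classified per sample. Rays that miss the
#' box contribute the background value 0; the rare boundary-grazing ray whose
#' clipped segment crosses fewer than two cluster planes cannot be bracketed
#' by the plane-cluster method and is sampled trilinearly instead. Rendering
#' is deterministic: identical volume and configuration give identical
#' images.
#'
#' @param volume a [ScalarVolume-class].
#' @param tf a [TransferFunction-class].
#' @param config a [renderConfig()] list.
#' @return A list with \code{image} (height x width matrix, or
#'   height x width x 3 array for RGB transfer functions) and \code{log}
#'   (sampler, axis used, step, ray/sample tallies, and the full
#'   configuration).
#' @examples
#' vol <- generatePhantom(phantomSpec("sphere", extents = c(16, 16, 16),
#'                                    spacing = c(1, 1, 1)))
#' tf <- rampTransferFunction(lo = 100, hi = 1000)
#' out <- renderVolume(vol, tf, renderConfig(width = 8, height = 8, step = 1))
#' dim(out$image)
#' @export
renderVolume <- function(volume, tf, config = renderConfig()) {
  stopifnot(inherits(config, "renderConfig"))
  pitch <- config$pixelPitch
  if (is.null(pitch))
    pitch <- sqrt(sum(volumeBox(volume)^2)) /
      max(config$width, config$height)
  rays <- orthographicRays(volume, config$viewDir, config$width,
                           config$height, pitch, step = config$step)
  axis <- if (identical(config$axis, "auto"))
    chooseAxis(rays[[1]]@direction) else config$axis
  nch <- ncol(tf@color)

  pre <- identical(config$classify, "pre")
  if (pre) {
    cls <- applyTransfer(tf, as.numeric(volume@values))
    opacVol <- scalarVolume(array(cls$opacity, dim(volume@values)),
                            volume@spacing)
    colorVols <- lapply(seq_len(nch), function(ch)
      scalarVolume(array(cls$color[, ch], dim(volume@values)),
                   volume@spacing))
  }

  img <- array(0, dim = c(config$height, config$width, nch))
  nHit <- 0L
  nSamples <- 0L
  idx <- 1L
  for (py in seq_len(config$height)) {
    for (px in seq_len(config$width)) {
      r <- rays[[idx]]
      idx <- idx + 1L
      seg <- clipToVolume(r, volume)
      if (is.null(seg)) next
      ts <- samplePositions(seg, r)
      nHit <- nHit + 1L
      nSamples <- nSamples + length(ts)
      useTrilinear <- config$sampler == "traditional"
      if (!useTrilinear) {
        inter <- planeIntersections(r, volume, axis)
        # a boundary-grazing segment crossing < 2 cluster planes cannot be
        # bracketed; fall back to the exact baseline for that ray
        if (nrow(inter) < 2L) useTrilinear <- TRUE
      }
      if (useTrilinear) {
        pts <- cbind(r@origin[1] + ts * r@direction[1],
                     r@origin[2] + ts * r@direction[2],
                     r@origin[3] + ts * r@direction[3])
        if (pre) {
          opac <- trilinearSample(opacVol, pts)
          colr <- vapply(colorVols, trilinearSample, numeric(length(ts)),
                         points = pts)
        } else {
          cls <- applyTransfer(tf, trilinearSample(volume, pts))
          opac <- cls$opacity
          colr <- cls$color
        }
      } else {
        if (pre) {
          opac <- .planeSamplePositions(ts, inter$t,
                                        faceInterpolate(opacVol, inter, axis))
          colr <- vapply(colorVols, function(cv)
            .planeSamplePositions(ts, inter$t,
                                  faceInterpolate(cv, inter, axis)),
            numeric(length(ts)))
        } else {
          cls <- applyTransfer(tf,
            .planeSamplePositions(ts, inter$t,
                                  faceInterpolate(volume, inter, axis)))
          opac <- cls$opacity
          colr <- cls$color
        }
      }
      colr <- matrix(colr, ncol = nch)
      ok <- !is.na(opac)
      opac <- pmin(pmax(opac[ok], 0), 1)
      colr <- colr[ok, , drop = FALSE]
      if (config$backToFront) {
        opac <- rev(opac)
        colr <- colr[rev(seq_len(nrow(colr))), , drop = FALSE]
      }
      img[py, px, ] <- compositeSamples(colr, opac,
                                        earlyTermination = config$earlyTermination)
    }
  }
  if (nch == 1L) img <- img[, , 1]
  list(image = img,
       log = list(sampler = config$sampler, axis = axis, step = config$step,
                  pixelPitch = pitch, raysHit = nHit,
                  samplesTaken = nSamples, config = unclass(config)))
}

#' Render with both samplers and compare
#'
#' Renders the same volume and configuration with the traditional trilinear
#' backend and the plane-cluster backend and reports the normalized RMSE
#' between the two images (RMSE divided by the dynamic range of the
#' trilinear reference image).
#'
#' @inheritParams renderVolume
#' @return A list with \code{traditional} and \code{plane} (the two render
#'   results) and \code{nrmse}.
#' @export
compareSamplers <- function(volume, tf, config = renderConfig()) {
  cfgA <- config; cfgA$sampler <- "traditional"
  cfgB <- config; cfgB$sampler <- "plane"
  a <- renderVolume(volume, tf, cfgA)
  b <- renderVolume(volume, tf, cfgB)
  list(traditional = a, plane = b,
       nrmse = imageNRMSE(a$image, b$image))
}

#' Normalized RMSE between two images
#'
#' Root-mean-square difference divided by the dynamic range of the reference
#' (first) image. Identical constant images give 0.
#'
#' @param reference,image numeric arrays of identical dimensions.
#' @return numeric(1).
#' @export
imageNRMSE <- function(reference, image) {
  stopifnot(identical(dim(reference), dim(image)))
  rmse <- sqrt(mean((reference - image)^2))
  rng <- diff(range(reference))
  if (rng == 0) {
    if (rmse == 0) 0 else Inf
  } else rmse / rng
}
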