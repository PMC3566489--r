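#' Front-to-back opacity compositing
#'
#' Accumulates sampled colors into the output pixel color as
#' \deqn{c_{out} = \sum_{i=0}^{n-1} c_i \prod_{j=0}^{i-1} (1 - a_j)
#'   = c_0 + c_1 (1 - a_0) + c_2 (1 - a_1)(1 - a_0) + \cdots,}
#' a single pass with an accumulated transparency product. Index 0 is the
#' viewer-nearest sample (its weight is the empty product, 1). The empty
#' sequence composites to 0. No opacity correction for the sampling distance
#' is applied, so changing the step changes brightness; the optional early
#' termination stops once accumulated transparency drops below 1e-4 and is
#' OFF by default so the result matches the literal sum exactly.
#'
#' @param color numeric vector (one channel) or n x C matrix of per-sample
#'   colors, viewer-nearest first.
#' @param opacity numeric vector of per-sample opacities in [0, 1].
#' @param earlyTermination logical; stop compositing when the accumulated
#'   transparency is below 1e-4 (default FALSE).
#' @return numeric(C) composited color (numeric(1) for one channel).
#' @examples
#' compositeSamples(c(1, 1, 1), c(0.5, 0.5, 0.5))  # 1.75
#' @export
compositeSamples <- function(color, opacity, earlyTermination = FALSE) {
  color <- .asColorMatrix(color, length(opacity))
  if (any(opacity < 0 | opacity > 1) || anyNA(opacity))
    stop("opacity values must lie in [0, 1]")
  n <- length(opacity)
  if (n == 0L) return(numeric(ncol(color)))
  trans <- cumprod(1 - opacity)
  if (earlyTermination) {
    cut <- which(trans < 1e-4)
    if (length(cut)) {
      n <- cut[1]
      trans <- trans[seq_len(n)]
      color <- color[seq_len(n), , drop = FALSE]
    }
  }
  weights <- c(1, trans[-n])
  colSums(color * weights)
}

#' Literal double-loop compositing oracle
#'
#' The same contract as [compositeSamples()], evaluated as the literal
#' O(n^2) expansion: for each sample, recompute the transparency product of
#' everything in front of it. Kept as an independent cross-check of the fast
#' single-pass accumulation.
#'
#' @inheritParams compositeSamples
#' @return numeric(C) composited color.
#' @examples
#' compositeBruteforce(c(1, 1, 1), c(0.5, 0.5, 0.5))  # 1.75
#' @export
compositeBruteforce <- function(color, opacity) {
  color <- .asColorMatrix(color, length(opacity))
  if (any(opacity < 0 | opacity > 1) || anyNA(opacity))
    stop("opacity values must lie in [0, 1]")
  out <- numeric(ncol(color))
  for (i in seq_along(opacity)) {
    w <- 1
    for (j in seq_len(i - 1L)) w <- w * (1 - opacity[j])
    out <- out + color[i, ] * w
  }
  out
}

.asColorMatrix <- function(color, n) {
  if (is.null(dim(color))) color <- matrix(color, ncol = 1L)
  if (nrow(color) != n)
    stop("color must have one row per opacity value")
  color
}
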