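#' Generate a synthetic phantom volume
#'
#' Evaluates the phantom's defining function at every grid vertex
#' \code{(i dx, j dy, k dz)}. Analytic kinds satisfy their closed form at the
#' vertexes exactly; \code{head_like} is a deterministic composite controlled
#' by the spec's seed (identical specs produce bit-identical volumes). Gray
#' ranges roughly follow CT conventions (0--3000) so default transfer
#' functions are meaningful.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [ScalarVolume-class].
#' @examples
#' vol <- generatePhantom(phantomSpec("gaussian_blob", extents = c(16, 16, 16),
#'                                    spacing = c(1, 1, 1)))
#' @rdname generatePhantom
#' @export
setMethod("generatePhantom", "PhantomSpec", function(spec) {
  ext <- spec@extents
  sp <- spec@spacing
  x <- (seq_len(ext[1]) - 1) * sp[1]
  y <- (seq_len(ext[2]) - 1) * sp[2]
  z <- (seq_len(ext[3]) - 1) * sp[3]
  pts <- cbind(rep(x, times = ext[2] * ext[3]),
               rep(rep(y, each = ext[1]), times = ext[3]),
               rep(z, each = ext[1] * ext[2]))
  vals <- if (spec@kind == "head_like") .headLikeValues(spec, pts)
          else closedForm(spec, pts)
  scalarVolume(array(vals, dim = ext), spacing = sp)
})

#' Closed-form phantom value at arbitrary points
#'
#' Evaluates the defining function of an analytic phantom at arbitrary
#' (off-grid) world points -- the exactness oracle for the samplers. The
#' \code{head_like} kind has no closed form and is rejected.
#'
#' @param spec a [PhantomSpec-class] of an analytic kind.
#' @param points numeric(3) or n x 3 matrix of world points (mm).
#' @return numeric vector of phantom values.
#' @examples
#' spec <- phantomSpec("affine", params = list(intercept = 1, coef = c(2, 3, 5)))
#' closedForm(spec, c(0.5, 0.25, 0.75))  # 6.5
#' @rdname closedForm
#' @export
setMethod("closedForm", signature("PhantomSpec", "numeric"),
          function(spec, points) closedForm(spec, .asPointMatrix(points)))

#' @rdname closedForm
#' @export
setMethod("closedForm", signature("PhantomSpec", "matrix"),
          function(spec, points) {
  p <- spec@params
  x <- points[, 1]; y <- points[, 2]; z <- points[, 3]
  switch(spec@kind,
    constant = rep(.par(p, "value", 1000), nrow(points)),
    affine = {
      cf <- .par(p, "coef", c(1, 1, 1))
      .par(p, "intercept", 0) + cf[1] * x + cf[2] * y + cf[3] * z
    },
    trilinear = {
      cf <- .par(p, "coef", c(0, 0, 0, 0, 0, 0, 0, 1))
      cf[1] + cf[2] * x + cf[3] * y + cf[4] * z +
        cf[5] * x * y + cf[6] * y * z + cf[7] * x * z + cf[8] * x * y * z
    },
    sphere = {
      ctr <- .par(p, "center", .boxCenter(spec))
      r2 <- (x - ctr[1])^2 + (y - ctr[2])^2 + (z - ctr[3])^2
      ifelse(r2 <= .par(p, "radius", .defaultRadius(spec))^2,
             .par(p, "inside", 1000), .par(p, "outside", 0))
    },
    shell = {
      ctr <- .par(p, "center", .boxCenter(spec))
      r <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2 + (z - ctr[3])^2)
      rO <- .par(p, "rOuter", .defaultRadius(spec))
      rI <- .par(p, "rInner", 0.8 * rO)
      ifelse(r <= rI, .par(p, "interior", 50),
             ifelse(r <= rO, .par(p, "value", 2000),
                    .par(p, "outside", 0)))
    },
    gaussian_blob = {
      ctr <- .par(p, "center", .boxCenter(spec))
      sg <- .par(p, "sigma", .defaultRadius(spec) / 2)
      if (length(sg) == 1L) sg <- rep(sg, 3L)
      .par(p, "amplitude", 2000) *
        exp(-((x - ctr[1])^2 / (2 * sg[1]^2) +
              (y - ctr[2])^2 / (2 * sg[2]^2) +
              (z - ctr[3])^2 / (2 * sg[3]^2)))
    },
    stop(sprintf("phantom kind '%s' has no closed form", spec@kind)))
})

# Deterministic CT-like head: ellipsoidal bone shell around smooth soft
# tissue modulated by seeded Gaussian bumps.
.headLikeValues <- function(spec, pts) {
  p <- spec@params
  box <- (spec@extents - 1L) * spec@spacing
  ctr <- .par(p, "center", box / 2)
  semi <- .par(p, "semiaxes", 0.42 * box)
  shellFrac <- .par(p, "shellFrac", 0.88)
  bone <- .par(p, "bone", 2200)
  tissue <- .par(p, "tissue", 60)
  nBumps <- .par(p, "nBumps", 4L)
  u <- sqrt(((pts[, 1] - ctr[1]) / semi[1])^2 +
            ((pts[, 2] - ctr[2]) / semi[2])^2 +
            ((pts[, 3] - ctr[3]) / semi[3])^2)
  vals <- numeric(nrow(pts))
  vals[u <= 1] <- bone
  interior <- u <= shellFrac
  vals[interior] <- tissue
  if (nBumps > 0) {
    rng <- .seededRNG(spec@seed)
    for (b in seq_len(nBumps)) {
      bctr <- ctr + (rng() - 0.5) * semi * shellFrac
      bsig <- (0.1 + 0.2 * rng()) * min(box)
      bamp <- 100 + 300 * rng()[1]
      d2 <- (pts[, 1] - bctr[1])^2 + (pts[, 2] - bctr[2])^2 +
            (pts[, 3] - bctr[3])^2
      vals[interior] <- vals[interior] +
        bamp * exp(-d2[interior] / (2 * bsig[1]^2))
    }
  }
  vals
}

# Local RNG stream: leaves the global .Random.seed untouched.
.seededRNG <- function(seed) {
  state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    s
  })
  function(n = 3L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", state, globalenv())
    r <- stats::runif(n)
    state <<- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    r
  }
}

.par <- function(params, name, default)
  if (!is.null(params[[name]])) params[[name]] else default

.boxCenter <- function(spec) (spec@extents - 1L) * spec@spacing / 2

.defaultRadius <- function(spec)
  0.35 * min((spec@extents - 1L) * spec@spacing)
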