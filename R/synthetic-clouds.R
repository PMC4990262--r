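# 2-D pseudo-Gaussian cloud generator used to demonstrate consensus
# clustering on point data (and to stress plain K-means).

#' Specify a set of distorted 2-D Gaussian clouds
#'
#' Each cloud is a mixture of Gaussian components; mixing several displaced
#' or anisotropic components per cloud produces the elongated, bent,
#' "pseudo-Gaussian" shapes on which single K-means partitions fail while
#' the consensus over many K-means runs succeeds.
#'
#' @param clouds list with one entry per cloud; each entry is itself a list
#'   of components, each component a list with fields `mean` (length-2),
#'   `cov` (2 x 2 symmetric positive-definite) and `weight` (positive;
#'   weights are normalized within each cloud).
#' @param pointsPerCloud number of points drawn from every cloud.
#' @param seed integer RNG seed.
#' @return an object of class `CloudSpec` (validated list).
#' @export
cloudSpec <- function(clouds, pointsPerCloud = 200L, seed = 1L) {
  stopifnot(length(clouds) >= 1L, pointsPerCloud >= 1L)
  for (ci in seq_along(clouds)) {
    comps <- clouds[[ci]]
    stopifnot(length(comps) >= 1L)
    w <- vapply(comps, function(cp) cp$weight, numeric(1))
    if (any(w <= 0)) stop("component weights must be positive")
    for (cp in comps) {
      if (length(cp$mean) != 2L) stop("component means must be 2-D")
      S <- cp$cov
      if (!isTRUE(all.equal(S, t(S))) ||
          any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0))
        stop("every component covariance must be symmetric positive-definite")
    }
    # normalize weights to sum to one
    for (k in seq_along(comps)) comps[[k]]$weight <- w[k] / sum(w)
    clouds[[ci]] <- comps
  }
  structure(list(clouds = clouds,
                 pointsPerCloud = as.integer(pointsPerCloud),
                 seed = as.integer(seed)),
            class = "CloudSpec")
}

#' Default five-cloud layout
#'
#' A built-in configuration with five distorted clouds: two elongated
#' mixtures (one bent), one broad oblique cloud, and a close pair of
#' compact clouds. The geometry is chosen so that the clouds are separated
#' by clear density gaps (consensus clustering recovers them) while their
#' anisotropy and unequal spread defeat a single K-means run at K = 5.
#'
#' @param pointsPerCloud points per cloud (default 200).
#' @param seed RNG seed.
#' @return a `CloudSpec`
#' @export
defaultCloudSpec <- function(pointsPerCloud = 200L, seed = 1L) {
  rot <- function(theta) {
    matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  }
  covr <- function(sx, sy, theta = 0) {
    R <- rot(theta)
    R %*% diag(c(sx^2, sy^2)) %*% t(R)
  }
  clouds <- list(
    # long horizontal cloud built from three displaced components; its
    # tips lie closer to the oblique cloud's centroid than to its own, so
    # the generating partition is not even a stable K-means fixed point
    list(
      list(mean = c(-6.5, 0), cov = covr(1.4, 0.5), weight = 1),
      list(mean = c(0, 1), cov = covr(1.4, 0.5, 0.25), weight = 1),
      list(mean = c(6.5, 2), cov = covr(1.4, 0.55, 0.45), weight = 1)
    ),
    # bent (banana) cloud above it
    list(
      list(mean = c(-5, 14), cov = covr(1.26, 0.45, -0.5), weight = 1),
      list(mean = c(0, 15.5), cov = covr(1.26, 0.45), weight = 1),
      list(mean = c(5, 14), cov = covr(1.26, 0.45, 0.5), weight = 1)
    ),
    # oblique cloud on the right
    list(
      list(mean = c(14, 6), cov = covr(1.2, 0.6, 1.0), weight = 1)
    ),
    # compact pair in the lower right: cheap for K-means to merge, clearly
    # separated for a density-sensitive method
    list(
      list(mean = c(13, -6), cov = covr(0.5, 0.5), weight = 1)
    ),
    list(
      list(mean = c(17.2, -6), cov = covr(0.5, 0.5), weight = 1)
    )
  )
  cloudSpec(clouds, pointsPerCloud = pointsPerCloud, seed = seed)
}

#' Draw labelled points from a cloud specification
#'
#' @param spec a `CloudSpec` from [cloudSpec()].
#' @return list with `points` (n x 2 matrix) and `labels` (integer cloud id
#'   per point, 1-based); reproducible given the spec's seed.
#' @export
makeClouds <- function(spec) {
  stopifnot(inherits(spec, "CloudSpec"))
  withSeed(spec$seed, {
    pts <- list()
    labs <- list()
    for (ci in seq_along(spec$clouds)) {
      comps <- spec$clouds[[ci]]
      w <- vapply(comps, function(cp) cp$weight, numeric(1))
      comp <- sample.int(length(comps), spec$pointsPerCloud,
                         replace = TRUE, prob = w)
      x <- matrix(NA_real_, spec$pointsPerCloud, 2L)
      for (k in seq_along(comps)) {
        sel <- comp == k
        if (any(sel))
          x[sel, ] <- MASS::mvrnorm(sum(sel), comps[[k]]$mean,
                                    comps[[k]]$cov)
      }
      pts[[ci]] <- x
      labs[[ci]] <- rep.int(ci, spec$pointsPerCloud)
    }
    list(points = do.call(rbind, pts), labels = unlist(labs))
  })
}
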