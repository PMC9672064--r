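# Subject-bootstrap and voxel half-brain ensembles, and mean aggregation
# of member risk estimates.

# Evenly spread unit directions (spherical Fibonacci point set over the
# full sphere), then a seeded uniform random rotation.  Full-sphere
# coverage makes the half-space subsets jointly cover every voxel (no
# common negative half-space); the generic construction contains no exact
# antipodal pair, so no two members select complementary halves.
fibonacci_sphere <- function(m) {
  k <- seq_len(m)
  z <- (2 * k - 1) / m - 1
  phi <- 2 * pi * k * (sqrt(5) - 1) / 2
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

random_rotation <- function(seed) {
  with_seed(seed, {
    qr_d <- qr(matrix(rnorm(9), 3, 3))
    Q <- qr.Q(qr_d)
    Q <- Q %*% diag(sign(diag(qr.R(qr_d))))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  })
}

#' Build a half-brain voxel ensemble plan
#'
#' Generates `n_members` unit directions (a deterministic spherical
#' Fibonacci point set, rotated by a seed-derived random rotation) and,
#' for each, the subset of in-mask voxels lying on the non-negative side of
#' the plane through the mask centroid orthogonal to the direction
#' (boundary voxels with a zero dot product are assigned to the subset).
#'
#' @param mask logical 3-D array.
#' @param voxel_size_mm per-axis voxel sizes.
#' @param n_members number of members (default 18).
#' @param seed integer seed for the rotation.
#' @return class `"vx_half_brain_plan"`: `directions` (members x 3, mm
#'   space), `centroid`, and `subsets` (list of logical vectors over the
#'   in-mask voxels, in mask-flattening order).
#' @export
make_half_brain_plan <- function(mask, voxel_size_mm, n_members = 18,
                                 seed = 1) {
  if (n_members < 1) stop("n_members must be >= 1")
  idx <- which(mask)
  if (length(idx) == 0) stop("empty mask")
  coords <- arrayInd(idx, dim(mask))
  mm <- sweep(coords, 2, voxel_size_mm, "*")
  centroid <- colMeans(mm)
  dirs <- fibonacci_sphere(n_members) %*% t(random_rotation(seed))
  rel <- sweep(mm, 2, centroid)
  subsets <- lapply(seq_len(n_members), function(k) {
    drop(rel %*% dirs[k, ]) >= 0
  })
  if (length(idx) == 1) {
    vx_note("degenerate single-voxel mask: all subsets equal the mask")
    subsets <- lapply(subsets, function(s) rep(TRUE, 1))
  }
  structure(list(directions = dirs, centroid = centroid, subsets = subsets,
                 n_members = n_members, seed = as.integer(seed),
                 mask_dim = dim(mask)),
            class = "vx_half_brain_plan")
}

#' Aggregate ensemble member risk estimates
#'
#' Arithmetic mean of the member linear predictors per subject; the risk
#' group is high (HRR) iff the mean is strictly positive (ties at 0 go to
#' the low-risk group).
#'
#' @param member_lp matrix of linear predictors, subjects x members (or a
#'   list of equal-length member vectors).
#' @return class `"vx_risk_estimate"`: `lp` (mean), `member_lp`,
#'   `risk_group` (factor low/HRR).
#' @export
aggregate_members <- function(member_lp) {
  if (is.list(member_lp)) {
    lens <- lengths(member_lp)
    if (length(member_lp) == 0) stop("empty member list")
    if (length(unique(lens)) != 1) stop("member lengths differ")
    member_lp <- do.call(cbind, member_lp)
  }
  member_lp <- as.matrix(member_lp)
  if (ncol(member_lp) == 0) stop("empty member list")
  lp <- rowMeans(member_lp)
  structure(list(lp = lp, member_lp = member_lp,
                 risk_group = factor(lp > 0, c(FALSE, TRUE),
                                     c("low", "HRR"))),
            class = "vx_risk_estimate")
}

#' @export
print.vx_risk_estimate <- function(x, ...) {
  cat("Risk estimates for", length(x$lp), "subjects (",
      ncol(x$member_lp), "members ):", sum(x$risk_group == "HRR"),
      "HRR /", sum(x$risk_group == "low"), "low\n")
  invisible(x)
}
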