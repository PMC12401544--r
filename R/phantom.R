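#' Specification of a synthetic neurite phantom
#'
#' Describes a 3D block containing tubular neurites of fixed radius, with a
#' requested number of crossing pairs (two centerlines intersecting) and
#' closely parallel pairs (centerlines at distance `2 * radius + parallel_gap`
#' over a corridor of at least 30 voxels, splaying apart at the ends).
#' Remaining neurites are smooth random walks kept at least `min_separation`
#' voxels from all other neurites, emulating dense but distinct axons.
#'
#' @param shape voxel extent `(nx, ny, nz)`.
#' @param n_neurites total number of neurites.
#' @param neurite_radius tube radius in voxels.
#' @param curvature_scale maximum turn per 1-voxel step (radians).
#' @param n_crossings number of crossing pairs (uses 2 neurites each).
#' @param n_parallel_pairs number of parallel pairs (2 neurites each).
#' @param parallel_gap extra centerline gap beyond `2 * neurite_radius`
#'   (voxels); used when `parallel_gaps` is not given.
#' @param crossing_angles optional vector of crossing angles in degrees,
#'   recycled over crossing pairs; sampled in `[30, 90]` when `NULL`.
#' @param parallel_gaps optional vector of per-pair gaps (voxels).
#' @param foreground_intensity tube voxel intensity (8-bit scale).
#' @param target_snr target SNR in dB for [add_background_noise()]; `NA`
#'   leaves the volume noise-free.
#' @param min_separation minimum distance between non-paired neurites.
#' @param rng_seed integer seed; the phantom is a pure function of the spec.
#' @param offset global block offset `(x, y, z)`.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128, 128), n_neurites = 2,
                         neurite_radius = 3, curvature_scale = 0.12,
                         n_crossings = 0, n_parallel_pairs = 0,
                         parallel_gap = 1, crossing_angles = NULL,
                         parallel_gaps = NULL, foreground_intensity = 200,
                         target_snr = NA, min_separation = 8,
                         rng_seed = 1, offset = c(0L, 0L, 0L)) {
  if (neurite_radius <= 0) stop("neurite_radius must be > 0")
  if (parallel_gap < 0) stop("parallel_gap must be >= 0")
  if (!is.na(target_snr) && !is.finite(target_snr)) {
    stop("target_snr must be finite (or NA for a clean volume)")
  }
  if (2 * (n_crossings + n_parallel_pairs) > n_neurites) {
    stop("configured pairs need more neurites than requested")
  }
  structure(list(shape = shape, n_neurites = n_neurites,
                 neurite_radius = neurite_radius,
                 curvature_scale = curvature_scale,
                 n_crossings = n_crossings,
                 n_parallel_pairs = n_parallel_pairs,
                 parallel_gap = parallel_gap,
                 crossing_angles = crossing_angles,
                 parallel_gaps = parallel_gaps,
                 foreground_intensity = foreground_intensity,
                 target_snr = target_snr, min_separation = min_separation,
                 rng_seed = rng_seed, offset = as.integer(offset)),
            class = "phantom_spec")
}

# Run `expr` under a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_unit <- function() {
  repeat {
    v <- rnorm(3)
    n <- vnorm(v)
    if (n > 1e-8) return(v / n)
  }
}

# unit vector perpendicular to u
random_perp <- function(u) {
  repeat {
    w <- random_unit()
    w <- w - sum(w * u) * u
    n <- vnorm(w)
    if (n > 1e-6) return(w / n)
  }
}

rotate_towards <- function(dir, target, max_angle) {
  cosang <- max(-1, min(1, sum(dir * target)))
  ang <- acos(cosang)
  if (ang <= max_angle) return(target)
  # slerp by max_angle toward target
  perp <- target - cosang * dir
  n <- vnorm(perp)
  if (n < 1e-9) return(dir)
  dir * cos(max_angle) + (perp / n) * sin(max_angle)
}

# Smooth random-walk centerline with bounded per-step turn.  By default the
# walk is steered away from the block boundary; with `stop_at_boundary` it
# terminates there instead (an axon leaving the imaged block).
random_walk_curve <- function(start, dir, len, curvature, shape, margin,
                              stop_at_boundary = FALSE) {
  pts <- matrix(0, nrow = len + 1, ncol = 3)
  pts[1, ] <- start
  p <- start
  lo <- rep(margin, 3)
  hi <- shape - 1 - margin
  center <- (lo + hi) / 2
  for (s in seq_len(len)) {
    ang <- runif(1, 0, curvature)
    axis <- random_perp(dir)
    cand <- unitize(dir * cos(ang) + axis * sin(ang))
    nxt <- p + cand
    if (any(nxt < lo) || any(nxt > hi)) {
      if (stop_at_boundary) break
      # steer back toward the interior when close to the boundary
      back <- unitize(center - p)
      cand <- unitize(rotate_towards(dir, back, 6 * curvature))
      nxt <- p + cand
      if (any(nxt < lo) || any(nxt > hi)) break
    }
    dir <- cand
    p <- nxt
    pts[s + 1, ] <- p
  }
  used <- which(rowSums(abs(pts)) > 0 | seq_len(nrow(pts)) == 1)
  pts[seq_len(max(used)), , drop = FALSE]
}

straightish_curve <- function(center, dir, half_len, curvature, shape, margin) {
  fw <- random_walk_curve(center, dir, half_len, curvature, shape, margin)
  bw <- random_walk_curve(center, -dir, half_len, curvature, shape, margin)
  rbind(bw[rev(seq_len(nrow(bw))), , drop = FALSE][-nrow(bw), , drop = FALSE],
        fw)
}

min_dist_to_set <- function(pts, ref, cap) {
  if (is.null(ref) || nrow(ref) == 0) return(Inf)
  min(cpp_nn_within(pts, ref, cap)$dist)
}

#' Generate a synthetic neurite phantom
#'
#' Produces a clean intensity volume (tube voxels at
#' `spec$foreground_intensity`, background 0) and the ground-truth skeleton in
#' global coordinates, interpolated to at most 1-voxel point spacing.  When
#' `spec$target_snr` is finite, background noise is added with
#' [add_background_noise()].
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `volume` (a [voxel_volume()]) and `skeleton`
#'   (a `gt_skeleton`: list of per-neurite polylines in global coordinates).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  r <- spec$neurite_radius
  margin <- max(ceiling(2 * r), 6)
  if (any(shape < 4 * margin)) {
    stop("block shape ", paste(shape, collapse = "x"),
         " too small to host the requested configuration")
  }
  curves <- with_seed(spec$rng_seed, {
    out <- list()
    occupied <- NULL
    add_pair <- function(a, b) {
      out[[length(out) + 1]] <<- a
      out[[length(out) + 1]] <<- b
      occupied <<- rbind(occupied, a, b)
    }
    lo <- rep(margin, 3)
    hi <- shape - 1 - margin
    mid <- (lo + hi) / 2
    span <- min(hi - lo)
    half <- floor(span / 2) - 2

    # a pair is accepted only when both curves stay min_separation away from
    # every previously placed neurite (the two curves of one pair may touch)
    place_pair <- function(make) {
      for (try in seq_len(40)) {
        pair <- make()
        if (is.null(pair)) next
        if (nrow(pair[[1]]) < 25 || nrow(pair[[2]]) < 25) next
        both <- rbind(pair[[1]], pair[[2]])
        if (min_dist_to_set(both, occupied, spec$min_separation) >
            spec$min_separation) {
          add_pair(pair[[1]], pair[[2]])
          return(invisible(TRUE))
        }
      }
      stop("block too crowded: could not place a configured pair at ",
           "separation ", spec$min_separation)
    }

    # crossing pairs
    angs <- spec$crossing_angles %||% runif(max(spec$n_crossings, 1), 30, 90)
    for (k in seq_len(spec$n_crossings)) {
      ang <- angs[((k - 1) %% length(angs)) + 1] * pi / 180
      place_pair(function() {
        cpt <- c(runif(1, lo[1] + span / 4, hi[1] - span / 4),
                 runif(1, lo[2] + span / 4, hi[2] - span / 4),
                 runif(1, lo[3] + span / 4, hi[3] - span / 4))
        u1 <- random_unit()
        u2 <- cos(ang) * u1 + sin(ang) * random_perp(u1)
        list(straightish_curve(cpt, u1, half, spec$curvature_scale / 3,
                               shape, margin),
             straightish_curve(cpt, u2, half, spec$curvature_scale / 3,
                               shape, margin))
      })
    }

    # closely parallel pairs: corridor at gap, splayed ends
    gaps <- spec$parallel_gaps %||% rep(spec$parallel_gap,
                                        max(spec$n_parallel_pairs, 1))
    for (k in seq_len(spec$n_parallel_pairs)) {
      gap <- gaps[((k - 1) %% length(gaps)) + 1]
      place_pair(function() {
        u <- random_unit()
        w <- random_perp(u)
        cpt <- c(runif(1, lo[1] + span / 4, hi[1] - span / 4),
                 runif(1, lo[2] + span / 4, hi[2] - span / 4),
                 runif(1, lo[3] + span / 4, hi[3] - span / 4))
        L <- 2 * half
        t <- seq(-L / 2, L / 2, by = 1)
        base <- cbind(cpt[1] + t * u[1], cpt[2] + t * u[2], cpt[3] + t * u[3])
        corridor <- 20  # half-length of the parallel corridor (>= 30 total)
        d0 <- 2 * r + gap
        extra <- pmin(12, pmax(0, abs(t) - corridor) * 0.6)
        off <- d0 + extra
        partner <- base + off * matrix(w, nrow = length(t), ncol = 3,
                                       byrow = TRUE)
        keep_a <- apply(base, 1, function(p) all(p >= lo & p <= hi))
        keep_b <- apply(partner, 1, function(p) all(p >= lo & p <= hi))
        list(base[keep_a, , drop = FALSE], partner[keep_b, , drop = FALSE])
      })
    }

    # free neurites traverse the block face to face, like passing axons;
    # rejected if closer than min_separation to existing neurites
    n_free <- spec$n_neurites - 2 * (spec$n_crossings + spec$n_parallel_pairs)
    for (k in seq_len(n_free)) {
      ok <- FALSE
      for (try in seq_len(60)) {
        axis <- sample(3, 1)
        side <- sample(c(0, 1), 1)
        start <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]),
                   runif(1, lo[3], hi[3]))
        start[axis] <- if (side == 0) lo[axis] else hi[axis]
        inward <- c(0, 0, 0)
        inward[axis] <- if (side == 0) 1 else -1
        dir <- unitize(inward + 0.6 * random_unit())
        if (sum(dir * inward) < 0.3) dir <- unitize(inward)
        cur <- random_walk_curve(start, dir, 3 * max(shape),
                                 spec$curvature_scale, shape, margin,
                                 stop_at_boundary = TRUE)
        if (nrow(cur) < max(30, min(shape) / 3)) next
        if (min_dist_to_set(cur, occupied, spec$min_separation) >
            spec$min_separation) {
          out[[length(out) + 1]] <- cur
          occupied <- rbind(occupied, cur)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("block too crowded: could not place free neurite ", k,
                    " at separation ", spec$min_separation)
    }
    out
  })

  polylines <- lapply(curves, function(cv) {
    p <- resample_polyline(cv, spacing = 1)
    sweep(p, 2, as.numeric(spec$offset), "+")  # global frame
  })
  skeleton <- gt_skeleton(polylines)

  dims <- rev(shape)  # (nz, ny, nx)
  local_pts <- do.call(rbind, lapply(polylines, function(p) {
    sweep(p, 2, as.numeric(spec$offset), "-")
  }))
  d <- cpp_dist_field(as.integer(dims), local_pts, r)
  arr <- array(0, dim = dims)
  arr[is.finite(d) & d <= r] <- spec$foreground_intensity
  vol <- voxel_volume(arr, offset = spec$offset)

  if (!is.na(spec$target_snr)) {
    vol <- add_background_noise(vol, skeleton, spec$target_snr,
                                rng_seed = spec$rng_seed + 1L)
  }
  list(volume = vol, skeleton = skeleton)
}

#' Ground-truth skeleton container
#'
#' @param polylines list of numeric matrices (3 columns, global x/y/z),
#'   each a neurite centerline at <= 1-voxel point spacing.
#' @param ids optional neurite identifiers.
#' @return an object of class `gt_skeleton`.
#' @export
gt_skeleton <- function(polylines, ids = seq_along(polylines)) {
  structure(list(polylines = polylines, ids = ids), class = "gt_skeleton")
}

#' @export
print.gt_skeleton <- function(x, ...) {
  cat(sprintf("<gt_skeleton: %d neurites, %d points>\n",
              length(x$polylines),
              sum(vapply(x$polylines, nrow, integer(1)))))
  invisible(x)
}

all_skeleton_points <- function(skeleton) {
  do.call(rbind, skeleton$polylines)
}

#' Add background noise calibrated to a target SNR
#'
#' Adds zero-mean Gaussian background noise plus sparse low-amplitude salt
#' spots, with the noise scale solved by bisection so that [compute_snr()] on
#' the result matches `target_snr` within 0.5 dB.  Values are clipped to the
#' 8-bit range.
#'
#' @param volume a clean [voxel_volume()].
#' @param skeleton the phantom's `gt_skeleton` (defines the SNR masks).
#' @param target_snr target SNR in dB (must be finite).
#' @param rng_seed integer seed for the noise draw.
#' @return a noisy [voxel_volume()].
#' @export
add_background_noise <- function(volume, skeleton, target_snr, rng_seed = 1) {
  if (!is.finite(target_snr)) stop("target_snr must be finite")
  masks <- snr_masks(volume, skeleton)
  if (length(masks$fg) == 0) stop("empty foreground: SNR undefined")
  nvox <- length(volume$data)
  noise <- with_seed(rng_seed, {
    base <- rnorm(nvox)
    salt <- (runif(nvox) < 5e-4) * runif(nvox, 1, 2)
    base + salt * 2
  })
  snr_at <- function(sigma) {
    v <- pmin(255, pmax(0, volume$data + sigma * noise))
    snr_from_masks(v, masks)
  }
  lo <- 1e-4
  hi <- 1
  while (snr_at(hi) > target_snr && hi < 2048) hi <- hi * 2
  if (snr_at(hi) > target_snr) {
    stop("target SNR unattainable at this foreground intensity")
  }
  if (snr_at(lo) < target_snr) {
    stop("volume background is already noisier than the target SNR")
  }
  for (it in seq_len(60)) {
    mid <- sqrt(lo * hi)
    if (snr_at(mid) > target_snr) lo <- mid else hi <- mid
    if (hi / lo < 1.0005) break
  }
  sigma <- sqrt(lo * hi)
  out <- volume
  out$data <- array(pmin(255, pmax(0, volume$data + sigma * noise)),
                    dim = dim(volume$data))
  out
}

#' Distance-field label volume from a ground-truth skeleton
#'
#' Voxels within `radius` of the (interpolated) skeleton hold
#' `exp(-d^2 / (2 sigma^2))` of the distance `d` to the nearest skeleton
#' point, normalized so the maximum is 1; all other voxels are 0.  This is the
#' supervision target a segmentation network would be trained on, and
#' thresholding it at 0.5 yields the foreground point set the reconstruction
#' consumes.
#'
#' @param skeleton a `gt_skeleton` in global coordinates.
#' @param shape block extent `(nx, ny, nz)`.
#' @param offset global block offset `(x, y, z)`.
#' @param radius candidate-region radius around skeleton points (voxels).
#' @param sigma Gaussian kernel width (voxels).
#' @return a [voxel_volume()] with values in `[0, 1]`.
#' @export
make_distance_field_labels <- function(skeleton, shape,
                                       offset = c(0L, 0L, 0L),
                                       radius = 5, sigma = 2) {
  dims <- rev(shape)
  pts <- all_skeleton_points(skeleton)
  if (is.null(pts) || nrow(pts) == 0) {
    return(voxel_volume(array(0, dim = dims), offset = offset))
  }
  local <- sweep(pts, 2, as.numeric(offset), "-")
  d <- cpp_dist_field(as.integer(dims), local, radius)
  field <- ifelse(is.finite(d), exp(-d^2 / (2 * sigma^2)), 0)
  mx <- max(field)
  if (mx > 0) field <- field / mx
  voxel_volume(array(field, dim = dims), offset = as.integer(offset))
}

#' Generate a synthetic smooth branch with a known root
#'
#' Builds a smooth neurite branch as a bounded-turn random walk (at most
#' `max_turn_deg` degrees per unit step) with 1-3 side branches splitting off
#' at moderate angles, the way an axonal arbor leaves a soma: the root is the
#' start of the trunk, and every path from it flows smoothly outward.  Used to
#' measure how often the information-flow minimum recovers the true root.
#'
#' @param n_steps trunk length in unit steps.
#' @param n_bifurcations number of side branches (1-3).
#' @param max_turn_deg per-step turn bound (degrees).
#' @param rng_seed integer seed.
#' @return a list with `tree` (a [neurite_tree()] rooted at the true root)
#'   and `root` (its node index, always 1).
#' @export
generate_branch_phantom <- function(n_steps = 80, n_bifurcations = 2,
                                    max_turn_deg = 20, rng_seed = 1) {
  stopifnot(n_bifurcations >= 1, n_bifurcations <= 3)
  with_seed(rng_seed, {
    turn <- max_turn_deg * pi / 180
    walk <- function(start, dir, len) {
      pts <- matrix(0, nrow = len, ncol = 3)
      p <- start
      for (s in seq_len(len)) {
        ang <- runif(1, 0, turn)
        axis <- random_perp(dir)
        dir <- unitize(dir * cos(ang) + axis * sin(ang))
        p <- p + dir
        pts[s, ] <- p
      }
      pts
    }
    trunk <- rbind(c(0, 0, 0), walk(c(0, 0, 0), random_unit(), n_steps))
    pos <- trunk
    parent <- c(0L, seq_len(n_steps))
    # side branches split off the trunk interior at 30-60 degrees
    at <- sort(sample(seq(10, n_steps - 10), n_bifurcations))
    for (a in at) {
      tdir <- unitize(trunk[a + 1, ] - trunk[a, ])
      ang <- runif(1, 30, 60) * pi / 180
      bdir <- unitize(tdir * cos(ang) + random_perp(tdir) * sin(ang))
      blen <- sample(20:40, 1)
      bp <- walk(trunk[a + 1, ], bdir, blen)
      first <- nrow(pos) + 1L
      pos <- rbind(pos, bp)
      parent <- c(parent, a + 1L, first + seq_len(blen - 1L) - 1L)
    }
    n <- nrow(pos)
    head <- as.integer(parent)
    left <- right <- integer(n)
    for (i in seq_len(n)) {
      if (head[i] == 0) next
      h <- head[i]
      if (left[h] == 0) left[h] <- i else right[h] <- i
    }
    list(tree = neurite_tree(pos, head, left, right), root = 1L)
  })
}
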