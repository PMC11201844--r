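# Shared fixtures, memoised so expensive phantom builds and pipeline runs
# happen once per test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small paired phantom used by segmentation/matching/pipeline unit tests
small_phantom <- function() {
  memo("small_phantom", generate_phantom(small_phantom_spec()))
}

small_phantom_spec <- function(...) {
  args <- utils::modifyList(list(seed = 7L, dims = c(120L, 120L, 120L),
                                 tumor_center = c(60, 41, 87), tumor_radius = 6,
                                 resection_offset_mm = 7, wedge_halfwidth_mm = 14,
                                 collapse_amplitude_mm = 3.5),
                            list(...))
  do.call(phantom_spec, args)
}

# small phantom without surgery: ideal for matching self-tests
intact_phantom <- function() {
  memo("intact_phantom",
       generate_phantom(small_phantom_spec(resection_offset_mm = NA,
                                           warp_amplitude_mm = 0,
                                           collapse_amplitude_mm = 0)))
}

# full-size phantom and pipeline run shared between the acceptance checks
# and the feature-point yield test
full_phantom <- function() {
  memo("full_phantom", generate_phantom(phantom_spec()))
}

full_pipeline_run <- function() {
  memo("full_pipeline_run", {
    ph <- full_phantom()
    lm <- bifurcation_landmarks(ph, 20)
    seedvox <- round(world_to_voxel(ph$pre, matrix(ph$spec$tumor_center, 1)))[1, ]
    run_pipeline(ph$pre, ph$post, tumor_seed = seedvox, landmarks = lm,
                 verbose = FALSE)
  })
}

# solid box mask helper
box_mask <- function(dims, lo, hi, spacing = c(1, 1, 1)) {
  a <- array(FALSE, dims)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  binary_mask(a, spacing)
}

# ellipsoidal mask helper
ellipsoid_fixture <- function(dims, center, semi, spacing = c(1, 1, 1)) {
  z <- (seq_len(dims[1]) - 1) - center[1]
  y <- (seq_len(dims[2]) - 1) - center[2]
  x <- (seq_len(dims[3]) - 1) - center[3]
  m <- outer(outer((z / semi[1])^2, (y / semi[2])^2, "+"), (x / semi[3])^2, "+") < 1
  binary_mask(m, spacing)
}

# solid axis-aligned tube along z
tube_mask <- function(dims, center_yx, radius, z_range, spacing = c(1, 1, 1)) {
  a <- array(FALSE, dims)
  for (z in z_range[1]:z_range[2]) {
    for (y in seq_len(dims[2])) {
      for (x in seq_len(dims[3])) {
        if ((y - center_yx[1])^2 + (x - center_yx[2])^2 <= radius^2) a[z, y, x] <- TRUE
      }
    }
  }
  binary_mask(a, spacing)
}

# random blob masks for brute-force Dice comparisons
random_mask <- function(dims, p, spacing = c(1, 1, 1)) {
  binary_mask(array(stats::runif(prod(dims)) < p, dims), spacing)
}

# manual feature point set constructor
fps_fixture <- function(post, pre, src = NULL) {
  structure(list(post_points = post, pre_points = pre,
                 source_tree = src %||% rep("t", nrow(post))),
            class = "feature_point_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# dense skeleton-like point cloud on a bent polyline (for CPD tests)
polyline_points <- function(vertices, step = 0.5) {
  pts <- list()
  for (i in seq_len(nrow(vertices) - 1)) {
    a <- vertices[i, ]; b <- vertices[i + 1, ]
    L <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, by = step / L)
    pts[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
                      a[3] + t * (b[3] - a[3]))
  }
  unique(do.call(rbind, pts))
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

# 26-connected component count helper (thin wrapper over the compiled core)
cpp_label_wrap <- function(arr) {
  resectmargin:::cpp_label(as.logical(arr), dim(arr), 26L)
}

# shared two-regime displacement fixture (resection-plane analogue)
two_regime_fixture <- function() {
  memo("two_regime", {
    dims <- c(80L, 80L, 80L)
    lungish <- box_mask(dims, c(11, 11, 11), c(70, 70, 70))
    tumor <- binary_mask(array(FALSE, dims))
    for (z in 36:44) for (y in 36:44) for (x in 36:44)
      if ((z - 40)^2 + (y - 40)^2 + (x - 40)^2 <= 16) tumor$data[z, y, x] <- TRUE
    set.seed(64)
    nA <- 220; nB <- 220
    postA <- cbind(runif(nA, 12, 68), runif(nA, 12, 68), runif(nA, 12, 28))
    postB <- cbind(runif(nB, 12, 68), runif(nB, 12, 68), runif(nB, 50, 68))
    disp <- rbind(matrix(0, nA, 3),
                  matrix(rep(c(0, 0, 6), each = nB), nB, 3))
    fps <- fps_fixture(rbind(postA, postB), rbind(postA, postB) + disp)
    list(lung = lungish, tumor = tumor, fps = fps, jumpsize = 6)
  })
}
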