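#' Rigid coherent point drift
#'
#' Aligns `moving` to `fixed` with a similarity transform (rotation,
#' translation, isotropic scale) by EM over a Gaussian mixture whose
#' centroids are the transformed moving points, with a uniform outlier
#' component of weight `w`. Iterations stop when the change in the mixture
#' variance falls below `tol` or after `max_iter` iterations. Point clouds
#' are normalized to zero mean and unit scale internally.
#'
#' @param moving,fixed Numeric matrices (n x 3) of points in mm; at least 4
#'   points each.
#' @param w Uniform outlier weight in \[0, 1).
#' @param max_iter,tol EM stopping controls.
#' @return List with `rotation` (3x3), `translation` (length 3), `scale`,
#'   `sigma2`, `iterations`, and `degenerate` (TRUE when the point sets are
#'   collinear and the fit is a best-effort).
#' @export
rigid_cpd <- function(moving, fixed, w = 0.1, max_iter = 100, tol = 1e-8) {
  Y0 <- as.matrix(moving); X0 <- as.matrix(fixed)
  if (nrow(Y0) < 4 || nrow(X0) < 4) stop("rigid_cpd: need at least 4 points in each set")
  degenerate <- min(svd(scale(Y0, scale = FALSE))$d) < 1e-8 * max(svd(scale(Y0, scale = FALSE))$d)
  if (degenerate) warning("rigid_cpd: moving points are (near-)collinear; fit is degenerate")

  mux0 <- colMeans(X0); muy0 <- colMeans(Y0)
  Xc <- sweep(X0, 2, mux0); Yc <- sweep(Y0, 2, muy0)
  sx <- sqrt(sum(Xc^2) / nrow(Xc)); sy <- sqrt(sum(Yc^2) / nrow(Yc))
  if (sx < 1e-12 || sy < 1e-12) stop("rigid_cpd: degenerate (zero-extent) point set")
  X <- Xc / sx; Y <- Yc / sy
  N <- nrow(X); M <- nrow(Y); D <- 3

  R <- diag(3); s <- 1; tt <- rep(0, 3)
  TY <- Y
  sigma2 <- sum(outer(rowSums(X^2), rep(1, M)) + outer(rep(1, N), rowSums(Y^2)) -
                  2 * X %*% t(Y)) / (D * N * M)
  iter <- 0
  repeat {
    iter <- iter + 1
    # E-step
    d2 <- outer(rowSums(TY^2), rep(1, N)) + outer(rep(1, M), rowSums(X^2)) -
      2 * TY %*% t(X)                                  # M x N
    K <- exp(-d2 / (2 * sigma2))
    cst <- (2 * pi * sigma2)^(D / 2) * w / (1 - w) * M / N
    den <- colSums(K) + cst
    P <- sweep(K, 2, pmax(den, 1e-300), "/")
    Pt1 <- colSums(P); P1 <- rowSums(P)
    Np <- sum(P1)
    if (Np < 1e-12) break
    # M-step (similarity transform)
    mux <- as.numeric(t(X) %*% Pt1) / Np
    muy <- as.numeric(t(Y) %*% P1) / Np
    Xh <- sweep(X, 2, mux); Yh <- sweep(Y, 2, muy)
    A <- t(Xh) %*% t(P) %*% Yh
    sv <- svd(A)
    C <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))
    R <- sv$u %*% C %*% t(sv$v)
    denom <- sum(rowSums(P) * rowSums(Yh^2))
    s <- sum(diag(diag(sv$d) %*% C)) / denom
    tt <- mux - s * as.numeric(R %*% muy)
    TY <- s * Y %*% t(R) + matrix(tt, M, 3, byrow = TRUE)
    sigma2_new <- (sum(colSums(P) * rowSums(Xh^2)) - s * sum(diag(diag(sv$d) %*% C))) / (Np * D)
    if (sigma2_new <= 0) sigma2_new <- tol / 10
    if (abs(sigma2 - sigma2_new) < tol || iter >= max_iter) { sigma2 <- sigma2_new; break }
    sigma2 <- sigma2_new
  }

  # denormalize: x = sx * (s R (y - muy0)/sy + t) + mux0
  scale_full <- s * sx / sy
  trans_full <- as.numeric(sx * tt + mux0 - scale_full * R %*% muy0)
  list(rotation = R, translation = trans_full, scale = scale_full,
       sigma2 = sigma2, iterations = iter, degenerate = degenerate)
}

#' Apply a rigid CPD result to points
#' @param pts n x 3 matrix (mm).
#' @param fit Result of [rigid_cpd()].
#' @export
apply_rigid <- function(pts, fit) {
  pts <- as.matrix(pts)
  sweep(fit$scale * pts %*% t(fit$rotation), 2, fit$translation, "+")
}

#' Non-rigid coherent point drift
#'
#' Deforms `moving` toward `fixed` with the Gaussian-kernel motion-coherence
#' model (kernel width `beta`, regularization `lambda`, uniform outlier
#' weight `w`), run to convergence of the mixture variance. The
#' correspondence of each moving point is the fixed point with the highest
#' final posterior probability, and that row-normalized posterior maximum is
#' returned as a per-point confidence.
#'
#' @param moving,fixed Numeric matrices (n x 3), at least 5 points each.
#' @param beta Gaussian kernel width in units of the normalized point-cloud
#'   scale.
#' @param lambda Regularization weight.
#' @inheritParams rigid_cpd
#' @return List with `points` (displaced moving points, in fixed space),
#'   `correspondence` (index into `fixed` per moving point),
#'   `posterior_max`, `sigma2`, `iterations`, `degenerate`.
#' @export
nonrigid_cpd <- function(moving, fixed, beta = 2, lambda = 3, w = 0.1,
                         max_iter = 100, tol = 1e-8) {
  Y0 <- as.matrix(moving); X0 <- as.matrix(fixed)
  if (nrow(Y0) < 5 || nrow(X0) < 5) stop("nonrigid_cpd: need at least 5 points in each set")
  degenerate <- min(svd(scale(Y0, scale = FALSE))$d) < 1e-8 * max(svd(scale(Y0, scale = FALSE))$d)
  if (degenerate) warning("nonrigid_cpd: moving points are (near-)collinear; fit is degenerate")

  mux0 <- colMeans(X0); muy0 <- colMeans(Y0)
  Xc <- sweep(X0, 2, mux0); Yc <- sweep(Y0, 2, muy0)
  sx <- sqrt(sum(Xc^2) / nrow(Xc))
  if (sx < 1e-12) stop("nonrigid_cpd: degenerate (zero-extent) fixed set")
  X <- Xc / sx; Y <- Yc / sx     # common scale keeps displacements commensurate
  N <- nrow(X); M <- nrow(Y); D <- 3

  G <- exp(-as.matrix(stats::dist(Y))^2 / (2 * beta^2))
  W <- matrix(0, M, 3)
  TY <- Y
  sigma2 <- sum(outer(rowSums(X^2), rep(1, M)) + outer(rep(1, N), rowSums(Y^2)) -
                  2 * X %*% t(Y)) / (D * N * M)
  iter <- 0
  P <- NULL
  repeat {
    iter <- iter + 1
    d2 <- outer(rowSums(TY^2), rep(1, N)) + outer(rep(1, M), rowSums(X^2)) -
      2 * TY %*% t(X)
    K <- exp(-d2 / (2 * sigma2))
    cst <- (2 * pi * sigma2)^(D / 2) * w / (1 - w) * M / N
    den <- colSums(K) + cst
    P <- sweep(K, 2, pmax(den, 1e-300), "/")
    P1 <- rowSums(P); Np <- sum(P1)
    if (Np < 1e-12) break
    # M-step: (diag(P1) G + lambda sigma2 I) W = P X - diag(P1) Y
    LHS <- G * P1 + diag(lambda * sigma2, M)
    RHS <- P %*% X - Y * P1
    W <- solve(LHS, RHS)
    TY <- Y + G %*% W
    Pt1 <- colSums(P)
    sigma2_new <- (sum(Pt1 * rowSums(X^2)) - 2 * sum((t(P) %*% TY) * X) +
                     sum(P1 * rowSums(TY^2))) / (Np * D)
    if (sigma2_new <= 1e-12) { sigma2 <- max(sigma2_new, 1e-12); break }
    # relative change: the variance decays over many orders of magnitude
    if (abs(sigma2 - sigma2_new) < tol * sigma2_new || iter >= max_iter) {
      sigma2 <- sigma2_new
      break
    }
    sigma2 <- sigma2_new
  }

  # row-normalized posterior over fixed points (+ outlier mass); the
  # temperature is floored so a fully collapsed variance cannot underflow
  # the exponentials of near-exact matches
  s2p <- max(sigma2, 1e-6)
  d2 <- outer(rowSums(TY^2), rep(1, N)) + outer(rep(1, M), rowSums(X^2)) - 2 * TY %*% t(X)
  K <- exp(-d2 / (2 * s2p))
  cst <- (2 * pi * s2p)^(D / 2) * w / (1 - w) * M / N
  post <- K / pmax(rowSums(K) + cst, 1e-300)
  corr <- max.col(post, ties.method = "first")
  pmax_ <- post[cbind(seq_len(M), corr)]

  pts_out <- sweep(TY * sx, 2, mux0, "+")
  list(points = pts_out, correspondence = corr, posterior_max = pmax_,
       sigma2 = sigma2, iterations = iter, degenerate = degenerate)
}
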