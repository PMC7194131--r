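#' Tikhonov-regularized inverse reconstruction
#'
#' Solves the ill-posed inverse problem of electrocardiographic imaging:
#' given the transfer matrix `T` and body-surface potentials `y(t)`, find
#' heart-surface potentials
#' \deqn{\hat x_\lambda = \arg\min_x \|Tx - y\|_2^2 + \lambda^2 \|x\|_2^2,}
#' zero-order Tikhonov with identity weighting, applied column-wise over
#' time. The solution is computed from the singular value decomposition of
#' `T`, which is factorized once per call; by default one global lambda is
#' used for the whole beat (per-frame selection available via `per_frame`).
#'
#' @param transfer a `transfer_matrix` (or plain matrix).
#' @param y electrode potentials, `n_electrodes x n_time` (uV).
#' @param lambda regularization parameter; ignored when `method` is not
#'   `"fixed"`.
#' @param method `"fixed"`, `"lcurve"` or `"creso"`.
#' @param per_frame logical; select and apply lambda per time frame.
#' @return an `egm_set`: list with `egms` (`n_heart_nodes x n_time`, uV),
#'   `lambda_used`, `valid` (per-node mask, all `TRUE` here; quality control
#'   downstream may clear entries), `sampling_rate` and `time_ms` when the
#'   input carried them.
#' @export
tikhonov_solve <- function(transfer, y, lambda = NULL,
                           method = c("fixed", "lcurve", "creso"),
                           per_frame = FALSE) {
  method <- match.arg(method)
  A <- if (inherits(transfer, "transfer_matrix")) transfer$entries else
    as.matrix(transfer)
  y <- as.matrix(y)
  if (nrow(A) != nrow(y)) stop("electrode dimensions of `transfer` and `y` disagree")
  sv <- attr(transfer, "svd")
  if (is.null(sv)) sv <- svd(A)
  if (method == "fixed") {
    if (is.null(lambda)) stop("method 'fixed' requires an explicit `lambda`")
    if (lambda < 0) stop("`lambda` must be non-negative")
    if (lambda == 0 && min(sv$d) < 1e-12 * max(sv$d)) {
      stop("transfer matrix is rank deficient; use lambda > 0")
    }
    lam <- lambda
  } else {
    lam <- select_lambda(A, y, method = method, sv = sv,
                         per_frame = per_frame)
  }
  X <- tikhonov_apply(sv, y, lam, per_frame)
  structure(list(egms = X,
                 lambda_used = lam,
                 valid = rep(TRUE, ncol(A)),
                 sampling_rate = attr(y, "sampling_rate"),
                 time_ms = attr(y, "time_ms")),
            class = "egm_set")
}

# filter-factor application of the SVD solution
tikhonov_apply <- function(sv, y, lam, per_frame) {
  uty <- crossprod(sv$u, y)
  if (per_frame && length(lam) == ncol(y)) {
    Z <- vapply(seq_len(ncol(y)), function(j) {
      f <- sv$d / (sv$d^2 + lam[j]^2)
      as.vector(sv$v %*% (f * uty[, j]))
    }, numeric(nrow(sv$v)))
  } else {
    f <- sv$d / (sv$d^2 + lam[1L]^2)
    Z <- sv$v %*% (f * uty)
  }
  Z
}

#' @export
print.egm_set <- function(x, ...) {
  cat(sprintf("<egm_set> %d nodes x %d samples, lambda %s\n",
              nrow(x$egms), ncol(x$egms),
              paste(signif(unique(x$lambda_used), 3), collapse = "/")))
  invisible(x)
}

#' Automatic selection of the regularization parameter
#'
#' Two classical policies evaluated on a fixed 64-point logarithmic grid
#' spanning `[1e-6, 1] * sigma_max(T)`:
#' * `"lcurve"`: the maximum-curvature corner of the
#'   (log residual norm, log solution norm) curve;
#' * `"creso"`: the first local maximum of the derivative of
#'   `lambda^2 * ||x_lambda||^2` with respect to `lambda^2` (composite
#'   residual and smoothing operator criterion).
#'
#' When the criterion curve is degenerate (no interior corner or maximum)
#' the grid midpoint is returned with a warning.
#'
#' @param transfer transfer matrix (or `transfer_matrix` object).
#' @param y electrode potentials.
#' @param method `"lcurve"` or `"creso"`.
#' @param n_grid grid size.
#' @param sv optional pre-computed `svd(T)`.
#' @param per_frame select a separate lambda per column of `y`.
#' @return scalar lambda (or vector, when `per_frame`).
#' @export
select_lambda <- function(transfer, y, method = c("lcurve", "creso"),
                          n_grid = 64, sv = NULL, per_frame = FALSE) {
  method <- match.arg(method)
  A <- if (inherits(transfer, "transfer_matrix")) transfer$entries else
    as.matrix(transfer)
  if (is.null(sv)) sv <- svd(A)
  y <- as.matrix(y)
  grid <- max(sv$d) * 10^seq(-6, 0, length.out = n_grid)
  if (per_frame) {
    vapply(seq_len(ncol(y)), function(j) {
      pick_lambda(grid, sv, y[, j, drop = FALSE], method)
    }, 0)
  } else {
    pick_lambda(grid, sv, y, method)
  }
}

# criterion evaluation on the lambda grid; `y` may hold several time frames,
# whose singular-direction energies add
pick_lambda <- function(grid, sv, y, method) {
  UtY <- crossprod(sv$u, y)
  u2 <- rowSums(UtY^2)
  extra <- max(sum(y^2) - sum(UtY^2), 0)   # energy outside the range of T
  d <- sv$d
  if (method == "lcurve") {
    eta2 <- vapply(grid, function(l) sum(d^2 * u2 / (d^2 + l^2)^2), 0)
    rho2 <- vapply(grid, function(l) sum(l^4 * u2 / (d^2 + l^2)^2), 0) + extra
    # analytic first derivatives; curvature of (log rho, log eta)
    deta2 <- vapply(grid, function(l) -4 * l * sum(d^2 * u2 / (d^2 + l^2)^3), 0)
    drho2 <- -grid^2 * deta2
    u <- log(grid)
    xp <- drho2 / (2 * rho2) * grid           # d(log rho)/d(log lambda)
    yp <- deta2 / (2 * eta2) * grid
    xpp <- c(NA, diff(xp) / diff(u))
    ypp <- c(NA, diff(yp) / diff(u))
    kappa <- (xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
    kappa[!is.finite(kappa)] <- -Inf
    j <- which.max(kappa)
    if (!length(j) || !is.finite(kappa[j]) || kappa[j] <= 0) {
      warning("degenerate L-curve; falling back to the grid midpoint")
      return(grid[length(grid) %/% 2])
    }
    grid[j]
  } else {
    # CRESO: d/d(lambda^2) of lambda^2 * ||x_lambda||^2
    cres <- vapply(grid, function(l) {
      sum(d^2 * (d^2 - l^2) / (d^2 + l^2)^3 * u2)
    }, 0)
    j <- first_local_max(cres)
    if (is.na(j)) {
      # no interior maximum: use the sign change of the criterion
      flip <- which(cres[-1] <= 0 & cres[-length(cres)] > 0)
      if (length(flip)) return(grid[flip[1L]])
      warning("degenerate CRESO curve; falling back to the grid midpoint")
      return(grid[length(grid) %/% 2])
    }
    grid[j]
  }
}

first_local_max <- function(v) {
  n <- length(v)
  for (i in 2:(n - 1L)) {
    if (v[i] > v[i - 1L] && v[i] >= v[i + 1L]) return(i)
  }
  NA_integer_
}
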