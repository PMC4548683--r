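# Steady groundwater flow on a gridded 3-D domain with constant-head
# boundaries: 7-point finite differences with harmonic-mean interface
# conductivities, assembled sparse and solved directly. A minimal
# re-implementation of the standard block-centred flow machinery.

#' Gridded 3-D site model
#'
#' Regular block-centred grid: `ny` rows by `nx` columns by `nlayers`
#' layers, spacing `dx` by `dy` horizontally and per-layer `thickness`
#' vertically. Hydraulic conductivity may be scalar (homogeneous) or a full
#' `ny * nx * nlayers` array; the vertical conductivity defaults to
#' one-tenth of the horizontal, a standard anisotropy assumption. Boundary
#' conditions are constant-head cells (`fixed_head` non-`NA`); all external
#' faces are otherwise no-flow. The convenience arguments `head_west` /
#' `head_east` pin entire boundary columns, giving the gentle uniform
#' gradient typical of the modelled site.
#'
#' @param nx,ny Columns and rows; defaults give the 100 m x 100 m site at
#'   1 m quadratic mesh.
#' @param nlayers Number of layers (default 4).
#' @param dx,dy Horizontal cell size (m).
#' @param thickness Layer thicknesses (m), length `nlayers` (default 2 m
#'   each, spanning 0-8 m below ground).
#' @param hk Horizontal hydraulic conductivity (m/d), scalar or array.
#'   Default `10 * vk0` with `vk0 = 2.25e-7 m/s` the measured vertical
#'   conductivity of the aquifer soil.
#' @param vk Vertical conductivity (m/d), scalar or array; default `hk/10`.
#' @param porosity Effective porosity, scalar or array.
#' @param head_west,head_east Constant heads (m) applied to the full west
#'   (col 1) and east (col nx) boundary columns; set `NULL` to omit.
#' @param fixed_head Optional `ny * nx * nlayers` array, `NA` for free
#'   cells, head value (m) for constant-head cells. Overrides/extends the
#'   face arguments.
#' @return An object of class `site_model`.
#' @export
site_model <- function(nx = 100, ny = 100, nlayers = 4, dx = 1, dy = 1,
                       thickness = rep(2, nlayers),
                       hk = 2.25e-7 * 86400 * 10, vk = NULL,
                       porosity = 0.296,
                       head_west = 10.05, head_east = 10.00,
                       fixed_head = NULL) {
  stopifnot(nx >= 2, ny >= 1, nlayers >= 1, dx > 0, dy > 0,
            length(thickness) == nlayers, all(thickness > 0))
  dims <- c(ny, nx, nlayers)
  expand <- function(x, what) {
    if (length(x) == 1) x <- array(x, dims)
    if (!all(dim(x) == dims)) stop("site_model: bad dimensions for ", what)
    x
  }
  hk <- expand(hk, "hk")
  if (is.null(vk)) vk <- hk / 10 else vk <- expand(vk, "vk")
  porosity <- expand(porosity, "porosity")
  if (any(hk <= 0) || any(vk <= 0))
    stop("site_model: conductivities must be > 0")
  if (any(porosity <= 0) || any(porosity >= 1))
    stop("site_model: porosity must lie in (0, 1)")
  if (is.null(fixed_head)) fixed_head <- array(NA_real_, dims)
  if (!all(dim(fixed_head) == dims))
    stop("site_model: bad dimensions for fixed_head")
  if (!is.null(head_west)) fixed_head[, 1, ] <- head_west
  if (!is.null(head_east)) fixed_head[, nx, ] <- head_east
  if (!any(is.finite(fixed_head)))
    stop("site_model: at least one constant-head cell is required")
  structure(list(nx = nx, ny = ny, nlayers = nlayers, dx = dx, dy = dy,
                 thickness = thickness, hk = hk, vk = vk,
                 porosity = porosity, fixed_head = fixed_head),
            class = "site_model")
}

#' @method print site_model
#' @export
print.site_model <- function(x, ...) {
  cat(sprintf("Site model: %d x %d x %d cells (%g x %g m mesh, layers %s m)\n",
              x$ny, x$nx, x$nlayers, x$dx, x$dy,
              paste(x$thickness, collapse = "/")))
  cat(sprintf("  K_h %.3g..%.3g m/d, K_v %.3g..%.3g m/d, %d constant-head cells\n",
              min(x$hk), max(x$hk), min(x$vk), max(x$vk),
              sum(is.finite(x$fixed_head))))
  invisible(x)
}

#' Solve steady saturated groundwater flow on a site grid
#'
#' Finite-difference solution of `div(K grad h) = 0` with harmonic-mean
#' interface conductivities and constant-head cells as Dirichlet rows;
#' solved with a sparse direct factorisation. Face Darcy fluxes and
#' cell-centred pore velocities are derived from the head field.
#'
#' @param site A [site_model()].
#' @return An object of class `flow_solution`: `heads` (array, m), face
#'   Darcy fluxes `qx` (ny x (nx+1) x nl), `qy` ((ny+1) x nx x nl), `qz`
#'   (ny x nx x (nl+1)), all m/d positive in +col/+row/+layer direction,
#'   cell-centred pore velocities `vx`, `vy`, `vz` (m/d), the linear-solver
#'   `residual_norm` and the maximum interior mass-balance defect
#'   `divergence_max` (m^3/d).
#' @export
solve_steady_flow <- function(site) {
  stopifnot(inherits(site, "site_model"))
  ny <- site$ny; nx <- site$nx; nl <- site$nlayers
  dx <- site$dx; dy <- site$dy; dz <- site$thickness
  n <- ny * nx * nl
  idx <- function(i, j, k) (k - 1L) * ny * nx + (j - 1L) * ny + i

  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diag_acc <- numeric(n)
  harm <- function(a, b) 2 * a * b / (a + b)

  for (k in seq_len(nl)) {
    az <- dz[k]
    if (nx > 1) {
      for (j in seq_len(nx - 1)) {
        cond <- harm(site$hk[, j, k], site$hk[, j + 1, k]) * dy * az / dx
        ia <- idx(seq_len(ny), j, k); ib <- idx(seq_len(ny), j + 1, k)
        ii <- c(ii, ia, ib); jj <- c(jj, ib, ia); vv <- c(vv, cond, cond)
        diag_acc[ia] <- diag_acc[ia] - cond
        diag_acc[ib] <- diag_acc[ib] - cond
      }
    }
    if (ny > 1) {
      for (i in seq_len(ny - 1)) {
        cond <- harm(site$hk[i, , k], site$hk[i + 1, , k]) * dx * az / dy
        ia <- idx(i, seq_len(nx), k); ib <- idx(i + 1, seq_len(nx), k)
        ii <- c(ii, ia, ib); jj <- c(jj, ib, ia); vv <- c(vv, cond, cond)
        diag_acc[ia] <- diag_acc[ia] - cond
        diag_acc[ib] <- diag_acc[ib] - cond
      }
    }
  }
  if (nl > 1) {
    for (k in seq_len(nl - 1)) {
      dzf <- (dz[k] + dz[k + 1]) / 2
      cond <- harm(site$vk[, , k], site$vk[, , k + 1]) * dx * dy / dzf
      ia <- idx(rep(seq_len(ny), nx), rep(seq_len(nx), each = ny), k)
      ib <- idx(rep(seq_len(ny), nx), rep(seq_len(nx), each = ny), k + 1)
      ii <- c(ii, ia, ib); jj <- c(jj, ib, ia)
      vv <- c(vv, as.numeric(cond), as.numeric(cond))
      diag_acc[ia] <- diag_acc[ia] - as.numeric(cond)
      diag_acc[ib] <- diag_acc[ib] - as.numeric(cond)
    }
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(vv, diag_acc), dims = c(n, n))
  fixed <- which(is.finite(site$fixed_head))
  if (!length(fixed)) stop("solve_steady_flow: no constant-head cell ",
                           "(singular system)")
  hfix <- site$fixed_head[fixed]
  free <- setdiff(seq_len(n), fixed)
  h <- numeric(n)
  h[fixed] <- hfix
  if (length(free)) {
    Aff <- A[free, free, drop = FALSE]
    rhs <- -as.numeric(A[free, fixed, drop = FALSE] %*% hfix)
    hf <- as.numeric(Matrix::solve(Aff, rhs))
    h[free] <- hf
    residual_norm <- sqrt(sum((as.numeric(Aff %*% hf) - rhs)^2))
  } else {
    residual_norm <- 0
  }
  heads <- array(h, c(ny, nx, nl))

  # face Darcy fluxes, positive toward +j / +i / +k
  qx <- array(0, c(ny, nx + 1, nl))
  qy <- array(0, c(ny + 1, nx, nl))
  qz <- array(0, c(ny, nx, nl + 1))
  for (k in seq_len(nl)) {
    if (nx > 1) {
      Kf <- harm(site$hk[, -nx, k], site$hk[, -1, k])
      qx[, 2:nx, k] <- Kf * (heads[, -nx, k] - heads[, -1, k]) / dx
    }
    if (ny > 1) {
      Kf <- harm(site$hk[-ny, , k], site$hk[-1, , k])
      qy[2:ny, , k] <- Kf * (heads[-ny, , k] - heads[-1, , k]) / dy
    }
  }
  if (nl > 1) {
    for (k in seq_len(nl - 1)) {
      dzf <- (dz[k] + dz[k + 1]) / 2
      Kf <- harm(site$vk[, , k], site$vk[, , k + 1])
      qz[, , k + 1] <- Kf * (heads[, , k] - heads[, , k + 1]) / dzf
    }
  }

  # interior mass-balance defect (m^3/d) per free cell
  div <- array(0, c(ny, nx, nl))
  for (k in seq_len(nl)) {
    az <- dz[k]
    div[, , k] <- (qx[, 2:(nx + 1), k] - qx[, 1:nx, k]) * dy * az +
      (qy[2:(ny + 1), , k] - qy[1:ny, , k]) * dx * az +
      (qz[, , k + 1] - qz[, , k]) * dx * dy
  }
  div[fixed] <- 0
  vx <- array(qx[, 1:nx, , drop = FALSE] + qx[, 2:(nx + 1), , drop = FALSE],
              c(ny, nx, nl)) / 2 / site$porosity
  vy <- array(qy[1:ny, , , drop = FALSE] + qy[2:(ny + 1), , , drop = FALSE],
              c(ny, nx, nl)) / 2 / site$porosity
  vz <- array(qz[, , 1:nl, drop = FALSE] + qz[, , 2:(nl + 1), drop = FALSE],
              c(ny, nx, nl)) / 2 / site$porosity

  structure(list(heads = heads, qx = qx, qy = qy, qz = qz,
                 vx = vx, vy = vy, vz = vz,
                 residual_norm = residual_norm,
                 divergence_max = max(abs(div)),
                 fixed = fixed, site = site),
            class = "flow_solution")
}

#' @method print flow_solution
#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("Steady flow solution on %d x %d x %d grid\n",
              x$site$ny, x$site$nx, x$site$nlayers))
  cat(sprintf("  head range %.4g..%.4g m, solver residual %.2e, max cell defect %.2e m^3/d\n",
              min(x$heads), max(x$heads), x$residual_norm, x$divergence_max))
  cat(sprintf("  |v| up to %.3g m/d\n",
              max(sqrt(x$vx^2 + x$vy^2 + x$vz^2))))
  invisible(x)
}
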