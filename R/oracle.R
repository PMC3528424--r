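#' Numerical gradient-magnitude field (validation oracle)
#'
#' Independent check of the closed-form field expression: the field is, by
#' definition, the magnitude of the negative gradient of the scalar
#' potential, so a second-order central difference of [pair_potential()]
#' must converge to [pair_field()] at rate O(h^2) as the step shrinks.
#'
#' @param x,y Evaluation point (m); scalars.
#' @param pair An `nf_pair_geometry` with voltage set.
#' @param h Stencil step (m); a good default is `1e-6 * pair$d_AB`.
#' @return Field magnitude estimate (V/m).
#' @export
numeric_gradient_field <- function(x, y, pair, h = 1e-6 * pair$d_AB) {
  stopifnot(length(x) == 1L, length(y) == 1L, h > 0)
  Ex <- -(pair_potential(x + h, y, pair) - pair_potential(x - h, y, pair)) / (2 * h)
  Ey <- -(pair_potential(x, y + h, pair) - pair_potential(x, y - h, pair)) / (2 * h)
  sqrt(Ex^2 + Ey^2)
}

#' Finite-difference Laplace solution for a single pair (validation oracle)
#'
#' Solves the 2-D Laplace equation on an `n` x `n` grid over the tissue
#' square by successive over-relaxation (SOR), completely independently of
#' the analytic image-charge solution it validates. Dirichlet conditions:
#' nodes inside each conductor circle are fixed at +/- V_AB/2; the outer
#' boundary ring is fixed at the analytic pair potential so the comparison
#' isolates interior accuracy (a validation choice, not a physics claim).
#' Free nodes whose stencil arms are cut by a conductor circle use the
#' Shortley--Weller fractional-arm stencil, so the Dirichlet condition is
#' honoured on the true circle rather than on its staircase approximation;
#' without this correction the effective conductor radius is off by up to
#' half a grid step and the near-logarithmic potential inherits an O(h)
#' error visible everywhere.
#'
#' @param layout A single-pair `nf_layout` (exactly two electrodes).
#' @param n Grid size per side (>= 100); nodes at
#'   `x_i = (i-0.5)/n * L - L/2` as in [mesh_axes()].
#' @param omega SOR relaxation factor; default 1.9.
#' @param tol Convergence tolerance on the max per-sweep update (V).
#' @param max_iters Iteration cap; non-convergence is an error.
#' @return An object of class `nf_relaxation_grid`: `potential` (n x n
#'   matrix, rows indexing y ascending), `fixed` (logical matrix),
#'   `x`, `y` (node coordinates), `iterations`, `residual`, `pair`.
#' @export
fd_laplace_solve <- function(layout, n = 200L, omega = 1.9,
                             tol = 1e-8, max_iters = 50000L) {
  stopifnot(inherits(layout, "nf_layout"), n >= 100)
  pairs <- enumerate_pairs(layout)
  if (length(pairs) != 1L)
    stop("the relaxation oracle supports single-pair layouts only", call. = FALSE)
  pg <- pairs[[1L]]
  spec <- mesh_spec(layout$tissue_side, n, n)
  ax <- mesh_axes(spec)
  X <- matrix(ax$x, nrow = n, ncol = n, byrow = TRUE)
  Y <- matrix(ax$y, nrow = n, ncol = n)

  u <- matrix(0, n, n)
  fixed <- matrix(FALSE, n, n)
  # conductor interiors at +/- V/2
  inA <- (X - pg$xA)^2 + (Y - pg$yA)^2 <= pg$rho0^2
  inB <- (X - pg$xB)^2 + (Y - pg$yB)^2 <= pg$rho0^2
  if (!any(inA) || !any(inB))
    stop("grid too coarse: no node falls inside an electrode circle", call. = FALSE)
  u[inA] <- +pg$voltage / 2
  u[inB] <- -pg$voltage / 2
  fixed[inA | inB] <- TRUE
  # outer ring at the analytic potential
  ring <- matrix(FALSE, n, n)
  ring[c(1, n), ] <- TRUE
  ring[, c(1, n)] <- TRUE
  u[ring] <- pair_potential(X[ring], Y[ring], pg)
  fixed[ring] <- TRUE

  # Shortley-Weller arm fractions for free nodes next to a conductor circle
  h <- ax$x[2] - ax$x[1]
  aN <- aS <- aW <- aE <- matrix(1, n, n)
  cond <- inA | inB
  circ <- list(A = c(pg$xA, pg$yA), B = c(pg$xB, pg$yB))
  # direction -> (row offset, col offset, dx, dy, arm matrix name)
  dirs <- list(N = list(1L, 0L, 0, +h, "aN"), S = list(-1L, 0L, 0, -h, "aS"),
               W = list(0L, -1L, -h, 0, "aW"), E = list(0L, 1L, +h, 0, "aE"))
  shift_hit <- matrix(FALSE, n, n)
  for (d in dirs) {
    nb <- matrix(FALSE, n, n)
    ri <- seq_len(n) + d[[1L]]; ci <- seq_len(n) + d[[2L]]
    ok_r <- ri >= 1 & ri <= n; ok_c <- ci >= 1 & ci <= n
    nb[ok_r, ok_c] <- cond[ri[ok_r], ci[ok_c]]
    shift_hit <- shift_hit | nb
  }
  for (idx in which(!fixed & shift_hit)) {
    i <- (idx - 1L) %% n + 1L; j <- (idx - 1L) %/% n + 1L
    px0 <- ax$x[j]; py0 <- ax$y[i]
    for (dn in names(dirs)) {
      d <- dirs[[dn]]
      ii <- i + d[[1L]]; jj <- j + d[[2L]]
      if (ii < 1 || ii > n || jj < 1 || jj > n || !cond[ii, jj]) next
      c0 <- if (inA[ii, jj]) circ$A else circ$B
      # smallest t in (0, 1] with |P + t*(dx,dy) - c0| = rho0
      p <- c(px0 - c0[1], py0 - c0[2]); v <- c(d[[3L]], d[[4L]])
      b <- sum(p * v); cc <- sum(p * p) - pg$rho0^2; a2 <- sum(v * v)
      disc <- b^2 - a2 * cc
      t <- if (disc >= 0) (-b - sqrt(disc)) / a2 else 1
      alpha <- min(max(t, 1e-3), 1)
      nm <- paste0("a", dn)
      m <- get(nm); m[i, j] <- alpha; assign(nm, m)
    }
  }

  res <- sor_laplace(u, fixed, aN, aS, aW, aE, omega, tol, as.integer(max_iters))
  if (!res$converged)
    stop("SOR did not converge in ", max_iters, " iterations (max update ",
         signif(res$max_update, 4), " V > tol ", tol, " V)", call. = FALSE)
  structure(list(potential = res$potential, fixed = fixed,
                 x = ax$x, y = ax$y,
                 iterations = res$iterations, residual = res$residual,
                 pair = pg),
            class = "nf_relaxation_grid")
}

#' Compare a relaxation solution to the analytic potential
#'
#' Deviation is normalized by the maximum absolute analytic potential over
#' the compared nodes: the potential crosses zero on the pair bisector, so
#' a pointwise relative error is undefined there. Nodes within
#' `exclude_radius` of either electrode centre and fixed nodes are excluded.
#'
#' @param relax An `nf_relaxation_grid`.
#' @param exclude_radius Exclusion radius around electrode centres (m);
#'   default 5 conductor radii.
#' @return List with `max_rel_dev` (fraction), `n_compared`, `scale_V`.
#' @export
compare_relaxation <- function(relax, exclude_radius = 5 * relax$pair$rho0) {
  pg <- relax$pair
  n <- length(relax$x)
  X <- matrix(relax$x, nrow = n, ncol = n, byrow = TRUE)
  Y <- matrix(relax$y, nrow = n, ncol = n)
  far <- ((X - pg$xA)^2 + (Y - pg$yA)^2 > exclude_radius^2) &
         ((X - pg$xB)^2 + (Y - pg$yB)^2 > exclude_radius^2) &
         !relax$fixed
  ana <- matrix(pair_potential(as.vector(X), as.vector(Y), pg), n, n)
  scale <- max(abs(ana[far]))
  dev <- max(abs(relax$potential[far] - ana[far])) / scale
  list(max_rel_dev = dev, n_compared = sum(far), scale_V = scale)
}

#' Dump a relaxation grid as TSV (debugging aid)
#' @param relax An `nf_relaxation_grid`.
#' @param path Output TSV path; row 1 at maximum y.
#' @return `path`, invisibly.
#' @export
write_relaxation_grid <- function(relax, path) {
  m <- relax$potential[rev(seq_along(relax$y)), , drop = FALSE]
  utils::write.table(format(m, digits = 6, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
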