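new_dipole_solution <- function(P, E_inc, alpha, wave, residual, iterations,
                                method, converged) {
  structure(
    list(P = P, E_inc = E_inc, alpha = alpha, wave = wave,
         residual = residual, iterations = iterations, method = method,
         converged = converged),
    class = "dipole_solution"
  )
}

#' @export
print.dipole_solution <- function(x, ...) {
  cat(sprintf(
    "<dipole_solution> %d dipoles, method = %s, residual = %.3g (%d iterations)\n",
    nrow(x$P), x$method, x$residual, x$iterations))
  invisible(x)
}

# relative residual of the coupled equations P/alpha - G P = E_inc
coupled_residual <- function(model, k, P, alpha, E_inc, kernel = NULL) {
  r <- P / alpha - apply_interaction(model, k, P, kernel = kernel)
  sqrt(sum(Mod(r - E_inc)^2)) / sqrt(sum(Mod(E_inc)^2))
}

# Dense system matrix in component-block layout: rows/cols (x-block, y-block,
# z-block), A = diag(1/alpha) - G.
dense_system_matrix <- function(model, k, alpha) {
  pos <- dipole_positions(model)
  g <- green_pair_matrices(pos, k)
  n <- nrow(pos)
  A <- rbind(cbind(-g$xx, -g$xy, -g$xz),
             cbind(-g$xy, -g$yy, -g$yz),
             cbind(-g$xz, -g$yz, -g$zz))
  idx <- seq_len(3L * n)
  A[cbind(idx, idx)] <- A[cbind(idx, idx)] + rep(1 / alpha, 3L)
  A
}

flatten_blocks <- function(P) c(P[, 1], P[, 2], P[, 3])
unflatten_blocks <- function(v) {
  n <- length(v) / 3L
  cbind(v[seq_len(n)], v[n + seq_len(n)], v[2L * n + seq_len(n)])
}

# BiCGSTAB for the complex non-Hermitian coupled-dipole system.
bicgstab_solve <- function(matvec, b, tol, maxit, x0 = NULL) {
  nb <- sqrt(sum(Mod(b)^2))
  x <- if (is.null(x0)) b * 0i else x0
  r <- b - matvec(x)
  rhat <- r
  rho <- alpha <- omega <- 1 + 0i
  v <- p <- r * 0i
  hist <- numeric(0)
  cdot <- function(a, b) sum(Conj(a) * b)
  for (it in seq_len(maxit)) {
    rho1 <- cdot(rhat, r)
    if (Mod(rho1) < 1e-300) break
    beta <- (rho1 / rho) * (alpha / omega)
    p <- r + beta * (p - omega * v)
    v <- matvec(p)
    alpha <- rho1 / cdot(rhat, v)
    s <- r - alpha * v
    if (sqrt(sum(Mod(s)^2)) / nb < tol) {
      x <- x + alpha * p
      hist <- c(hist, sqrt(sum(Mod(s)^2)) / nb)
      return(list(x = x, iterations = it, residual = utils::tail(hist, 1),
                  converged = TRUE, history = hist))
    }
    t <- matvec(s)
    omega <- cdot(t, s) / cdot(t, t)
    x <- x + alpha * p + omega * s
    r <- s - omega * t
    rel <- sqrt(sum(Mod(r)^2)) / nb
    hist <- c(hist, rel)
    if (rel < tol) {
      return(list(x = x, iterations = it, residual = rel, converged = TRUE,
                  history = hist))
    }
    rho <- rho1
  }
  list(x = x, iterations = length(hist), residual = utils::tail(hist, 1),
       converged = FALSE, history = hist)
}

#' Solve the coupled-dipole equations
#'
#' Finds dipole moments satisfying
#' `P_i = alpha_i (E_inc,i + sum_{j != i} G_ij P_j)` for plane-wave
#' illumination, to a relative residual `tol`. The default path is a Krylov
#' iteration (BiCGSTAB) with the FFT-accelerated interaction product; small
#' systems (or `method = "dense"`) use a direct LAPACK factorization of the
#' full 3N x 3N coupling matrix.
#'
#' @param model A [dipole_model()].
#' @param wave A [plane_wave()].
#' @param tol Relative residual stopping criterion (default 1e-5, the
#'   conventional coupled-dipole stopping magnitude).
#' @param method `"auto"`, `"bicgstab"` or `"dense"`.
#' @param maxit Iteration cap for the Krylov path.
#' @param polarizability `"ldr"` (default) or `"cm"`.
#' @param s_mode LDR direction-factor mode, see [ldr_polarizability()];
#'   additionally `"iso"` uses the orientation-isotropic value S = 1/5.
#' @param kernel Optional precomputed [interaction_kernel()].
#' @return A `dipole_solution` with fields `P`, `E_inc`, `alpha`, `residual`,
#'   `iterations`, `converged`.
#' @examples
#' m <- voxelize(solenoid_spec(), dipoles_per_longest = 8)
#' sol <- solve_dipoles(m, plane_wave())
#' sol$residual
#' @export
solve_dipoles <- function(model, wave, tol = 1e-5,
                          method = c("auto", "bicgstab", "dense"),
                          maxit = 2000L, polarizability = "ldr",
                          s_mode = "avgpol", kernel = NULL) {
  method <- match.arg(method)
  n <- n_dipoles(model)
  if (method == "auto") method <- if (n <= 300L) "dense" else "bicgstab"
  alpha <- model_alpha(model, wave, polarizability, s_mode)
  E <- incident_field(model, wave)
  k <- k_medium(wave)
  if (max(Mod(alpha)) < 1e-30) {
    # no contrast: the zero moment field solves the coupled equations
    return(new_dipole_solution(E * 0i, E, alpha, wave, 0, 0L, "trivial",
                               converged = TRUE))
  }
  if (method == "dense") {
    A <- dense_system_matrix(model, k, alpha)
    x <- solve(A, flatten_blocks(E))
    P <- unflatten_blocks(x)
    res <- coupled_residual(model, k, P, alpha, E, kernel = kernel)
    return(new_dipole_solution(P, E, alpha, wave, res, 1L, "dense",
                               converged = res <= max(tol, 1e-8)))
  }
  if (is.null(kernel)) kernel <- interaction_kernel(model, k)
  matvec <- function(v) {
    P <- unflatten_blocks(v)
    flatten_blocks(P / alpha - apply_kernel(kernel, P))
  }
  x0 <- flatten_blocks(alpha * E)      # first Born guess
  out <- bicgstab_solve(matvec, flatten_blocks(E), tol = tol, maxit = maxit,
                        x0 = x0)
  if (!out$converged) {
    stop(sprintf(
      "coupled-dipole iteration did not converge: residual %.3g after %d iterations (history tail: %s)",
      out$residual, out$iterations,
      paste(signif(utils::tail(out$history, 5L), 3), collapse = ", ")),
      call. = FALSE)
  }
  P <- unflatten_blocks(out$x)
  new_dipole_solution(P, E, alpha, wave, out$residual, out$iterations,
                      "bicgstab", converged = TRUE)
}

model_alpha <- function(model, wave, polarizability = "ldr",
                        s_mode = "avgpol") {
  m <- model$rel_index
  if (length(m) == 1L) m <- rep(m, n_dipoles(model))
  if (identical(polarizability, "cm")) {
    return(cm_polarizability(m, model$spacing))
  }
  if (identical(s_mode, "iso")) {
    ldr_polarizability_s(m, model$spacing, k_medium(wave), S = 1 / 5)
  } else {
    vapply(m, function(mi) ldr_polarizability(mi, model$spacing, wave,
                                              s_mode = s_mode), complex(1))
  }
}

# LDR value at an explicitly supplied direction factor S (vectorized in m).
ldr_polarizability_s <- function(m, d, k, S) {
  m <- as.complex(m)
  a_cm <- (3 * d^3 / (4 * pi)) * (m^2 - 1) / (m^2 + 2)
  kd <- k * d
  denom <- 1 + (a_cm / d^3) *
    ((LDR_B1 + LDR_B2 * m^2 + LDR_B3 * m^2 * S) * kd^2 - (2 / 3) * 1i * kd^3)
  a_cm / denom
}

#' First Born approximation dipole moments
#'
#' Switches off all inter-dipole coupling: `P_i = alpha_i E_inc,i`
#' (single-scattering regime). For assemblies of isotropic polarizabilities
#' this mode yields identically zero CIDS, which is the classic Born-limit
#' null result for chiral arrangements of isotropic scatterers.
#'
#' @inheritParams solve_dipoles
#' @return A `dipole_solution` (residual of the uncoupled equation is 0).
#' @export
born_dipoles <- function(model, wave, polarizability = "ldr",
                         s_mode = "avgpol") {
  alpha <- model_alpha(model, wave, polarizability, s_mode)
  E <- incident_field(model, wave)
  new_dipole_solution(alpha * E, E, alpha, wave, residual = 0,
                      iterations = 0L, method = "born", converged = TRUE)
}

# Dense multi-right-hand-side solve: factor A once, solve for every column of
# the 3N x nrhs incident-field matrix. Requires a single shared alpha.
solve_dense_multi <- function(model, k, alpha, E_blocks) {
  A <- dense_system_matrix(model, k, alpha)
  solve(A, E_blocks)
}
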