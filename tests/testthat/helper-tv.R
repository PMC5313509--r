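# Exact 1D total-variation proximal map (taut-string / direct algorithm),
# written from the running min/max formulation: an independent oracle for
# the package's dual-ascent TV prox on line masks.
tv1d_taut_string <- function(y, lam) {
  n <- length(y)
  if (n == 0L) return(numeric(0))
  if (lam <= 0 || n == 1L) return(y)
  x <- numeric(n)
  k <- k0 <- km <- kp <- 1L
  vmin <- y[1] - lam
  vmax <- y[1] + lam
  umin <- lam
  umax <- -lam
  repeat {
    if (k == n) {
      if (umin < 0) {
        x[k0:km] <- vmin
        k <- k0 <- km <- km + 1L
        vmin <- y[k]
        umin <- lam
        umax <- y[k] + lam - vmax
      } else if (umax > 0) {
        x[k0:kp] <- vmax
        k <- k0 <- kp <- kp + 1L
        vmax <- y[k]
        umax <- -lam
        umin <- y[k] - lam - vmin
      } else {
        x[k0:n] <- vmin + umin / (k - k0 + 1)
        return(x)
      }
      if (k > n) return(x)
    }
    if (k < n) {
      if (y[k + 1] + umin < vmin - lam) {
        x[k0:km] <- vmin
        k <- k0 <- km <- kp <- km + 1L
        vmin <- y[k]
        vmax <- y[k] + 2 * lam
        umin <- lam
        umax <- -lam
      } else if (y[k + 1] + umax > vmax + lam) {
        x[k0:kp] <- vmax
        k <- k0 <- km <- kp <- kp + 1L
        vmin <- y[k] - 2 * lam
        vmax <- y[k]
        umin <- lam
        umax <- -lam
      } else {
        k <- k + 1L
        umin <- umin + y[k] - vmin
        umax <- umax + y[k] - vmax
        if (umin >= lam) {
          vmin <- vmin + (umin - lam) / (k - k0 + 1)
          umin <- lam
          km <- k
        }
        if (umax <= -lam) {
          vmax <- vmax + (umax + lam) / (k - k0 + 1)
          umax <- -lam
          kp <- k
        }
      }
    }
  }
}

# Exact 1D fused-signal solution by exhaustive KKT enumeration (n <= 12):
# enumerate segment partitions and jump signs, solve each candidate in
# closed form and keep those whose interior dual variables stay feasible.
# Slow but unambiguous; used to certify tv1d_taut_string.
tv1d_enumerate <- function(y, lam) {
  n <- length(y)
  stopifnot(n <= 12L)
  if (lam <= 0 || n == 1L) return(y)
  best <- NULL
  best_obj <- Inf
  objective <- function(z) 0.5 * sum((z - y)^2) + lam * sum(abs(diff(z)))
  for (cut_mask in 0:(2^(n - 1L) - 1L)) {
    cuts <- which(bitwAnd(cut_mask, 2^(0:(n - 2L))) > 0L)
    bounds <- c(0L, cuts, n)
    k <- length(bounds) - 1L
    sign_sets <- if (k == 1L) list(integer(0)) else {
      do.call(expand.grid, rep(list(c(-1, 1)), k - 1L)) |>
        apply(1L, identity, simplify = FALSE)
    }
    for (sgn in sign_sets) {
      s_full <- c(0, lam * unlist(sgn), 0) # dual at segment boundaries
      z <- numeric(n)
      ok <- TRUE
      for (j in seq_len(k)) {
        idx <- (bounds[j] + 1L):bounds[j + 1L]
        z[idx] <- mean(y[idx]) + (s_full[j + 1L] - s_full[j]) / length(idx)
      }
      # jump signs must match
      if (k > 1L) {
        jumps <- z[bounds[2:k] + 1L] - z[bounds[2:k]]
        if (any(sign(jumps) != unlist(sgn)) || any(jumps == 0)) ok <- FALSE
      }
      # interior duals feasible: u_i = u_{left} + cumsum(z - y) in [-lam, lam]
      if (ok) {
        for (j in seq_len(k)) {
          idx <- (bounds[j] + 1L):bounds[j + 1L]
          u <- s_full[j] + cumsum(z[idx] - y[idx])
          if (any(u > lam + 1e-9) || any(u < -lam - 1e-9)) { ok <- FALSE; break }
        }
      }
      if (ok) {
        o <- objective(z)
        if (o < best_obj) { best_obj <- o; best <- z }
      }
    }
  }
  best
}

# Derivative-free brute-force prox oracle for small instances:
# argmin_z 0.5||z - v||^2 + step * (wtv * ||grad z||_1 + w1 * ||z||_1),
# by Nelder-Mead from several starts.
prox_oracle_nm <- function(v, grid, step, wtv = 0, w1 = 0, restarts = 6) {
  obj <- function(z) {
    g <- discrete_gradient(z, grid)
    0.5 * sum((z - v)^2) + step * (wtv * sum(abs(g)) + w1 * sum(abs(z)))
  }
  best <- NULL
  best_obj <- Inf
  starts <- c(list(v, numeric(length(v))),
              lapply(seq_len(restarts - 2), function(i) {
                v + stats::rnorm(length(v), sd = 0.2 * (1 + abs(v)))
              }))
  for (s in starts) {
    for (rep in 1:3) {
      o <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(maxit = 20000, reltol = 1e-14))
      s <- o$par
    }
    if (o$value < best_obj) { best_obj <- o$value; best <- o$par }
  }
  list(z = best, objective = best_obj, fn = obj)
}
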