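# Blind source separation / noise-reduction registry.
#
# FastICA, JADE and the Laplacian-eigenmap spectral embedding are
# implemented here from their published algorithms and validated against
# toy-mixture oracles in the test suite; PCA goes through stats::prcomp.

#' Describe a source-separation configuration
#'
#' @param method one of `"none"`, `"fastica"`, `"pca"`, `"pca_ica"`,
#'   `"jade"`, `"spectral_embedding"`.
#' @param repeats number of sequential ICA passes (1-3; the output of one
#'   pass feeds the next). Passes beyond 3 are clamped with a warning —
#'   further repetitions have no effect on the extracted components.
#' @param mode `"joint"` feeds all channels as one matrix; `"per_channel"`
#'   applies the method to each channel on its own.
#' @param seed integer seed driving ICA initialisation and embedding
#'   determinism.
#' @return an object of class `separation_spec`.
#' @export
separation_spec <- function(method = "fastica", repeats = 1L,
                            mode = "joint", seed = 1L) {
  methods <- c("none", "fastica", "pca", "pca_ica", "jade",
               "spectral_embedding")
  if (!method %in% methods) stop_validation("unknown method: ", method)
  if (!mode %in% c("joint", "per_channel")) {
    stop_validation("unknown mode: ", mode)
  }
  repeats <- as.integer(repeats)
  if (repeats < 1L) stop_validation("repeats must be >= 1")
  if (repeats > 3L) {
    warning("ICA passes beyond 3 have no effect; clamping repeats to 3")
    repeats <- 3L
  }
  structure(list(method = method, repeats = repeats, mode = mode,
                 seed = as.integer(seed)),
            class = "separation_spec")
}

# Whiten rows of X (n x T): centre, decorrelate, unit variance.
# Returns list(z, mean): z = K %*% (X - mean).
whiten_rows <- function(X) {
  n <- nrow(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- Xc %*% t(Xc) / ncol(Xc)
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, .Machine$double.eps)
  K <- diag(1 / sqrt(vals), n) %*% t(eg$vectors)
  list(z = K %*% Xc, mean = mu)
}

# Symmetric decorrelation: W <- (W W^T)^{-1/2} W.
sym_decorrelate <- function(W) {
  s <- La.svd(W)
  s$u %*% diag(1 / s$d, nrow(W)) %*% t(s$u) %*% W
  # equivalent to (W W^T)^{-1/2} W
}

# FastICA with symmetric (parallel) estimation and the logcosh
# nonlinearity; whitening on, tolerance 1e-4, at most 500 iterations.
# Returns list(components = n x T, converged = logical).
fastica_extract <- function(X, seed = 1L, tol = 1e-4, max_iter = 500L) {
  n <- nrow(X)
  Tn <- ncol(X)
  if (n == 1L) {
    v <- as.numeric(X) - mean(X)
    s <- sd(v)
    if (s == 0) s <- 1
    return(list(components = matrix(v / s, 1L), converged = TRUE))
  }
  wh <- whiten_rows(X)
  Z <- wh$z
  W <- with_local_seed(seed, matrix(rnorm(n * n), n, n))
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W1 <- (G %*% t(Z)) / Tn - diag(rowMeans(Gp), n) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(components = W %*% Z, converged = converged)
}

# JADE: joint approximate diagonalisation of fourth-order cumulant
# matrices (Jacobi rotations on the whitened data), real-valued variant.
# Returns list(components = n x T, converged = logical).
jade_extract <- function(X, tol = 1e-6, max_sweeps = 100L) {
  n <- nrow(X)
  Tn <- ncol(X)
  if (n == 1L) {
    return(fastica_extract(X, seed = 1L))
  }
  Z <- whiten_rows(X)$z
  # Parallel set of cumulant matrices Q_ij for i <= j:
  # Q_ij = E[z_i z_j z z'] - delta_ij I - e_i e_j' - e_j e_i'
  cum <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      Q <- (Z * rep(Z[i, ] * Z[j, ], each = n)) %*% t(Z) / Tn
      if (i == j) Q <- Q - diag(n)
      Eij <- matrix(0, n, n)
      Eij[i, j] <- Eij[i, j] + 1
      Eij[j, i] <- Eij[j, i] + 1
      cum[[length(cum) + 1L]] <- Q - Eij
    }
  }
  V <- diag(n)
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    rotated <- FALSE
    for (p in 1:(n - 1)) {
      for (q in (p + 1):n) {
        # closed-form Givens angle maximising joint diagonality
        Gm <- matrix(0, 2, 2)
        for (Q in cum) {
          h <- c(Q[p, p] - Q[q, q], Q[p, q] + Q[q, p])
          Gm <- Gm + h %o% h
        }
        eg <- eigen(Gm, symmetric = TRUE)
        ang <- eg$vectors[, 1]
        if (ang[1] < 0) ang <- -ang
        r <- sqrt(sum(ang^2))
        cth <- sqrt((ang[1] + r) / (2 * r))
        sth <- ang[2] / sqrt(2 * r * (ang[1] + r))
        if (abs(sth) > tol) {
          rotated <- TRUE
          Rot <- diag(n)
          Rot[p, p] <- cth; Rot[q, q] <- cth
          Rot[p, q] <- -sth; Rot[q, p] <- sth
          V <- V %*% Rot
          cum <- lapply(cum, function(Q) t(Rot) %*% Q %*% Rot)
        }
      }
    }
    if (!rotated) {
      converged <- TRUE
      break
    }
  }
  list(components = t(V) %*% Z, converged = converged)
}

# Laplacian-eigenmap spectral embedding of the T samples (columns of X,
# points in R^n) using an RBF affinity with gamma = 1/n. Returns the
# n_components eigenvectors of the symmetric normalised Laplacian after
# the constant one, each used as a candidate time series.
spectral_embed <- function(X, n_components = nrow(X), seed = 1L) {
  n <- nrow(X)
  Tn <- ncol(X)
  P <- t(X)                        # T x n sample coordinates
  d2 <- as.matrix(stats::dist(P))^2
  A <- exp(-d2 / n)
  diag(A) <- 0
  deg <- rowSums(A)
  deg[deg == 0] <- .Machine$double.eps
  Dm <- 1 / sqrt(deg)
  Lsym <- diag(Tn) - (Dm * A) %*% diag(Dm, Tn)
  eg <- eigen(Lsym, symmetric = TRUE)
  k <- min(n_components, Tn - 1L)
  # smallest eigenvalues last in eigen()'s ordering; skip the constant one
  idx <- seq.int(Tn - 1L, by = -1L, length.out = k)
  emb <- t(eg$vectors[, idx, drop = FALSE] * Dm)
  # fix sign deterministically: largest-magnitude coordinate positive
  for (i in seq_len(nrow(emb))) {
    m <- which.max(abs(emb[i, ]))
    if (emb[i, m] < 0) emb[i, ] <- -emb[i, ]
  }
  emb
}

#' Extract candidate pulse components from a multi-channel matrix
#'
#' Applies the configured noise-reduction / source-extraction method to
#' the channel matrix and returns candidate component series, each with a
#' provenance tag naming the method, component index and source mode.
#'
#' @param channels numeric matrix, one row per channel signal (rows
#'   pre-aligned to one even grid); rownames are used as provenance
#'   labels.
#' @param spec a [separation_spec()].
#' @return list of candidates; each is a list with `values`, `method`,
#'   `index`, `source` and `converged`.
#' @export
separate <- function(channels, spec = separation_spec()) {
  stopifnot(inherits(spec, "separation_spec"))
  X <- as.matrix(channels)
  n <- nrow(X)
  if (n < 1L) stop_validation("need at least one channel")
  if (ncol(X) <= n) stop_validation("need more samples than channels")
  labels <- rownames(X)
  if (is.null(labels)) labels <- paste0("ch", seq_len(n))

  if (spec$mode == "per_channel" && spec$method != "none") {
    out <- list()
    for (i in seq_len(n)) {
      sub <- separate(matrix(X[i, ], 1L, dimnames = list(labels[i])),
                      separation_spec(spec$method, spec$repeats, "joint",
                                      spec$seed))
      for (cand in sub) {
        cand$source <- labels[i]
        out[[length(out) + 1L]] <- cand
      }
    }
    return(out)
  }

  mk <- function(S, method, converged = TRUE) {
    lapply(seq_len(nrow(S)), function(i) {
      list(values = as.numeric(S[i, ]), method = method, index = i,
           source = if (method == "none") labels[i] else "joint",
           converged = converged)
    })
  }

  switch(spec$method,
    none = mk(X, "none"),
    fastica = {
      S <- X
      converged <- TRUE
      for (k in seq_len(spec$repeats)) {
        res <- fastica_extract(S, seed = spec$seed + k - 1L)
        S <- res$components
        converged <- converged && res$converged
      }
      mk(S, "fastica", converged)
    },
    pca = {
      pc <- prcomp(t(X), center = TRUE, scale. = FALSE)
      mk(t(pc$x[, seq_len(n), drop = FALSE]), "pca")
    },
    pca_ica = {
      pc <- prcomp(t(X), center = TRUE, scale. = FALSE)
      scores <- t(pc$x[, seq_len(n), drop = FALSE])
      S <- scores
      converged <- TRUE
      for (k in seq_len(spec$repeats)) {
        res <- fastica_extract(S, seed = spec$seed + k - 1L)
        S <- res$components
        converged <- converged && res$converged
      }
      mk(S, "pca_ica", converged)
    },
    jade = {
      res <- jade_extract(X)
      mk(res$components, "jade", res$converged)
    },
    spectral_embedding = {
      emb <- spectral_embed(X, n_components = n, seed = spec$seed)
      mk(emb, "spectral_embedding")
    }
  )
}

#' Align a region's channels onto the colour stream's even grid
#'
#' IR frames run on their own clock, so before joint separation every
#' channel is linearly interpolated onto an evenly spaced grid spanning
#' the colour stream's samples inside the window.
#'
#' @param region named list of [channel_series()] (one region of a
#'   `region_store`).
#' @param window numeric `(start_ms, end_ms)` bounds; samples with
#'   `start_ms <= t < end_ms` are used.
#' @return numeric matrix, one row per channel (canonical order R, G, B,
#'   Gy, IR restricted to the channels present), with attributes
#'   `timestamps` (the even grid, ms) and `fs` (grid rate, Hz).
#' @export
align_channels <- function(region, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  chans <- intersect(CHANNEL_LABELS, names(region))
  if (length(chans) == 0L) stop_validation("region has no channels")
  ref <- region[[intersect(COLOUR_CHANNELS, chans)[1]]]
  if (is.null(ref)) ref <- region[[chans[1]]]
  keep <- ref$timestamps >= window[1] & ref$timestamps < window[2]
  if (sum(keep) < 2L) stop_validation("insufficient samples in window")
  ts <- ref$timestamps[keep]
  n <- length(ts)
  grid <- seq(ts[1], ts[n], length.out = n)
  M <- matrix(NA_real_, length(chans), n,
              dimnames = list(chans, NULL))
  for (ch in chans) {
    cs <- region[[ch]]
    inw <- cs$timestamps >= window[1] & cs$timestamps < window[2]
    if (sum(inw) < 2L) {
      stop_validation("channel ", ch, ": < 2 samples in window")
    }
    M[ch, ] <- approx(cs$timestamps[inw], cs$values[inw], xout = grid,
                      rule = 2)$y
  }
  attr(M, "timestamps") <- grid
  attr(M, "fs") <- 1000 * (n - 1) / (grid[n] - grid[1])
  M
}
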