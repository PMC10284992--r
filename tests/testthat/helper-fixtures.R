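# Shared fixtures and independent oracles used across the suite.

# random connected triangle mesh built as a perturbed grid strip
random_mesh <- function(n_faces = 50L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nx <- max(3L, ceiling(sqrt(n_faces / 2)) + 1L)
  ny <- nx
  m <- grid_mesh(nx, ny, spacing = 1, z = 100)
  m$vertices <- m$vertices + matrix(stats::runif(3L * nrow(m$vertices),
                                                 -0.2, 0.2),
                                    ncol = 3L)
  m
}

# brute-force edge enumeration oracle: set of sorted vertex pairs
oracle_edge_count <- function(faces) {
  pairs <- character()
  for (r in seq_len(nrow(faces))) {
    f <- faces[r, ]
    for (p in list(c(1, 2), c(2, 3), c(1, 3))) {
      key <- paste(sort(f[p]), collapse = "-")
      pairs <- c(pairs, key)
    }
  }
  length(unique(pairs))
}

# dense matrix rank via QR
oracle_rank <- function(M) qr(as.matrix(M))$rank

# exact dense solver for min ||A x - b||^2 s.t. x[idx] >= lb by enumerating
# every subset of bounds held active (exhaustive; valid because the optimal
# active set is one of the subsets)
oracle_bounded_ls <- function(A, b, idx, lb) {
  A <- as.matrix(A)
  best <- NULL
  best_obj <- Inf
  k <- length(idx)
  for (mask in 0:(2^k - 1)) {
    act <- idx[bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0]
    free <- setdiff(seq_len(ncol(A)), act)
    rhs <- b
    x <- numeric(ncol(A))
    if (length(act)) {
      x[act] <- lb[match(act, idx)]
      rhs <- b - A[, act, drop = FALSE] %*% x[act]
    }
    x[free] <- qr.coef(qr(A[, free, drop = FALSE]), rhs)
    if (any(is.na(x))) next
    if (any(x[idx] < lb - 1e-9)) next
    obj <- sum((A %*% x - b)^2)
    if (obj < best_obj) {
      best_obj <- obj
      best <- x
    }
  }
  best
}

# eigenvalues of a symmetric 3x3 by characteristic-polynomial root finding
oracle_sym_eigen <- function(S) {
  cp <- c(-det(S),
          S[1, 1] * S[2, 2] + S[1, 1] * S[3, 3] + S[2, 2] * S[3, 3] -
            S[1, 2]^2 - S[1, 3]^2 - S[2, 3]^2,
          -(S[1, 1] + S[2, 2] + S[3, 3]),
          1)
  sort(Re(polyroot(cp)), decreasing = TRUE)
}

# brute-force point-to-plane surface distance oracle
oracle_surface_distance <- function(V, R) {
  n <- nrow(V)
  out <- numeric(n)
  comp <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(R) - V[i, ])^2))
    ord <- order(d)
    A <- R[ord[1], ]; B <- R[ord[2], ]; C <- R[ord[3], ]
    nrm <- c((B - A)[2] * (C - A)[3] - (B - A)[3] * (C - A)[2],
             (B - A)[3] * (C - A)[1] - (B - A)[1] * (C - A)[3],
             (B - A)[1] * (C - A)[2] - (B - A)[2] * (C - A)[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    comp[i, ] <- sum((V[i, ] - A) * nrm) * nrm
    out[i] <- abs(sum((V[i, ] - A) * nrm))
  }
  list(distance = out, comp = comp)
}

# all-pairs directed HD95 oracle
oracle_hd95 <- function(A, B, probs = 0.95) {
  dmat <- function(P, Q) {
    sqrt(pmax(outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% t(Q), 0))
  }
  dab <- stats::quantile(apply(dmat(A, B), 1, min), probs, names = FALSE)
  dba <- stats::quantile(apply(dmat(B, A), 1, min), probs, names = FALSE)
  max(dab, dba)
}

# cached default-scenario artifacts shared by the heavier tests; built once
# per test run
.shared <- new.env(parent = emptyenv())

default_sequence <- function(seed = 42L) {
  key <- paste0("seq_", seed)
  if (is.null(.shared[[key]])) {
    .shared[[key]] <- generate_sequence(synthetic_scenario(), seed = seed)
  }
  .shared[[key]]
}

default_recovery <- function(seed = 42L, ...) {
  key <- paste0("rec_", seed, "_", paste(deparse(list(...)), collapse = ""))
  if (is.null(.shared[[key]])) {
    sq <- default_sequence(seed)
    .shared[[key]] <- run_sequence(sq$mesh0, sq$frames,
                                   config = recover_config(...))
  }
  .shared[[key]]
}
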