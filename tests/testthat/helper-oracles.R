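# Independent oracles used across the suite. These deliberately re-derive
# everything from first principles (plain loops, exact linear algebra)
# rather than calling the package's computational paths.

# Brute-force run-length encoding.
oracle_rle <- function(states) {
  st <- integer(0); dur <- integer(0)
  cur <- states[1]; len <- 1L
  for (v in states[-1]) {
    if (v == cur) len <- len + 1L
    else { st <- c(st, cur); dur <- c(dur, len); cur <- v; len <- 1L }
  }
  data.frame(state = c(st, cur), duration = c(dur, len))
}

# Plain-R rescaled range: mean R/S over disjoint windows of size w.
oracle_rs <- function(x, w) {
  k <- floor(length(x) / w)
  vals <- numeric(0)
  for (b in seq_len(k)) {
    seg <- x[((b - 1) * w + 1):(b * w)]
    dev <- seg - mean(seg)
    cum <- cumsum(dev)
    s <- sqrt(mean(dev^2))
    if (s > 0) vals <- c(vals, (max(cum) - min(cum)) / s)
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# Exact single-step transition matrix of the gating walk with the slow
# process frozen, built from the exported potential functions and the
# documented stepping rules (threshold node skipped; crossing gated by
# the uphill half-step; reflection at the boundaries).
oracle_transition_matrix <- function(cfg, state = walker_state(cfg)) {
  pot <- if (cfg$model == 1) potential_m1 else potential_m2
  u <- function(x) pot(x, cfg, state)
  nodes <- setdiff(state$b1:state$b2, cfg$tp)
  n <- length(nodes)
  P <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n)) {
    x <- nodes[i]
    du <- if (x == cfg$tp - 1L) {
      u(cfg$tp) - u(cfg$tp - 0.5)
    } else if (x == cfg$tp + 1L) {
      u(cfg$tp + 0.5) - u(cfg$tp)
    } else {
      # centred difference, extrapolating linearly past the boundaries
      h <- 0.5
      xm <- max(x - h, state$b1); xp <- min(x + h, state$b2)
      (u(xp) - u(xm)) / (xp - xm)
    }
    p_up <- min(max(0.5 - du / 4, 0), 1)
    tgt_up <- x + 1L; if (tgt_up == cfg$tp) tgt_up <- tgt_up + 1L
    tgt_dn <- x - 1L; if (tgt_dn == cfg$tp) tgt_dn <- tgt_dn - 1L
    if (tgt_up > state$b2) tgt_up <- x
    if (tgt_dn < state$b1) tgt_dn <- x
    P[i, as.character(tgt_up)] <- P[i, as.character(tgt_up)] + p_up
    P[i, as.character(tgt_dn)] <- P[i, as.character(tgt_dn)] + (1 - p_up)
  }
  P
}

# Stationary distribution of a stochastic matrix (left eigenvector).
oracle_stationary <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# Expected dwell duration (in samples) in the set of `open` (rc > tp) or
# closed nodes, starting from the entry node, by absorbing-chain algebra.
oracle_mean_dwell <- function(cfg, state = walker_state(cfg), open = TRUE) {
  P <- oracle_transition_matrix(cfg, state)
  nodes <- as.integer(rownames(P))
  inside <- if (open) nodes > cfg$tp else nodes < cfg$tp
  Q <- P[inside, inside, drop = FALSE]
  t_vec <- solve(diag(nrow(Q)) - Q, rep(1, nrow(Q)))
  entry <- as.character(if (open) cfg$tp + 1L else cfg$tp - 1L)
  unname(t_vec[entry])
}

# Fractional Gaussian noise of Hurst index H by circulant embedding
# (Davies-Harte), an accepted exact synthesis method.
oracle_fgn <- function(n, H) {
  g <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  gv <- g(0:n)
  lam <- Re(stats::fft(c(gv, gv[n:2])))
  stopifnot(all(lam > -1e-8))
  lam <- pmax(lam, 0)
  m <- 2 * n
  W <- complex(m)
  W[1] <- sqrt(lam[1] / m) * rnorm(1)
  W[n + 1] <- sqrt(lam[n + 1] / m) * rnorm(1)
  k <- 2:n
  W[k] <- sqrt(lam[k] / (2 * m)) *
    complex(real = rnorm(n - 1), imaginary = rnorm(n - 1))
  W[m - k + 2] <- Conj(W[k])
  Re(stats::fft(W))[1:n]
}

# Standard-error of a mean from batch means (for autocorrelated series).
batch_se <- function(x, n_batch = 50) {
  m <- floor(length(x) / n_batch)
  bm <- vapply(seq_len(n_batch), function(b) mean(x[((b - 1) * m + 1):(b * m)]), 0)
  sd(bm) / sqrt(n_batch)
}

# Plain two-column view of a dwell series, for attribute-free comparisons.
ds_frame <- function(ds) data.frame(state = as.integer(ds$state),
                                    duration = as.integer(ds$duration))
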