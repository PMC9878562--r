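# Builders for synthetic track fixtures, all generated in code.

make_track <- function(positions, dt = 20, cell_id = "c1", group = "wt",
                       t0 = 0, polarity = NULL) {
  m <- as.matrix(positions)
  if (ncol(m) == 2) m <- cbind(m, 0)
  df <- tibble::tibble(
    cell_id = cell_id, group = group,
    frame = seq_len(nrow(m)) - 1L,
    t = t0 + (seq_len(nrow(m)) - 1L) * dt,
    x = m[, 1], y = m[, 2], z = m[, 3]
  )
  if (!is.null(polarity)) {
    pm <- as.matrix(polarity)
    df$px <- pm[, 1]
    df$py <- pm[, 2]
    df$pz <- pm[, 3]
  }
  as_track_table(df)
}

straight_positions <- function(n, step = c(10, 0, 0), origin = c(0, 0, 0)) {
  t(origin + outer(step, 0:(n - 1)))
}

random_walk_positions <- function(n, sd = 5, origin = c(0, 0, 0)) {
  steps <- matrix(rnorm(3 * (n - 1), 0, sd), ncol = 3)
  rbind(origin, origin + apply(steps, 2, cumsum))
}

# Random rigid motion: rotation about a random axis plus translation.
random_rotation <- function() {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rigid_transform <- function(positions, R = random_rotation(),
                            shift = rnorm(3, 0, 100)) {
  t(R %*% t(as.matrix(positions)) + shift)
}

# Brute-force oracles, deliberately written as plain loops, independent of
# the package's vectorized implementations.
oracle_metrics <- function(pos, dt, v_arrest = 2, eps_path = 1) {
  n <- nrow(pos)
  L <- 0
  arrested <- 0
  for (k in seq_len(n - 1)) {
    d <- sqrt(sum((pos[k + 1, ] - pos[k, ])^2))
    L <- L + d
    if (d / (dt / 60) < v_arrest) arrested <- arrested + 1
  }
  D <- sqrt(sum((pos[n, ] - pos[1, ])^2))
  list(D = D, L = L, v = L / ((n - 1) * dt / 60),
       A = arrested / (n - 1),
       Gamma = if (L >= eps_path) D / L else 0)
}
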