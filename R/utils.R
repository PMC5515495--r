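# Internal helpers shared across modules.

# Deterministic, index-based coordinate jitter used before triangulation so
# that exactly cocircular quadruples are broken reproducibly (no RNG draw).
.tie_jitter <- function(n, eps = 1e-9) {
  i <- seq_len(n)
  jx <- eps * (((i * 2654435761) %% 4294967296) / 4294967296 - 0.5)
  jy <- eps * (((i * 1013904223 + 12345) %% 4294967296) / 4294967296 - 0.5)
  cbind(jx, jy)
}

# Unordered edge key (indices are < 2^20 in any realistic disc).
.edge_key <- function(a, b) {
  pmin(a, b) * 2^21 + pmax(a, b)
}

.disc_centroid <- function(x, y) c(mean(x), mean(y))

# Position of every cell relative to the disc centroid.
.radial_distance <- function(x, y, center = NULL) {
  if (is.null(center)) center <- .disc_centroid(x, y)
  sqrt((x - center[1])^2 + (y - center[2])^2)
}

.assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

# Per-step probability for a first-order rate, exact under dt rescaling.
.rate_to_prob <- function(k, dt) {
  p <- 1 - exp(-k * dt)
  if (any(k * dt < 0)) abort("rate * dt must be non-negative.")
  p
}

# Grouped minimum over integer group ids 1..ng; returns vector of length ng
# with Inf for empty groups. Much faster than tapply for our sizes.
.group_min <- function(values, group, ng) {
  out <- rep(Inf, ng)
  ord <- order(group, values)
  g <- group[ord]
  first <- !duplicated(g)
  out[g[first]] <- values[ord][first]
  out
}

.group_sum <- function(values, group, ng) {
  out <- numeric(ng)
  s <- rowsum(values, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

.group_count <- function(group, ng) {
  tabulate(group, nbins = ng)
}
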