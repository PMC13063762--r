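# Independent oracles, written deliberately naively (scalar, loop-based)
# so they share no code path with the package implementations they check.

# per-gene interaction classification, one gene at a time
oracle_classify_one <- function(h, s, hs, tol = 0.5) {
  to_pex <- function(x) {
    if (x >= 0) 2^x - 1 else -(2^(-x)) + 1
  }
  dev <- to_pex(hs) - (to_pex(h) + to_pex(s))
  if (dev > tol) {
    "enhanced"
  } else if (dev < -tol) {
    "divergent"
  } else {
    "additive"
  }
}

# literal Benjamini-Hochberg step-up: q_(i) = min_{k >= i} p_(k) * m / k,
# capped at 1, returned in input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m / (i:m) * ps[i:m]))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# exact two-sided rank-sum p-value by enumeration of all group assignments
oracle_wilcox_exact <- function(x, y) {
  nx <- length(x)
  vals <- c(x, y)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(length(vals), nx)
  us <- apply(idx, 2, function(j) sum(r[j]) - nx * (nx + 1) / 2)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# small factorial count_matrix built by hand for filter/contrast tests
make_tiny_cm <- function(counts_by_cond, reps = 4L, tissue = "shoot") {
  conds <- names(counts_by_cond)
  mats <- lapply(conds, function(cc) {
    m <- counts_by_cond[[cc]]
    colnames(m) <- paste(tissue, cc, seq_len(ncol(m)), sep = "_")
    m
  })
  counts <- do.call(cbind, mats)
  samples <- data.frame(
    sample_id = colnames(counts),
    condition = rep(conds, vapply(mats, ncol, 1L)),
    tissue = tissue,
    replicate = unlist(lapply(mats, function(m) seq_len(ncol(m)))),
    stringsAsFactors = FALSE
  )
  count_matrix(counts, samples)
}
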