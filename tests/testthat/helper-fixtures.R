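# Shared fixtures: everything is generated in code at test time.

# a small, fast parameter set for pipeline-level tests
tiny_params <- function(seed = 1L, n_per_class = 3L, ...) {
  sim_params(n_events_per_class = n_per_class, seed = seed, ...)
}

# a flat background frame
flat_bg <- function(level = 40, shape = c(128L, 160L)) {
  matrix(level, shape[1], shape[2])
}

# brute-force flood fill (8-connectivity), independent of the package's
# labeling: recursive queue over a logical mask
oracle_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  comps <- list()
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || seen[i, j]) next
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    members <- matrix(integer(), 0, 2)
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      members <- rbind(members, p)
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
            mask[ni, nj] && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          queue[[length(queue) + 1L]] <- c(ni, nj)
        }
      }
    }
    comps[[length(comps) + 1L]] <- members
  }
  comps
}

# exhaustive minimum-total-offset one-to-one assignment for small matching
# problems (<= 10 x 10), used as the pairing oracle
oracle_assignment <- function(to, te, tolerance_s) {
  stopifnot(length(to) <= 10, length(te) <= 10)
  best <- NULL; best_cost <- Inf; best_n <- -1L
  k <- min(length(to), length(te))
  # enumerate injections of the smaller set into the larger
  swap <- length(to) > length(te)
  a <- if (swap) te else to
  b <- if (swap) to else te
  perms <- function(v, m) {
    if (m == 0) return(list(integer()))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i], m - 1)) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  subsets <- utils::combn(seq_along(a), k, simplify = FALSE)
  for (n_pairs in k:0) {
    for (sub in utils::combn(seq_along(a), n_pairs, simplify = FALSE)) {
      for (tgt in perms(seq_along(b), n_pairs)) {
        d <- abs(a[sub] - b[tgt])
        if (all(d <= tolerance_s)) {
          cost <- sum(d)
          if (n_pairs > best_n || (n_pairs == best_n && cost < best_cost)) {
            best_n <- n_pairs; best_cost <- cost
            best <- if (swap) cbind(i = tgt, j = sub) else cbind(i = sub, j = tgt)
          }
        }
      }
    }
    if (best_n == n_pairs && best_n >= 0) break
  }
  best
}
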