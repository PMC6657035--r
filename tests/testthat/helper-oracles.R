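# Independent brute-force oracles used to cross-check the package's
# implementations, plus small fixture builders.

# Medcouple by literal enumeration of the kernel over all (xi <= med <= xj)
# pairs, written independently of ewasrf::medcouple (explicit double loop).
medcouple_bruteforce <- function(x) {
  x <- x[!is.na(x)]
  med <- median(x)
  lo <- sort(x[x <= med])
  hi <- sort(x[x >= med])
  k <- sum(x == med)
  h <- c()
  for (a in seq_along(lo)) {
    for (b in seq_along(hi)) {
      xi <- lo[a]; xj <- hi[b]
      if (xi == med && xj == med) {
        i <- sum(lo[seq_len(a)] == med)   # index among tied values
        j <- sum(hi[seq_len(b)] == med)
        h <- c(h, sign(i + j - 1 - k))
      } else {
        h <- c(h, ((xj - med) - (med - xi)) / (xj - xi))
      }
    }
  }
  median(h)
}

# Exact simplex-constrained least squares by enumerating active sets:
# for every non-empty support S, solve the equality-constrained problem
# min ||A_S w - b|| s.t. sum w = 1 by Lagrange multipliers, keep feasible
# candidates (w >= 0), and return the feasible solution with the smallest
# residual. Exponential in the number of cell types (fine for K <= 7).
simplex_ls_bruteforce <- function(A, b) {
  K <- ncol(A)
  best <- NULL; best_obj <- Inf
  for (size in seq_len(K)) {
    for (S in utils::combn(K, size, simplify = FALSE)) {
      As <- A[, S, drop = FALSE]
      G <- crossprod(As)
      ones <- rep(1, length(S))
      KKT <- rbind(cbind(2 * G, ones), c(ones, 0))
      rhs <- c(2 * crossprod(As, b), 1)
      sol <- tryCatch(solve(KKT, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      w <- sol[seq_along(S)]
      if (any(w < -1e-9)) next
      w <- pmax(w, 0); w <- w / sum(w)
      obj <- sum((As %*% w - b)^2)
      if (obj < best_obj - 1e-12) {
        best_obj <- obj
        best <- numeric(K); best[S] <- w
      }
    }
  }
  best
}

# A small default cohort used across tests where the full 370 x 5000 scale
# is unnecessary.
tiny_cohort <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_samples = 80, n_cpgs = 400, n_discriminating_cpgs_per_type = 8,
         n_planted_cpgs = 5, n_expression_probes = 20, rng_seed = seed),
    list(...))
  generate_cohort(do.call(simulation_config, args))
}
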