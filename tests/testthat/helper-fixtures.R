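# Shared fixtures: small simulated datasets, a desk-scale trunk, and the
# independent linear-programming oracles for the transport tests.

the_bank <- build_code_bank(paper_code())

# small simulated dataset cached per (sessions, trials, snr, jitter, seed)
sim_small <- local({
  cache <- list()
  function(n_sessions = 2L, n_trials = 18L, snr_db = 20, jitter = 0L,
           seed = 11L) {
    key <- paste(n_sessions, n_trials, snr_db, jitter, seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- simulate_epochs(
        sim_config(n_sessions = n_sessions, n_trials_per_session = n_trials,
                   snr_db = snr_db, jitter_samples = jitter, seed = seed),
        the_bank)
    cache[[key]]
  }
})

# a deliberately small trunk for fast network tests (full temporal
# resolution, fewer filters)
tiny_trunk_config <- function()
  trunk_config(spatial_filters = 4L, temporal_kernel1 = 5L,
               temporal_filters1 = 6L, temporal_kernel2 = 5L,
               temporal_filters2 = 8L, dropout1 = 0.1, dropout2 = 0.1,
               resample_to = 252L)

# ---- independent transport oracles ----------------------------------------

# Feasibility of banded transport by Hall's interval condition: mass in any
# source interval must fit inside the R-dilated target interval (and vice
# versa, by symmetry of the bipartite matching condition).
transport_feasible <- function(p, q, R) {
  K <- length(p)
  for (a in seq_len(K)) for (b in a:K) {
    lo <- max(1L, a - R); hi <- min(K, b + R)
    if (sum(p[a:b]) > sum(q[lo:hi]) + 1e-9) return(FALSE)
    if (sum(q[a:b]) > sum(p[lo:hi]) + 1e-9) return(FALSE)
  }
  TRUE
}

# LP duality certificate: given a feasible plan for the banded transport
# problem, build dual potentials u, v on the (connected) support and check
# u_k + v_j <= |k - j| on every admissible arc. If the certificate holds, the
# plan's cost is provably the LP optimum (complementary slackness holds by
# construction). Returns TRUE/FALSE.
certify_optimal <- function(plan, R, tol = 1e-7) {
  K <- nrow(plan)
  sup <- which(plan > 1e-10, arr.ind = TRUE)
  u <- rep(NA_real_, K); v <- rep(NA_real_, K)
  u[sup[1, 1]] <- 0
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(sup))) {
      k <- sup[e, 1]; j <- sup[e, 2]; c <- abs(k - j)
      if (!is.na(u[k]) && is.na(v[j])) { v[j] <- c - u[k]; changed <- TRUE }
      if (is.na(u[k]) && !is.na(v[j])) { u[k] <- c - v[j]; changed <- TRUE }
    }
    if (!changed) break
  }
  # support must be connected (staircase); otherwise no certificate
  if (anyNA(u[unique(sup[, 1])]) || anyNA(v[unique(sup[, 2])])) return(NA)
  u[is.na(u)] <- -Inf; v[is.na(v)] <- -Inf
  for (k in seq_len(K)) for (j in seq_len(K)) {
    if (abs(k - j) > R) next
    if (is.finite(u[k]) && is.finite(v[j]) &&
        u[k] + v[j] > abs(k - j) + tol) return(FALSE)
  }
  TRUE
}

random_pmf <- function(K) {
  v <- stats::runif(K)
  v / sum(v)
}
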