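# Independent reference implementations used as oracles, plus small
# fixture builders.  These are deliberately naive (scalar loops,
# exhaustive enumeration) and share no code with the package internals.

# Naive alternating-update fuzzy c-means, scalar loops throughout.
naive_fcm <- function(x, c, m, init, tol = 1e-6, max_iter = 300L) {
  memb <- function(v) {
    u <- matrix(0, nrow(x), nrow(v))
    for (i in seq_len(nrow(x))) {
      d2 <- numeric(nrow(v))
      for (k in seq_len(nrow(v))) d2[k] <- sum((x[i, ] - v[k, ])^2)
      if (any(d2 < 1e-24)) {
        z <- d2 < 1e-24
        u[i, ] <- z / sum(z)
      } else {
        for (k in seq_len(nrow(v))) {
          u[i, k] <- 1 / sum((d2[k] / d2)^(1 / (m - 1)))
        }
      }
    }
    u
  }
  v <- init
  u <- memb(v)
  obj <- NA_real_
  for (it in seq_len(max_iter)) {
    vnew <- matrix(0, nrow(v), ncol(x))
    for (k in seq_len(nrow(v))) {
      num <- rep(0, ncol(x)); den <- 0
      for (i in seq_len(nrow(x))) {
        num <- num + u[i, k]^m * x[i, ]
        den <- den + u[i, k]^m
      }
      vnew[k, ] <- num / den
    }
    v <- vnew
    unew <- memb(v)
    obj <- 0
    for (i in seq_len(nrow(x))) {
      for (k in seq_len(nrow(v))) {
        obj <- obj + unew[i, k]^m * sum((x[i, ] - v[k, ])^2)
      }
    }
    done <- max(abs(unew - u)) < tol
    u <- unew
    if (done) break
  }
  list(membership = u, centroids = v, objective = obj)
}

# Exhaustive hypergeometric upper tail: enumerate every n-subset of a
# universe of size N whose first K elements are the pathway.
enum_hyper_p <- function(N, K, n, k) {
  combos <- utils::combn(N, n)
  mean(colSums(combos <= K) >= k)
}

# Wrap a plain matrix as a TimeProfile (rows standardized on request).
as_profile <- function(x, timepoints = seq_len(ncol(x)),
                       standardized = FALSE) {
  if (is.null(rownames(x))) rownames(x) <- paste0("m", seq_len(nrow(x)))
  colnames(x) <- as.character(timepoints)
  structure(list(profile = x, timepoints = timepoints,
                 standardized = standardized,
                 dropped_zero_variance = character(0)),
            class = "TimeProfile")
}

# Random standardized profile matrix for fuzz tests.
random_profile <- function(n, p, seed) {
  x <- withr::with_seed(seed, matrix(rnorm(n * p), n, p))
  x <- (x - rowMeans(x)) / apply(x, 1, sd)
  as_profile(x, standardized = TRUE)
}

# Minimal valid study in memory: one ion mode, no noise knobs exposed.
tiny_study <- function(seed = 7L) {
  generate_study(fixture_config("tiny", seed = seed))
}

# Sample metadata for hand-built matrices: n subjects x days, group g.
toy_meta <- function(subjects, days, group = "C", ion = "POS") {
  grid <- expand.grid(subject = subjects, day = days,
                      stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("%s%02d_d%02d", group, grid$subject, grid$day),
    subject_id = sprintf("%s%02d", group, grid$subject),
    group = group, day = grid$day, ion_mode = ion, is_qc = FALSE,
    stringsAsFactors = FALSE)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
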