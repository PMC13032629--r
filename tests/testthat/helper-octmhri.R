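# Independent oracles and small constructors shared across the test files.

# closed-form digital-line oracle: walk the major axis; the minor coordinate
# advances by the rounded ideal offset (ties round down). Derived from the
# line equation, independently of the package's incremental rasterizer.
oracle_line_pixels <- function(r0, c0, r1, c1) {
  dr <- r1 - r0; dc <- c1 - c0
  if (abs(dc) >= abs(dr)) {
    n <- abs(dc); i <- 0:n
    cbind(r0 + sign(dr) * ((2 * i * abs(dr) + n - 1) %/% (2 * n)),
          c0 + sign(dc) * i)
  } else {
    n <- abs(dr); i <- 0:n
    cbind(r0 + sign(dr) * i,
          c0 + sign(dc) * ((2 * i * abs(dc) + n - 1) %/% (2 * n)))
  }
}

# exhaustive pairwise-win AUC oracle (ties count one half)
oracle_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  wins <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(wins)
}

# two-sided Fisher p by hypergeometric enumeration over all tables with the
# observed margins (probability-ordering definition)
oracle_fisher_p <- function(tab) {
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  x <- max(0, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Spearman rho via the classical sum-of-squared-rank-differences formula
# (valid without ties)
oracle_spearman_rho <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# build an octmhri_measurement from raw profile numbers
make_measurement <- function(central = c(100, 120, 150),
                             left = c(40, 55, 70),
                             right = c(60, 72, 90),
                             rpe = c(120, 125, 130)) {
  prof <- function(v) {
    structure(list(min_brightness = v[1], mean_brightness = v[2],
                   max_brightness = v[3], n_samples = 10L),
              class = "octmhri_profile")
  }
  structure(list(central = prof(central), paracentral_left = prof(left),
                 paracentral_right = prof(right), normal_rpe = prof(rpe)),
            class = "octmhri_measurement")
}

# a random valid measurement (min <= mean <= max per region, positive)
random_measurement <- function() {
  reg <- function(lo, hi) sort(runif(3, lo, hi))
  make_measurement(central = reg(80, 255), left = reg(20, 200),
                   right = reg(20, 200), rpe = reg(50, 255))
}

default_phantom <- function(...) generate_bscan(phantom_config(...))
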