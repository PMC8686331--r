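# Independent oracles used across test files.  These deliberately avoid
# the package's vectorized code paths: everything is scalar arithmetic.

# Brute-force scalar re-implementation of one SOM batch update.
oracle_som_batch <- function(inputs, layer, L, sigma, quantile) {
  n_units <- nrow(layer)
  D <- ncol(layer)
  movement <- matrix(0, n_units, D)
  x_new <- inputs
  for (b in seq_len(nrow(inputs))) {
    x <- inputs[b, ]
    d_x <- numeric(n_units)
    for (j in seq_len(n_units)) {
      s <- 0
      for (i in seq_len(D)) s <- s + (x[i] - layer[j, i])^2
      d_x[j] <- sqrt(s)
    }
    winner <- which.min(d_x)
    d_min <- numeric(n_units)
    for (j in seq_len(n_units)) {
      s <- 0
      for (i in seq_len(D)) s <- s + (layer[j, i] - layer[winner, i])^2
      d_min[j] <- sqrt(s)
    }
    S <- sort(d_min)[ceiling(quantile * n_units)]
    feedback <- numeric(D)
    for (j in seq_len(n_units)) {
      decay <- exp(-d_min[j]^2 / (2 * pi * sigma^2))
      sgn <- if (d_min[j] <= S) 1 else -1
      for (i in seq_len(D)) {
        delta_ji <- sgn * L * decay * (layer[j, i] - x[i])
        movement[j, i] <- movement[j, i] - delta_ji
        feedback[i] <- feedback[i] + delta_ji
      }
    }
    x_new[b, ] <- x + feedback
  }
  list(layer = layer + movement, x_new = x_new)
}

# Classical batch SOM step with a purely attractive Gaussian
# neighborhood around the winner (feature-space distances, no lattice).
oracle_vanilla_som <- function(inputs, layer, L, sigma) {
  movement <- layer * 0
  for (b in seq_len(nrow(inputs))) {
    x <- inputs[b, ]
    d_x <- sqrt(rowSums(sweep(layer, 2, x, `-`)^2))
    winner <- which.min(d_x)
    d_min <- sqrt(rowSums(sweep(layer, 2, layer[winner, ], `-`)^2))
    decay <- exp(-d_min^2 / (2 * pi * sigma^2))
    movement <- movement + (L * decay) * sweep(layer, 2, x, `-`) * -1
  }
  layer + movement
}

# Textbook two-group log-rank statistic by explicit risk-set
# tabulation over the pooled distinct event times.
oracle_logrank_2group <- function(time, event, group) {
  group <- as.integer(factor(group))
  stopifnot(all(group %in% 1:2))
  times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Decode an encoded mutation matrix back to its sequence (tests the
# injectivity of the encoding).
oracle_decode <- function(enc) {
  code_of <- function(v) {
    codes <- list(A = c(0, 0), T = c(0, 1), C = c(1, 0), G = c(1, 1),
                  N = c(-1, -1))
    for (nm in names(codes)) if (all(v == codes[[nm]])) return(nm)
    stop("unknown code")
  }
  m <- enc$matrix
  s <- enc$site_row
  n <- nrow(m)
  five <- if (s > 1)
    paste(vapply(seq_len(s - 1), function(i) code_of(m[i, 1:2]),
                 character(1)), collapse = "")
  else ""
  three <- if (s < n)
    paste(vapply((s + 1):n, function(i) code_of(m[i, 1:2]),
                 character(1)), collapse = "")
  else ""
  list(five_prime_flank = five,
       alt_allele = code_of(m[s, 1:2]),
       ref_allele = code_of(m[s, 3:4]),
       three_prime_flank = three)
}

# Random valid mutation sequence with flanks of length f.
random_mutation_sequence <- function(f) {
  bases <- c("A", "C", "G", "T")
  ra <- sample(bases, 2)
  mutation_sequence(
    paste(sample(bases, f, replace = TRUE), collapse = ""),
    ra[1], ra[2],
    paste(sample(bases, f, replace = TRUE), collapse = ""))
}
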