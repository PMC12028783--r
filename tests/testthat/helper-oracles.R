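# Independent brute-force oracles, written step by step from the defining
# formulas with explicit loops. They share no code with the package
# implementations they check.

oracle_entropy_weights <- function(x) {
  m <- nrow(x)
  k <- ncol(x)
  e <- numeric(k)
  for (j in seq_len(k)) {
    s <- sum(x[, j])
    acc <- 0
    for (i in seq_len(m)) {
      p <- x[i, j] / s
      if (p > 0) acc <- acc + p * log(p)
    }
    e[j] <- -acc / log(m)
  }
  d <- 1 - e
  for (j in seq_len(k)) if (max(x[, j]) == min(x[, j])) d[j] <- 0
  d / sum(d)
}

oracle_topsis_closeness <- function(x, w) {
  m <- nrow(x)
  k <- ncol(x)
  v <- matrix(0, m, k)
  for (j in seq_len(k)) {
    nrm <- sqrt(sum(x[, j]^2))
    for (i in seq_len(m)) v[i, j] <- x[i, j] / nrm * w[j]
  }
  ideal <- numeric(k)
  anti <- numeric(k)
  for (j in seq_len(k)) {
    ideal[j] <- max(v[, j])
    anti[j] <- min(v[, j])
  }
  cl <- numeric(m)
  for (i in seq_len(m)) {
    dp <- sqrt(sum((v[i, ] - ideal)^2))
    dm <- sqrt(sum((v[i, ] - anti)^2))
    cl[i] <- dm / (dp + dm)
  }
  cl
}

# Exhaustive span-testing oracle for Duncan's multiple range test: pair
# (i, j) of the descending means is significant iff its gap exceeds the LSR
# for its span AND every enclosing span also exceeds its own LSR. Letters
# come from full enumeration of maximal mutually-non-significant subsets.
oracle_duncan_letters <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  means <- tapply(values, g, mean)
  ns <- tapply(values, g, length)
  k <- length(means)
  sse <- sum(unlist(lapply(split(values, g),
                           function(v) sum((v - mean(v))^2))))
  dfe <- length(values) - k
  mse <- sse / dfe
  nh <- k / sum(1 / ns)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  lsr <- function(p) qtukey((1 - alpha)^(p - 1), p, dfe) * sqrt(mse / nh)
  sig <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s <- (m[i] - m[j]) > lsr(j - i + 1)
      if (s) {
        for (i2 in seq_len(i)) for (j2 in j:k) {
          if ((m[i2] - m[j2]) <= lsr(j2 - i2 + 1)) s <- FALSE
        }
      }
      sig[i, j] <- sig[j, i] <- s
    }
  }
  subsets <- list()
  for (code in seq_len(2^k - 1)) {
    idx <- which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0)
    ok <- TRUE
    if (length(idx) > 1) {
      for (a in idx) for (b in idx) if (a < b && sig[a, b]) ok <- FALSE
    }
    if (ok) subsets[[length(subsets) + 1L]] <- idx
  }
  maximal <- Filter(function(s) !any(vapply(
    subsets, function(t) length(t) > length(s) && all(s %in% t),
    logical(1))), subsets)
  maximal <- maximal[order(vapply(maximal, min, numeric(1)))]
  lett <- stats::setNames(rep("", k), names(m))
  for (s in seq_along(maximal))
    lett[maximal[[s]]] <- paste0(lett[maximal[[s]]], letters[s])
  lett
}

random_positive_matrix <- function(seed) {
  set.seed(seed)
  m <- sample(2:6, 1)
  k <- sample(2:6, 1)
  matrix(runif(m * k, 0.1, 10), m, k)
}
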