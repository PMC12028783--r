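#' One-way ANOVA for a single indicator
#'
#' Classical fixed-effects one-way analysis of variance (between/within
#' mean-square ratio with `(k - 1, N - k)` degrees of freedom), fitted via
#' [stats::aov()]. Returns the pieces the post-hoc layer needs: group means
#' and sizes, the error mean square and its degrees of freedom.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length as `values`; >= 2 groups with
#'   >= 2 replicates each.
#' @return Object of class `anova_oneway`: `F_stat`, `p_value`, `df`,
#'   `group_means`, `group_n`, `mse`, `df_error`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  n_per <- table(groups)
  if (any(n_per < 2)) stop("every group needs >= 2 replicates", call. = FALSE)
  if (length(values) != length(groups))
    stop("values and groups lengths differ", call. = FALSE)
  within_rng <- tapply(values, groups, function(v) diff(range(v)))
  if (all(within_rng == 0))
    stop(structure(class = c("alleloscreen_degenerate_anova",
                             "error", "condition"),
                   list(message = "zero within-group variance: F undefined",
                        call = sys.call(-1))))
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]  # row 1 = groups, last row = residuals
  mse <- tab[nrow(tab), "Mean Sq"]
  structure(list(
    F_stat = tab[1, "F value"], p_value = tab[1, "Pr(>F)"],
    df = c(tab[1, "Df"], tab[nrow(tab), "Df"]),
    group_means = tapply(values, groups, mean),
    group_n = as.integer(n_per), mse = mse,
    df_error = tab[nrow(tab), "Df"]
  ), class = "anova_oneway")
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F_stat, x$p_value))
  invisible(x)
}

# Least significant ranges for spans p = 2..k at protection level
# 1 - (1 - alpha)^(p - 1): studentized-range quantile times sqrt(MSE / n).
duncan_lsr <- function(alpha, k, df_error, mse, n) {
  p <- 2:k
  q <- stats::qtukey((1 - alpha)^(p - 1), p, df_error)
  stats::setNames(c(NA_real_, q * sqrt(mse / n)), as.character(1:k))[-1]
}

#' Duncan's multiple range test with compact letter display
#'
#' Post-hoc mean separation after one-way ANOVA. Means are sorted in
#' descending order; the least significant range (LSR) for a span of `p`
#' means is the studentized-range quantile at protection level
#' `1 - (1 - alpha)^(p - 1)` with `(p, df_error)` times `sqrt(MSE / n)`.
#' Two means are declared different iff their gap exceeds the LSR for their
#' span and no enclosing span is itself non-significant (the standard
#' multiple-range protection rule). Groups are labelled with a compact
#' letter display: groups sharing a letter are not separated at `alpha`.
#' Unbalanced designs use the harmonic mean of group sizes and are flagged.
#'
#' @param values Numeric response vector.
#' @param groups Group labels.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `duncan_mrt`: sorted `means`, `letters` (named by
#'   group), `lsr` per span, the ANOVA fit, `balanced` flag and `alpha`.
#' @export
duncan_mrt <- function(values, groups, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  aov_fit <- anova_oneway(values, groups)
  means <- sort(aov_fit$group_means, decreasing = TRUE)
  k <- length(means)
  balanced <- length(unique(aov_fit$group_n)) == 1L
  n_h <- k / sum(1 / aov_fit$group_n)  # harmonic mean; = n when balanced
  lsr <- duncan_lsr(alpha, k, aov_fit$df_error, aov_fit$mse, n_h)

  # nonsig[i, j]: some span (i', j') enclosing (i, j) has gap <= its LSR.
  # Processing spans largest-first and flooding failures downward implements
  # the protection rule; nonsignificance is closed under sub-spans.
  nonsig <- diag(TRUE, k)
  for (span in k:2) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      if (means[i] - means[j] <= lsr[[as.character(span)]])
        nonsig[i:j, i:j] <- TRUE
    }
  }
  # maximal non-significant intervals of the sorted means -> letters
  jmax <- vapply(seq_len(k), function(i) max(which(nonsig[i, ])), integer(1))
  intervals <- list()
  for (i in seq_len(k)) {
    if (i == 1 || jmax[i] > jmax[i - 1])
      intervals[[length(intervals) + 1L]] <- c(i, jmax[i])
  }
  lett <- rep("", k)
  for (s in seq_along(intervals)) {
    idx <- intervals[[s]][1]:intervals[[s]][2]
    lett[idx] <- paste0(lett[idx], letters[(s - 1) %% 26 + 1])
  }
  structure(list(
    means = means, letters = stats::setNames(lett, names(means)),
    lsr = lsr, alpha = alpha, anova = aov_fit,
    balanced = balanced, n_harmonic = n_h
  ), class = "duncan_mrt")
}

#' @export
print.duncan_mrt <- function(x, digits = 4, ...) {
  cat(sprintf("Duncan's multiple range test (alpha = %g%s)\n", x$alpha,
              if (x$balanced) "" else "; unbalanced, harmonic mean n"))
  print(data.frame(mean = round(x$means, digits), letters = x$letters))
  invisible(x)
}

#' Percent change of a treatment mean versus control
#'
#' `(treatment - control) / control x 100`, the signed percent statistic
#' used to report treatment effects against the control group.
#'
#' @param treatment_mean Treatment mean(s).
#' @param control_mean Control mean(s), strictly positive.
#' @return Signed percent(s).
#' @examples
#' percent_change(2, 1)  # +100
#' @export
percent_change <- function(treatment_mean, control_mean) {
  if (any(control_mean <= 0))
    stop("control mean must be strictly positive", call. = FALSE)
  (treatment_mean - control_mean) / control_mean * 100
}

#' Permutation variable importance for the composite effect
#'
#' Model-agnostic permutation importance of the germination parameters for
#' the composite effect SE (or any numeric response). A random-forest
#' regressor is fitted on a training split; each feature's importance is the
#' mean increase in held-out mean squared error when that feature's column
#' is permuted, averaged over `n_rounds` independent permutations. Ties are
#' broken by feature order.
#'
#' @param features Numeric matrix or data frame (observations x variables),
#'   >= 8 observations.
#' @param response Numeric response, non-constant.
#' @param n_rounds Permutation rounds per variable (default 50).
#' @param ntree Trees in the forest (default 500).
#' @param holdout Fraction of observations held out for the loss estimate
#'   (default 0.3, at least 2 observations).
#' @param seed Optional integer seed for the split, fit and permutations.
#' @return Object of class `importance_ranking`: data frame with `variable`,
#'   `importance` (MSE increase), `rank` (1 = most important), sorted by
#'   rank.
#' @export
importance_ranking <- function(features, response, n_rounds = 50,
                               ntree = 500, holdout = 0.3, seed = NULL) {
  features <- as.data.frame(features)
  n <- nrow(features)
  if (n < 8) stop("need at least 8 observations", call. = FALSE)
  if (length(response) != n)
    stop("response length must match rows of features", call. = FALSE)
  if (stats::sd(response) == 0)
    stop("constant response: importance undefined", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_test <- max(2L, round(holdout * n))
  test_idx <- sample.int(n, n_test)
  train <- features[-test_idx, , drop = FALSE]
  test <- features[test_idx, , drop = FALSE]
  y_train <- response[-test_idx]
  y_test <- response[test_idx]
  fit <- randomForest::randomForest(x = train, y = y_train, ntree = ntree)
  base_mse <- mean((stats::predict(fit, test) - y_test)^2)
  imp <- vapply(seq_along(features), function(j) {
    inc <- vapply(seq_len(n_rounds), function(r) {
      perm <- test
      perm[[j]] <- perm[[j]][sample.int(n_test)]
      mean((stats::predict(fit, perm) - y_test)^2) - base_mse
    }, numeric(1))
    mean(inc)
  }, numeric(1))
  ord <- order(-imp, seq_along(imp))
  out <- data.frame(variable = names(features)[ord],
                    importance = imp[ord],
                    rank = seq_along(imp), stringsAsFactors = FALSE)
  structure(out, class = c("importance_ranking", "data.frame"),
            base_mse = base_mse, n_rounds = n_rounds)
}

#' @export
print.importance_ranking <- function(x, digits = 4, ...) {
  cat("Permutation variable importance (held-out MSE increase,",
      attr(x, "n_rounds"), "rounds)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

# Average technical replicates into one value per (treatment, bio_rep,
# indicator) and pivot to a samples x indicators matrix.
physio_bio_matrix <- function(physio) {
  need <- c("treatment", "bio_rep", "indicator", "value")
  if (!all(need %in% names(physio)))
    stop("physiology table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  agg <- stats::aggregate(value ~ treatment + bio_rep + indicator,
                          data = physio, FUN = mean)
  wide <- stats::reshape(agg, idvar = c("treatment", "bio_rep"),
                         timevar = "indicator", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide
}

#' PCA of the physiological indicator profiles
#'
#' Technical replicates are averaged into biological replicates; indicators
#' are standardized to zero mean and unit variance (heterogeneous assay
#' units), and the correlation-matrix eigendecomposition is taken via
#' [stats::prcomp()]. Zero-variance indicators are dropped with a warning.
#' Components follow a deterministic sign convention: the largest-magnitude
#' loading of each component is made positive.
#'
#' @param physio Long physiology table (treatment, bio_rep, tech_rep,
#'   indicator, value).
#' @return Object of class `pca_profiles`: `scores` (samples x components,
#'   with treatment labels), `loadings`, `var_explained` (fractions summing
#'   to 1), `group_centroids`.
#' @export
pca_profiles <- function(physio) {
  wide <- physio_bio_matrix(physio)
  mat <- as.matrix(wide[, setdiff(names(wide), c("treatment", "bio_rep")),
                        drop = FALSE])
  if (nrow(mat) < 2 || ncol(mat) < 2)
    stop("need >= 2 samples and >= 2 indicators", call. = FALSE)
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance indicator(s): ",
            paste(colnames(mat)[sds == 0], collapse = ", "))
    mat <- mat[, sds > 0, drop = FALSE]
    if (ncol(mat) < 2) stop("fewer than 2 informative indicators", call. = FALSE)
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(pc$rotation))) {
    lead <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[lead, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  centroids <- stats::aggregate(pc$x, by = list(treatment = wide$treatment),
                                FUN = mean)
  structure(list(
    scores = data.frame(treatment = wide$treatment, bio_rep = wide$bio_rep,
                        pc$x, stringsAsFactors = FALSE),
    loadings = pc$rotation,
    var_explained = stats::setNames(ve, colnames(pc$x)),
    group_centroids = centroids
  ), class = "pca_profiles")
}

#' @export
print.pca_profiles <- function(x, ...) {
  ve <- x$var_explained
  cat(sprintf("PCA of physiological profiles: %d samples, %d indicators\n",
              nrow(x$scores), nrow(x$loadings)))
  cat(sprintf("Dim.1 + Dim.2 explain %.1f%% (%.1f%% + %.1f%%)\n",
              100 * sum(ve[1:2]), 100 * ve[1], 100 * ve[2]))
  invisible(x)
}

#' Radar-chart profile of indicator means
#'
#' Per-indicator min-max scaling of treatment means to `[0, 1]` across
#' treatments, the normalization used to overlay indicators with different
#' units on one radar chart. A constant indicator maps every treatment to
#' 0.5 with a warning.
#'
#' @param physio Long physiology table (treatment, indicator, value, plus
#'   any replicate columns, which are averaged out).
#' @return Tidy data frame: treatment, indicator, value (scaled to `[0, 1]`).
#' @export
radar_profile <- function(physio) {
  need <- c("treatment", "indicator", "value")
  if (!all(need %in% names(physio)))
    stop("physiology table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  agg <- stats::aggregate(value ~ treatment + indicator, data = physio,
                          FUN = mean)
  if (length(unique(agg$treatment)) < 2)
    stop("need >= 2 treatments per indicator", call. = FALSE)
  out <- do.call(rbind, lapply(split(agg, agg$indicator), function(s) {
    rng <- diff(range(s$value))
    if (rng == 0) {
      warning("constant indicator '", s$indicator[1],
              "': all treatments mapped to 0.5")
      s$value <- 0.5
    } else {
      s$value <- (s$value - min(s$value)) / rng
    }
    s
  }))
  rownames(out) <- NULL
  out[order(out$treatment, out$indicator), ]
}
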