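as_decision_matrix <- function(x) {
  if (is.data.frame(x)) {
    lbl_col <- which(!vapply(x, is.numeric, logical(1)))
    if (length(lbl_col) > 1)
      stop("decision matrix data frame may have at most one label column",
           call. = FALSE)
    labels <- if (length(lbl_col)) as.character(x[[lbl_col]]) else NULL
    x <- as.matrix(x[vapply(x, is.numeric, logical(1))])
    if (!is.null(labels)) rownames(x) <- labels
  }
  if (!is.matrix(x) || !is.numeric(x))
    stop("decision matrix must be numeric", call. = FALSE)
  if (anyNA(x)) stop("decision matrix has missing cells", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- paste0("A", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("C", seq_len(ncol(x)))
  x
}

# Shift rule for columns that are not strictly positive: entropy proportions
# need ln of positive numbers. Each offending column is shifted by
# |min| + 1e-6 * range (or +1 if the column is constant at <= 0).
shift_positive <- function(x) {
  shifted <- character(0)
  for (j in seq_len(ncol(x))) {
    cj <- x[, j]
    if (min(cj) <= 0) {
      rng <- diff(range(cj))
      eps <- if (rng > 0) 1e-6 * rng else 1
      x[, j] <- cj + abs(min(cj)) + eps
      shifted <- c(shifted, colnames(x)[j])
    }
  }
  if (length(shifted))
    warning("column(s) shifted to positivity for entropy weighting: ",
            paste(shifted, collapse = ", "))
  x
}

#' Entropy weights for a decision matrix
#'
#' Objective criterion weights from Shannon entropy of each criterion's
#' column proportions: with `m` alternatives and `p_ij = x_ij / sum_i x_ij`,
#' the normalized entropy is `e_j = -(1/ln m) sum_i p_ij ln p_ij` (with
#' `0 ln 0 = 0`), the information divergence `d_j = 1 - e_j`, and the weight
#' `w_j = d_j / sum_j d_j`. A criterion constant across alternatives carries
#' no information and gets weight exactly 0. Non-positive cells are shifted
#' (see Details of [topsis_rank()]).
#'
#' @param x Numeric matrix or data frame, alternatives in rows, criteria in
#'   columns; at least 2 alternatives.
#' @param uniform_fallback If all criteria are constant (total divergence
#'   0), fall back to uniform weights instead of erroring.
#' @return Named weight vector summing to 1, with attributes `entropy` and
#'   `divergence`.
#' @examples
#' entropy_weights(cbind(a = c(1, 1), b = c(1, 3)))  # (0, 1)
#' @export
entropy_weights <- function(x, uniform_fallback = FALSE) {
  x <- as_decision_matrix(x)
  m <- nrow(x)
  if (m < 2) stop("need at least 2 alternatives", call. = FALSE)
  x <- shift_positive(x)
  p <- sweep(x, 2, colSums(x), "/")
  plogp <- ifelse(p > 0, p * log(p), 0)
  e <- -colSums(plogp) / log(m)
  # columns constant across alternatives have p = 1/m exactly -> e = 1
  const <- apply(x, 2, function(c) diff(range(c)) == 0)
  e[const] <- 1
  d <- 1 - e
  d[d < 0] <- 0  # guard tiny negative from rounding
  if (sum(d) == 0) {
    if (uniform_fallback) {
      w <- rep(1 / ncol(x), ncol(x))
    } else {
      stop(structure(class = c("alleloscreen_degenerate_weights",
                               "error", "condition"),
                     list(message = paste("all criteria constant across",
                          "alternatives; set uniform_fallback = TRUE for",
                          "uniform weights"), call = sys.call(-1))))
    }
  } else {
    w <- d / sum(d)
  }
  names(w) <- colnames(x)
  attr(w, "entropy") <- stats::setNames(e, colnames(x))
  attr(w, "divergence") <- stats::setNames(unname(d), colnames(x))
  w
}

#' TOPSIS ranking of alternatives
#'
#' Technique for Order of Preference by Similarity to Ideal Solution. Each
#' criterion column is normalized (classical vector normalization by its
#' Euclidean norm, or min-max on request), multiplied by its weight, and
#' each alternative's Euclidean distances `d+` / `d-` to the ideal and
#' anti-ideal points are combined into the relative closeness
#' `c = d- / (d+ + d-)`, in `[0, 1]`. Alternatives are ranked by descending
#' closeness; ties are broken by input order and reported.
#'
#' @details Weights default to [entropy_weights()] of the matrix. The ideal
#'   point takes the per-criterion maximum for benefit criteria and minimum
#'   for cost criteria (`benefit = FALSE`); with min-max normalization cost
#'   columns are direction-flipped during scaling. Non-positive cells are
#'   shifted by `|column min| + 1e-6 x column range` before entropy
#'   weighting, with a warning.
#'
#' @param x Numeric matrix or data frame (alternatives x criteria).
#' @param weights Per-criterion nonnegative weights; normalized to sum 1.
#'   `NULL` (default) uses entropy weights.
#' @param benefit Logical, recycled per criterion: `TRUE` = larger is
#'   better. Default all benefit.
#' @param normalization `"vector"` (default) or `"minmax"`.
#' @return Object of class `topsis`: weights, `d_plus`, `d_minus`,
#'   `closeness`, per-alternative `rank`, `ranking` (labels best to worst),
#'   and tie information.
#' @examples
#' topsis_rank(rbind(A = c(1, 1), B = c(2, 2), C = c(3, 3)),
#'             weights = c(0.5, 0.5))
#' @export
topsis_rank <- function(x, weights = NULL, benefit = TRUE,
                        normalization = c("vector", "minmax")) {
  normalization <- match.arg(normalization)
  x <- as_decision_matrix(x)
  n <- ncol(x)
  benefit <- rep_len(as.logical(benefit), n)
  if (is.null(weights)) weights <- entropy_weights(x)
  if (length(weights) != n)
    stop("weights length must match the number of criteria", call. = FALSE)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (sum(weights) == 0) stop("weights sum to 0", call. = FALSE)
  w <- as.numeric(weights) / sum(weights)

  if (normalization == "vector") {
    norms <- sqrt(colSums(x^2))
    if (any(norms == 0)) stop("zero column cannot be vector-normalized",
                              call. = FALSE)
    r <- sweep(x, 2, norms, "/")
    eff_benefit <- benefit
  } else {
    r <- x
    for (j in seq_len(n)) {
      rng <- diff(range(x[, j]))
      r[, j] <- if (rng == 0) 0.5 else if (benefit[j])
        (x[, j] - min(x[, j])) / rng else (max(x[, j]) - x[, j]) / rng
    }
    eff_benefit <- rep(TRUE, n)  # direction folded into the scaling
  }
  v <- sweep(r, 2, w, "*")
  ideal <- vapply(seq_len(n), function(j)
    if (eff_benefit[j]) max(v[, j]) else min(v[, j]), numeric(1))
  anti <- vapply(seq_len(n), function(j)
    if (eff_benefit[j]) min(v[, j]) else max(v[, j]), numeric(1))
  d_plus <- sqrt(rowSums(sweep(v, 2, ideal, "-")^2))
  d_minus <- sqrt(rowSums(sweep(v, 2, anti, "-")^2))
  denom <- d_plus + d_minus
  closeness <- ifelse(denom == 0, 0.5, d_minus / denom)
  ord <- order(-closeness, seq_along(closeness))  # stable: ties by input order
  rank <- match(seq_along(closeness), ord)
  ties <- unname(closeness[duplicated(closeness)])
  structure(list(
    alternatives = rownames(x), criteria = colnames(x),
    weights = stats::setNames(w, colnames(x)),
    normalization = normalization, benefit = benefit,
    d_plus = stats::setNames(d_plus, rownames(x)),
    d_minus = stats::setNames(d_minus, rownames(x)),
    closeness = stats::setNames(closeness, rownames(x)),
    rank = stats::setNames(rank, rownames(x)),
    ranking = rownames(x)[ord],
    tied_closeness = unique(ties)
  ), class = "topsis")
}

#' @export
print.topsis <- function(x, digits = 4, ...) {
  cat("TOPSIS ranking (", x$normalization, " normalization, ",
      length(x$alternatives), " alternatives x ", length(x$criteria),
      " criteria)\n", sep = "")
  tab <- data.frame(alternative = x$alternatives,
                    d_plus = x$d_plus, d_minus = x$d_minus,
                    closeness = x$closeness, rank = x$rank)
  tab <- tab[order(tab$rank), ]
  print(format(tab, digits = digits), row.names = FALSE)
  if (length(x$tied_closeness))
    cat("note: tied closeness values present; ties broken by input order\n")
  cat("weights:", paste(sprintf("%s=%.*f", names(x$weights), digits,
                                x$weights), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.topsis <- function(object, ...) {
  cat("best alternative:", object$ranking[1],
      sprintf("(closeness %.4f)\n", max(object$closeness)))
  print(object, ...)
  invisible(object)
}
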