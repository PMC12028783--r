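#' Germination percentage
#'
#' Fraction of seeds germinated by day 7: `n7 / n_total`. Stored as a
#' fraction in `[0, 1]`; multiply by 100 to render as percent.
#'
#' @param n7 Seeds germinated by day 7 (vectorized).
#' @param n_total Total seeds sown (> 0).
#' @return Numeric fraction(s) in `[0, 1]`.
#' @examples
#' germination_percentage(27, 30)  # 0.9
#' @export
germination_percentage <- function(n7, n_total) {
  if (any(n_total <= 0)) stop("n_total must be > 0", call. = FALSE)
  if (any(n7 < 0) || any(n7 > n_total))
    stop("need 0 <= n7 <= n_total", call. = FALSE)
  n7 / n_total
}

#' Germination potential
#'
#' Fraction of seeds germinated by day 3 (early vigor): `n3 / n_total`.
#' Always less than or equal to the germination percentage computed from the
#' same dishes, because a day-3 germinated seed is also germinated by day 7.
#'
#' @param n3 Seeds germinated by day 3 (vectorized).
#' @param n_total Total seeds sown (> 0).
#' @return Numeric fraction(s) in `[0, 1]`.
#' @export
germination_potential <- function(n3, n_total) {
  if (any(n_total <= 0)) stop("n_total must be > 0", call. = FALSE)
  if (any(n3 < 0) || any(n3 > n_total))
    stop("need 0 <= n3 <= n_total", call. = FALSE)
  n3 / n_total
}

#' Simple vigor index (SVI)
#'
#' `SVI = germination percentage x seedling height x 100`, with the
#' germination percentage as a fraction and height in cm, giving percent
#' points x cm. SVI is 0 whenever nothing germinated. Any constant rescaling
#' of the units cancels in the downstream allelopathy index, which is a
#' ratio.
#'
#' @param germination_percentage Fraction(s) in `[0, 1]`.
#' @param mean_height_cm Mean seedling height(s), cm, >= 0.
#' @return Nonnegative numeric.
#' @examples
#' simple_vigor_index(0.9, 2.5)  # 225
#' @export
simple_vigor_index <- function(germination_percentage, mean_height_cm) {
  if (any(germination_percentage < 0) || any(mean_height_cm < 0, na.rm = TRUE))
    stop("inputs must be nonnegative", call. = FALSE)
  h <- ifelse(germination_percentage == 0 & is.na(mean_height_cm),
              0, mean_height_cm)
  germination_percentage * h * 100
}

#' Per-treatment germination metrics
#'
#' Computes the six germination parameters per treatment from dish-level
#' counts and per-seedling morphometrics: germination percentage,
#' germination potential, radicle length, germ length, seedling height, and
#' SVI. Metrics are computed per dish and averaged with equal dish weights,
#' so the replication unit downstream (ANOVA) is the dish. Dishes with no
#' germinated seed contribute 0 to SVI and are excluded from morphometric
#' means (no seedlings exist).
#'
#' @param dishes Data frame with columns treatment, dish_id, n_total, n3, n7.
#' @param seedlings Data frame with columns treatment, dish_id, radicle_mm,
#'   germ_mm, height_cm (one row per seedling).
#' @return Object of class `germination_metrics`: a list with `treatment`
#'   (one row per treatment, the six parameter means) and `dish` (tidy
#'   per-dish values: treatment, dish_id, parameter, value).
#' @export
summarize_treatments <- function(dishes, seedlings) {
  need <- c("treatment", "dish_id", "n_total", "n3", "n7")
  if (!all(need %in% names(dishes)))
    stop("dishes must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(dishes$n3 > dishes$n7) || any(dishes$n7 > dishes$n_total) ||
      any(dishes$n3 < 0))
    stop("counts must satisfy 0 <= n3 <= n7 <= n_total", call. = FALSE)
  if (anyDuplicated(dishes[c("treatment", "dish_id")]))
    stop("duplicated (treatment, dish_id) rows", call. = FALSE)

  key <- paste(dishes$treatment, dishes$dish_id, sep = "\r")
  morpho <- c("radicle_mm", "germ_mm", "height_cm")
  dish_morpho <- matrix(NA_real_, nrow(dishes), 3,
                        dimnames = list(NULL, morpho))
  if (nrow(seedlings)) {
    skey <- paste(seedlings$treatment, seedlings$dish_id, sep = "\r")
    if (!all(skey %in% key))
      stop("seedlings reference a (treatment, dish_id) absent from dishes",
           call. = FALSE)
    for (m in morpho) {
      agg <- tapply(seedlings[[m]], skey, mean)
      dish_morpho[, m] <- unname(agg[key])
    }
  }
  gp <- germination_percentage(dishes$n7, dishes$n_total)
  pot <- germination_potential(dishes$n3, dishes$n_total)
  svi <- simple_vigor_index(gp, dish_morpho[, "height_cm"])
  dish_wide <- data.frame(
    treatment = dishes$treatment, dish_id = dishes$dish_id,
    germination_percentage = gp, germination_potential = pot,
    radicle_mm = dish_morpho[, "radicle_mm"],
    germ_mm = dish_morpho[, "germ_mm"],
    height_cm = dish_morpho[, "height_cm"],
    svi = svi, stringsAsFactors = FALSE)

  params <- germination_parameters()
  dish_tidy <- do.call(rbind, lapply(params, function(p) {
    data.frame(treatment = dish_wide$treatment, dish_id = dish_wide$dish_id,
               parameter = p, value = dish_wide[[p]], stringsAsFactors = FALSE)
  }))
  trt_levels <- unique(dishes$treatment)
  trt <- do.call(rbind, lapply(trt_levels, function(g) {
    sub <- dish_wide[dish_wide$treatment == g, , drop = FALSE]
    vals <- vapply(params, function(p) mean(sub[[p]], na.rm = TRUE), numeric(1))
    cbind(data.frame(treatment = g, stringsAsFactors = FALSE),
          as.data.frame(as.list(vals)))
  }))
  rownames(trt) <- NULL
  structure(list(treatment = trt, dish = dish_tidy, dish_wide = dish_wide),
            class = "germination_metrics")
}

#' The six germination parameters of the screen
#'
#' @return Character vector naming the parameters in panel order.
#' @export
germination_parameters <- function() {
  c("germination_percentage", "germination_potential",
    "radicle_mm", "germ_mm", "height_cm", "svi")
}

#' @export
print.germination_metrics <- function(x, digits = 3, ...) {
  cat("Germination metrics for", nrow(x$treatment), "groups",
      sprintf("(%d dishes)\n", nrow(x$dish_wide)))
  print(format(x$treatment, digits = digits), row.names = FALSE)
  invisible(x)
}
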