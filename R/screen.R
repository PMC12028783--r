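#' Fit a full allelopathy screen
#'
#' The package's main entry point: from dish-level germination counts,
#' per-seedling morphometrics and (optionally) physiological measurements,
#' computes the six germination parameters per treatment, the allelopathy
#' index RI and composite effect SE versus the control, an entropy-weighted
#' TOPSIS ranking of the treatments, per-parameter one-way ANOVA with
#' Duncan's multiple range test letters, permutation variable importance of
#' the parameters for SE, and (when physiology is supplied) PCA and radar
#' profiles of the indicators.
#'
#' @param germination Data frame of dish counts (treatment, dish_id,
#'   n_total, n3, n7).
#' @param seedlings Data frame of per-seedling morphometrics (treatment,
#'   dish_id, radicle_mm, germ_mm, height_cm).
#' @param physiology Optional long physiology table (treatment, bio_rep,
#'   tech_rep, indicator, value).
#' @param control Control group label (default `"CK"`).
#' @param alpha Significance level for ANOVA / Duncan letters.
#' @param parameters Parameter set entering SE and TOPSIS; defaults to the
#'   six germination parameters.
#' @param ri_level `"treatment"` or `"dish"`; see [score_allelopathy()].
#' @param normalization TOPSIS normalization scheme; see [topsis_rank()].
#' @param importance Logical: compute permutation importance of the
#'   parameters for SE (needs >= 8 treatments; skipped with a message
#'   otherwise).
#' @param seed Optional seed for the importance forest.
#' @return Object of class `allelo_screen` with components `metrics`,
#'   `allelopathy`, `topsis`, `comparisons` (per-parameter Duncan results),
#'   `importance`, `pca`, `radar`.
#' @examples
#' d <- allelo_design(treatments = c("T1", "T2"), dishes_per_treatment = 4,
#'                    seed = 11)
#' eff <- list(CK = treatment_effect(0.8), T1 = treatment_effect(0.95,
#'             mean_height_cm = 3.3), T2 = treatment_effect(0.7))
#' sim <- simulate_germination(d, eff)
#' scr <- allelo_screen(sim$dishes, sim$seedlings, control = "CK")
#' print(scr)
#' @export
allelo_screen <- function(germination, seedlings, physiology = NULL,
                          control = "CK", alpha = 0.05,
                          parameters = germination_parameters(),
                          ri_level = c("treatment", "dish"),
                          normalization = c("vector", "minmax"),
                          importance = TRUE, seed = NULL) {
  ri_level <- match.arg(ri_level)
  normalization <- match.arg(normalization)
  if (!control %in% germination$treatment)
    stop(structure(class = c("alleloscreen_missing_control",
                             "error", "condition"),
                   list(message = paste0("control group '", control,
                                         "' absent from germination data"),
                        call = sys.call())))
  metrics <- summarize_treatments(germination, seedlings)
  allelo <- score_allelopathy(metrics, control = control,
                              parameters = parameters, level = ri_level)
  trt_tab <- metrics$treatment[metrics$treatment$treatment != control, ,
                               drop = FALSE]
  dm <- as.matrix(trt_tab[, parameters, drop = FALSE])
  rownames(dm) <- trt_tab$treatment
  tops <- topsis_rank(dm, normalization = normalization)

  comparisons <- lapply(parameters, function(p) {
    dw <- metrics$dish_wide
    ok <- !is.na(dw[[p]])
    tryCatch(duncan_mrt(dw[[p]][ok], dw$treatment[ok], alpha = alpha),
             error = function(e) e)
  })
  names(comparisons) <- parameters

  imp <- NULL
  if (isTRUE(importance)) {
    ri_wide <- stats::reshape(allelo$ri, idvar = "treatment",
                              timevar = "parameter", direction = "wide")
    feat <- ri_wide[, -1, drop = FALSE]
    names(feat) <- sub("^ri\\.", "", names(feat))
    if (nrow(feat) >= 8) {
      imp <- importance_ranking(feat, allelo$se$se, seed = seed)
    } else {
      message("importance skipped: fewer than 8 treatments")
    }
  }
  pca <- radar <- NULL
  if (!is.null(physiology) && nrow(physiology)) {
    pca <- pca_profiles(physiology)
    radar <- radar_profile(physiology)
  }
  structure(list(
    metrics = metrics, allelopathy = allelo, topsis = tops,
    comparisons = comparisons, importance = imp, pca = pca, radar = radar,
    control = control, alpha = alpha, parameters = parameters
  ), class = "allelo_screen")
}

#' @export
print.allelo_screen <- function(x, ...) {
  k <- nrow(x$allelopathy$se)
  cat("Allelopathy screen:", k, "treatments vs control", x$control, "\n")
  top <- x$allelopathy$se[x$allelopathy$se$rank == 1, ]
  cat(sprintf("  strongest composite effect: %s (SE = %.4f)\n",
              top$treatment, top$se))
  cat("  TOPSIS ranking:", paste(x$topsis$ranking, collapse = " > "), "\n")
  invisible(x)
}

#' @export
summary.allelo_screen <- function(object, digits = 4, ...) {
  print(object)
  cat("\nComposite effect (SE), best to worst:\n")
  se <- object$allelopathy$se
  se <- se[order(se$rank), ]
  se$effect <- ifelse(se$se > 0, "stimulatory",
                      ifelse(se$se < 0, "inhibitory", "neutral"))
  print(format(se, digits = digits), row.names = FALSE)
  cat("\nTOPSIS closeness:\n")
  print(round(sort(object$topsis$closeness, decreasing = TRUE), digits))
  cat("\nDuncan letters (alpha =", object$alpha, "):\n")
  for (p in object$parameters) {
    cmp <- object$comparisons[[p]]
    if (inherits(cmp, "duncan_mrt"))
      cat(sprintf("  %-24s %s\n", p,
                  paste(names(cmp$letters), cmp$letters, sep = ":",
                        collapse = " ")))
  }
  if (!is.null(object$importance)) {
    cat("\nParameter importance for SE:\n")
    print.data.frame(object$importance, digits = digits, row.names = FALSE)
  }
  if (!is.null(object$pca)) print(object$pca)
  invisible(object)
}

#' @export
plot.allelo_screen <- function(x, ...) {
  se <- x$allelopathy$se
  se <- se[order(se$rank, decreasing = TRUE), ]
  graphics::barplot(se$se, names.arg = se$treatment, horiz = TRUE, las = 1,
                    xlab = "comprehensive effect (SE)",
                    col = ifelse(se$se >= 0, "darkseagreen3", "indianred3"),
                    main = "Composite allelopathic effect by treatment", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
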