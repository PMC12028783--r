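#' Allelopathy response index (RI)
#'
#' Asymmetric ratio comparing a treatment value `T` to the control value `C`:
#' `(T - C) / T` when `T >= C`, `(T - C) / C` when `T < C`. Positive values
#' indicate stimulation, negative values inhibition; the index is bounded in
#' `(-1, 1]` for nonnegative inputs (it reaches -1 exactly when `T = 0`) and
#' is invariant to rescaling both values by the same positive constant.
#'
#' @param t Treatment value(s), >= 0.
#' @param c Control value(s), >= 0. `t` and `c` must not both be zero in any
#'   position.
#' @return Numeric vector of indices.
#' @examples
#' allelopathy_index(4, 2)   #  0.5
#' allelopathy_index(1, 2)   # -0.5
#' allelopathy_index(0, 5)   # -1
#' @export
allelopathy_index <- function(t, c) {
  if (any(t < 0, na.rm = TRUE) || any(c < 0, na.rm = TRUE))
    stop("treatment and control values must be nonnegative", call. = FALSE)
  if (any(t == 0 & c == 0, na.rm = TRUE))
    stop("allelopathy index undefined when treatment and control are both 0",
         call. = FALSE)
  ifelse(t >= c, (t - c) / t, (t - c) / c)
}

#' Comprehensive allelopathic effect (SE)
#'
#' Arithmetic mean of a treatment's RI values across the test parameters.
#' `SE > 0` marks a net-stimulatory treatment, `SE < 0` net-inhibitory.
#'
#' @param ri Nonempty numeric vector of RI values; `NA`s (undefined cells)
#'   are dropped with a warning.
#' @return Single numeric mean.
#' @export
comprehensive_effect <- function(ri) {
  if (length(ri) == 0L)
    stop("need at least one RI value", call. = FALSE)
  if (anyNA(ri)) {
    warning("dropping ", sum(is.na(ri)), " undefined RI value(s) from SE")
    ri <- ri[!is.na(ri)]
    if (!length(ri)) stop("all RI values undefined", call. = FALSE)
  }
  mean(ri)
}

#' Score a whole screen: RI per (treatment, parameter) and SE per treatment
#'
#' Vectorizes the allelopathy index over every treatment and germination
#' parameter against the control, then averages each treatment's RI values
#' into its comprehensive effect SE and ranks treatments by SE. By default
#' RI is computed on treatment-level means (the index is defined on a single
#' treatment/control value pair); `level = "dish"` instead computes RI per
#' dish against the control mean and averages, which propagates dish
#' replication into the index. Cells where treatment and control are both 0
#' become `NA` with a warning and are excluded from SE.
#'
#' @param metrics A [summarize_treatments()] result (or its `treatment` data
#'   frame).
#' @param control Control group label.
#' @param parameters Parameter columns to score; defaults to the six
#'   germination parameters.
#' @param level `"treatment"` (default) or `"dish"`.
#' @return Object of class `allelopathy_table`: list with `ri` (treatment,
#'   parameter, ri), `se` (treatment, se, rank; rank 1 = largest SE), the
#'   parameter set, and the computation level.
#' @export
score_allelopathy <- function(metrics, control = "CK",
                              parameters = germination_parameters(),
                              level = c("treatment", "dish")) {
  level <- match.arg(level)
  trt_tab <- if (inherits(metrics, "germination_metrics")) metrics$treatment
             else metrics
  if (!control %in% trt_tab$treatment)
    stop("control group '", control, "' not found", call. = FALSE)
  missing_p <- setdiff(parameters, names(trt_tab))
  if (length(missing_p))
    stop("parameter(s) absent from metrics: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  treatments <- setdiff(trt_tab$treatment, control)
  ctrl_means <- vapply(parameters, function(p)
    trt_tab[[p]][trt_tab$treatment == control], numeric(1))

  one_ri <- function(tv, cv) {
    if (tv == 0 && cv == 0) {
      warning("RI undefined (treatment and control both 0); cell set to NA")
      return(NA_real_)
    }
    allelopathy_index(tv, cv)
  }
  rows <- list()
  for (g in treatments) {
    for (p in parameters) {
      if (level == "treatment") {
        ri <- one_ri(trt_tab[[p]][trt_tab$treatment == g], ctrl_means[[p]])
      } else {
        dw <- metrics$dish_wide
        vals <- dw[[p]][dw$treatment == g]
        vals <- vals[!is.na(vals)]
        ri <- mean(vapply(vals, one_ri, numeric(1), cv = ctrl_means[[p]]))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = g, parameter = p, ri = ri, stringsAsFactors = FALSE)
    }
  }
  ri_tab <- do.call(rbind, rows)
  se <- vapply(treatments, function(g)
    comprehensive_effect(ri_tab$ri[ri_tab$treatment == g]), numeric(1))
  ord <- order(-se, match(treatments, treatments))
  se_tab <- data.frame(treatment = treatments, se = unname(se),
                       rank = match(seq_along(treatments), ord),
                       stringsAsFactors = FALSE)
  structure(list(ri = ri_tab, se = se_tab, parameters = parameters,
                 control = control, level = level),
            class = "allelopathy_table")
}

#' @export
print.allelopathy_table <- function(x, digits = 4, ...) {
  cat("Allelopathy scores vs", x$control,
      sprintf("(RI on %s-level values)\n", x$level))
  tab <- x$se[order(x$se$rank), ]
  tab$effect <- ifelse(tab$se > 0, "stimulatory",
                       ifelse(tab$se < 0, "inhibitory", "neutral"))
  print(format(tab, digits = digits), row.names = FALSE)
  invisible(x)
}
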