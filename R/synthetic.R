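#' Physiological indicators tracked by the screen
#'
#' The closed set of reactive-oxygen, antioxidant-system and osmolyte
#' indicators used throughout the physiology layer: superoxide anion
#' (`O2_minus`), hydroxyl radical (`OH_radical`), hydrogen peroxide (`H2O2`),
#' malondialdehyde (`MDA`), the antioxidant enzymes SOD, POD, CAT, APX and GR,
#' ascorbate (`ASA`) and dehydroascorbate (`DHA`), and the osmotic-adjustment
#' substances proline (`Pro`), soluble sugars (`SS`) and soluble proteins
#' (`SP`).
#'
#' @return Character vector of the 14 indicator labels.
#' @export
physio_indicators <- function() {
  c("O2_minus", "OH_radical", "H2O2", "MDA",
    "SOD", "POD", "CAT", "APX", "GR",
    "ASA", "DHA", "Pro", "SS", "SP")
}

#' Default control-level means for the physiological indicators
#'
#' Plausible assay-scale magnitudes for an unstressed control, one per
#' indicator in [physio_indicators()]. Units differ per indicator
#' (production rates, contents, enzyme activities); downstream analysis
#' standardizes per indicator, so only relative treatment effects matter.
#'
#' @return Named numeric vector (length 14, all positive).
#' @export
default_physio_means <- function() {
  c(O2_minus = 2.5, OH_radical = 12, H2O2 = 5.5, MDA = 8,
    SOD = 180, POD = 95, CAT = 40, APX = 15, GR = 9,
    ASA = 0.9, DHA = 0.45, Pro = 60, SS = 22, SP = 14)
}

#' Bioassay design configuration
#'
#' Describes the Petri-dish germination design and the physiology replication
#' structure: a set of donor-exudate treatments plus one distinguished
#' control, a fixed number of seeds per dish, dishes per treatment, and
#' biological x technical replicates for the physiological assays.
#'
#' @param treatments Character vector of treatment labels (excluding the
#'   control).
#' @param control Single control label, distinct from `treatments`.
#' @param seeds_per_dish Seeds sown per Petri dish (default 30).
#' @param dishes_per_treatment Replicate dishes per treatment (default 4).
#' @param physio_bio_reps Biological replicates per physiology assay
#'   (default 4).
#' @param physio_tech_reps Technical replicates per biological replicate
#'   (default 3).
#' @param seed Integer RNG seed for the whole generated dataset.
#' @return An object of class `allelo_design`.
#' @examples
#' allelo_design(treatments = c("T1", "T2"), seed = 1)
#' @export
allelo_design <- function(treatments = paste0("T", 1:10), control = "CK",
                          seeds_per_dish = 30, dishes_per_treatment = 4,
                          physio_bio_reps = 4, physio_tech_reps = 3,
                          seed = 1L) {
  stopifnot(is.character(treatments), length(treatments) >= 1)
  if (length(control) != 1L || !nzchar(control))
    stop("exactly one control label is required", call. = FALSE)
  if (control %in% treatments)
    stop("control label must not appear among treatments", call. = FALSE)
  if (anyDuplicated(treatments))
    stop("duplicated treatment labels", call. = FALSE)
  for (nm in c("seeds_per_dish", "dishes_per_treatment",
               "physio_bio_reps", "physio_tech_reps")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stop(sprintf("%s must be a positive integer", nm), call. = FALSE)
  }
  structure(list(
    treatments = treatments, control = control,
    seeds_per_dish = as.integer(seeds_per_dish),
    dishes_per_treatment = as.integer(dishes_per_treatment),
    physio_bio_reps = as.integer(physio_bio_reps),
    physio_tech_reps = as.integer(physio_tech_reps),
    seed = as.integer(seed)
  ), class = "allelo_design")
}

#' @export
print.allelo_design <- function(x, ...) {
  cat("Allelopathy bioassay design\n")
  cat("  groups:", length(x$treatments), "treatments + control", x$control, "\n")
  cat(sprintf("  germination: %d seeds/dish x %d dishes/treatment\n",
              x$seeds_per_dish, x$dishes_per_treatment))
  cat(sprintf("  physiology: %d biological x %d technical replicates\n",
              x$physio_bio_reps, x$physio_tech_reps))
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Planted effect of one treatment
#'
#' Phenomenological description of how one exudate treatment shifts the
#' germination and physiology response relative to control: day-7 germination
#' probability, conditional day-3 probability, mean morphometrics with a
#' common coefficient of variation, and per-indicator physiology multipliers.
#'
#' @param p_germ_day7 Probability a seed germinates by day 7.
#' @param p_germ_day3_given_day7 Probability a day-7 germinated seed had
#'   already germinated by day 3 (early vigor).
#' @param mean_radicle_mm,mean_germ_mm,mean_height_cm Positive morphometric
#'   means (radicle length mm, germ length mm, seedling height cm).
#' @param cv_morpho Coefficient of variation of per-seedling morphometrics
#'   (>= 0); seedling sizes are lognormal so they stay positive.
#' @param physio_multipliers Named positive multipliers of the control mean,
#'   one per indicator in [physio_indicators()], or `NULL` if the treatment
#'   is not assayed physiologically.
#' @param physio_cv Biological coefficient of variation for physiology
#'   (>= 0); technical noise defaults to half of it.
#' @return An object of class `treatment_effect`.
#' @export
treatment_effect <- function(p_germ_day7, p_germ_day3_given_day7 = 0.65,
                             mean_radicle_mm = 12, mean_germ_mm = 7,
                             mean_height_cm = 2.6, cv_morpho = 0.15,
                             physio_multipliers = NULL, physio_cv = 0.1) {
  for (p in c(p_germ_day7, p_germ_day3_given_day7))
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop("germination probabilities must lie in [0, 1]", call. = FALSE)
  for (m in c(mean_radicle_mm, mean_germ_mm, mean_height_cm))
    if (!is.numeric(m) || m <= 0)
      stop("morphometric means must be positive", call. = FALSE)
  if (cv_morpho < 0 || physio_cv < 0)
    stop("coefficients of variation must be >= 0", call. = FALSE)
  if (!is.null(physio_multipliers)) {
    if (is.null(names(physio_multipliers)) || any(physio_multipliers <= 0))
      stop("physio_multipliers must be a named vector of positive values",
           call. = FALSE)
    bad <- setdiff(names(physio_multipliers), physio_indicators())
    if (length(bad))
      stop("unknown physiology indicator(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  structure(list(
    p_germ_day7 = p_germ_day7,
    p_germ_day3_given_day7 = p_germ_day3_given_day7,
    mean_radicle_mm = mean_radicle_mm, mean_germ_mm = mean_germ_mm,
    mean_height_cm = mean_height_cm, cv_morpho = cv_morpho,
    physio_multipliers = physio_multipliers, physio_cv = physio_cv
  ), class = "treatment_effect")
}

# Deterministic substream seed per (group index, replicate index): each dish /
# assay gets its own stream so generated data do not depend on the order in
# which groups are drawn. Kept below 2^31 - 1 for 32-bit R integers.
substream_seed <- function(seed, i, j, k = 0L) {
  m <- 2147483647
  s <- (as.double(seed) %% m)
  s <- (s * 69069 + i * 104729 + j * 7919 + k * 611953 + 1) %% m
  as.integer(s)
}

# Lognormal draws with a given arithmetic mean and coefficient of variation;
# cv = 0 degenerates to the constant mean.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (n == 0L) return(numeric(0))
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

check_effects <- function(design, effects) {
  groups <- c(design$control, design$treatments)
  if (is.null(names(effects)) || !all(groups %in% names(effects)))
    stop("every group (control included) needs an entry in `effects`; missing: ",
         paste(setdiff(groups, names(effects)), collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(effects), groups)
  if (length(extra))
    stop("unknown treatment label(s) in `effects`: ",
         paste(extra, collapse = ", "), call. = FALSE)
  if (!all(vapply(effects, inherits, logical(1), "treatment_effect")))
    stop("all `effects` entries must be treatment_effect objects", call. = FALSE)
  groups
}

#' Simulate a germination bioassay
#'
#' Draws dish-level germination counts and per-seedling morphometrics for
#' every group of the design. Per seed, day-7 germination is Bernoulli with
#' the group's `p_germ_day7`; among germinated seeds, day-3 status is
#' Bernoulli with `p_germ_day3_given_day7`, so `n3 <= n7 <= n_total` holds by
#' construction. Morphometrics are lognormal with the group's means and CV,
#' one value per germinated seedling. Each (group, dish) pair draws from its
#' own RNG substream derived from the design seed, so output is reproducible
#' and independent of generation order.
#'
#' @param design An [allelo_design()].
#' @param effects Named list of [treatment_effect()]s, one per group
#'   including the control.
#' @return List with two data frames: `dishes` (treatment, dish_id, n_total,
#'   n3, n7) and `seedlings` (treatment, dish_id, seedling_id, radicle_mm,
#'   germ_mm, height_cm).
#' @examples
#' d <- allelo_design(treatments = "T1", seed = 7)
#' eff <- list(CK = treatment_effect(0.8), T1 = treatment_effect(0.95))
#' sim <- simulate_germination(d, eff)
#' head(sim$dishes)
#' @export
simulate_germination <- function(design, effects) {
  stopifnot(inherits(design, "allelo_design"))
  groups <- check_effects(design, effects)
  dish_rows <- vector("list", length(groups) * design$dishes_per_treatment)
  seedling_rows <- list()
  r <- 0L
  for (i in seq_along(groups)) {
    g <- groups[i]
    eff <- effects[[g]]
    for (d in seq_len(design$dishes_per_treatment)) {
      set.seed(substream_seed(design$seed, i, d))
      n_total <- design$seeds_per_dish
      germ7 <- stats::rbinom(n_total, 1L, eff$p_germ_day7)
      n7 <- sum(germ7)
      n3 <- if (n7 > 0) sum(stats::rbinom(n7, 1L, eff$p_germ_day3_given_day7)) else 0L
      r <- r + 1L
      dish_rows[[r]] <- data.frame(
        treatment = g, dish_id = d, n_total = n_total,
        n3 = as.integer(n3), n7 = as.integer(n7),
        stringsAsFactors = FALSE)
      if (n7 > 0) {
        seedling_rows[[length(seedling_rows) + 1L]] <- data.frame(
          treatment = g, dish_id = d, seedling_id = seq_len(n7),
          radicle_mm = rlnorm_mean_cv(n7, eff$mean_radicle_mm, eff$cv_morpho),
          germ_mm = rlnorm_mean_cv(n7, eff$mean_germ_mm, eff$cv_morpho),
          height_cm = rlnorm_mean_cv(n7, eff$mean_height_cm, eff$cv_morpho),
          stringsAsFactors = FALSE)
      }
    }
  }
  seedlings <- if (length(seedling_rows)) do.call(rbind, seedling_rows) else
    data.frame(treatment = character(0), dish_id = integer(0),
               seedling_id = integer(0), radicle_mm = numeric(0),
               germ_mm = numeric(0), height_cm = numeric(0))
  list(dishes = do.call(rbind, dish_rows), seedlings = seedlings)
}

#' Simulate physiological indicator measurements
#'
#' For every group whose effect carries `physio_multipliers`, each biological
#' replicate draws a latent true value `control_mean x multiplier x
#' (1 + biological noise)`; technical replicates add measurement noise around
#' that latent value (CV half the biological CV). Values are truncated at 0.
#'
#' @param design An [allelo_design()].
#' @param effects Named list of [treatment_effect()]s (groups without
#'   `physio_multipliers` are skipped).
#' @param control_means Named positive vector of control-level indicator
#'   means; defaults to [default_physio_means()].
#' @return Data frame with columns treatment, bio_rep, tech_rep, indicator,
#'   value.
#' @export
simulate_physiology <- function(design, effects,
                                control_means = default_physio_means()) {
  stopifnot(inherits(design, "allelo_design"))
  groups <- check_effects(design, effects)
  if (any(control_means <= 0))
    stop("control_means must be strictly positive", call. = FALSE)
  rows <- list()
  for (i in seq_along(groups)) {
    g <- groups[i]
    eff <- effects[[g]]
    mult <- eff$physio_multipliers
    if (is.null(mult)) next
    missing_ind <- setdiff(names(mult), names(control_means))
    if (length(missing_ind))
      stop("indicator(s) missing from control_means: ",
           paste(missing_ind, collapse = ", "), call. = FALSE)
    tech_cv <- eff$physio_cv / 2
    for (b in seq_len(design$physio_bio_reps)) {
      set.seed(substream_seed(design$seed, i, b, k = 1L))
      for (ind in names(mult)) {
        latent <- control_means[[ind]] * mult[[ind]] *
          (1 + if (eff$physio_cv > 0) stats::rnorm(1, 0, eff$physio_cv) else 0)
        tech <- latent *
          (1 + if (tech_cv > 0) stats::rnorm(design$physio_tech_reps, 0, tech_cv)
           else numeric(design$physio_tech_reps))
        rows[[length(rows) + 1L]] <- data.frame(
          treatment = g, bio_rep = b, tech_rep = seq_len(design$physio_tech_reps),
          indicator = ind, value = pmax(0, tech), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(treatment = character(0), bio_rep = integer(0),
                      tech_rep = integer(0), indicator = character(0),
                      value = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Demonstration effect structure for the 10-exudate screen
#'
#' A planted-effect preset mirroring the qualitative structure of a
#' 10-donor root-exudate screen: T1 is the strongest promoter across all six
#' germination parameters, T10 the weakest (barely above control), T2
#' inhibits germination percentage while mildly promoting seedling growth,
#' and the remaining treatments are graded intermediates. The control (CK),
#' T1 and T10 additionally carry physiology multipliers: T1 lowers
#' reactive-oxygen and MDA levels while raising the ascorbate pool; T10
#' mainly raises soluble sugars and proteins.
#'
#' @param design An [allelo_design()] whose treatments are `T1`..`T10`
#'   with control `CK` (the default design).
#' @return Named list of [treatment_effect()]s covering every group.
#' @export
demo_effects <- function(design = allelo_design()) {
  stopifnot(inherits(design, "allelo_design"))
  base <- list(p3 = 0.60, radicle = 12, germ = 7, height = 2.6, cv = 0.15)
  mk <- function(p7, p3, mult, physio = NULL) {
    treatment_effect(
      p_germ_day7 = p7, p_germ_day3_given_day7 = p3,
      mean_radicle_mm = base$radicle * mult,
      mean_germ_mm = base$germ * mult,
      mean_height_cm = base$height * mult,
      cv_morpho = base$cv, physio_multipliers = physio, physio_cv = 0.08)
  }
  ones <- stats::setNames(rep(1, 14), physio_indicators())
  t1_phys <- ones
  t1_phys[c("O2_minus", "OH_radical", "H2O2", "MDA")] <- c(0.70, 0.80, 0.75, 0.70)
  t1_phys[c("SOD", "POD", "CAT", "APX", "GR")] <- 1.30
  t1_phys[c("ASA", "DHA")] <- c(1.50, 1.40)
  t1_phys[c("Pro", "SS", "SP")] <- c(1.30, 1.15, 1.15)
  t10_phys <- ones
  t10_phys[c("SS", "SP")] <- c(1.40, 1.30)
  t10_phys["OH_radical"] <- 0.80
  t10_phys[c("SOD", "POD")] <- 1.10
  eff <- list(
    CK  = mk(0.78, base$p3, 1.00, physio = ones),
    T1  = mk(0.95, 0.80, 1.35, physio = t1_phys),
    T2  = mk(0.68, 0.62, 1.15),
    T3  = mk(0.84, 0.58, 1.18),
    T4  = mk(0.85, 0.58, 1.20),
    T5  = mk(0.88, 0.70, 1.28),
    T6  = mk(0.86, 0.68, 1.22),
    T7  = mk(0.87, 0.72, 1.12),
    T8  = mk(0.82, 0.55, 1.14),
    T9  = mk(0.84, 0.60, 1.15),
    T10 = mk(0.80, 0.60, 1.05, physio = t10_phys)
  )
  missing <- setdiff(c(design$control, design$treatments), names(eff))
  if (length(missing))
    stop("demo_effects covers CK and T1..T10 only; design has: ",
         paste(missing, collapse = ", "), call. = FALSE)
  eff[c(design$control, design$treatments)]
}

#' Write a simulated bioassay to CSV files
#'
#' Writes `germination.csv`, `seedlings.csv` and (when present)
#' `physiology.csv` in the package's tidy schemas: UTF-8, comma-separated,
#' header row, "." decimal.
#'
#' @param sim List as returned by [simulate_germination()], optionally with a
#'   `physiology` element from [simulate_physiology()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_bioassay_csv <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  write1 <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
    p
  }
  paths <- c(paths, write1(sim$dishes, "germination.csv"),
             write1(sim$seedlings, "seedlings.csv"))
  if (!is.null(sim$physiology))
    paths <- c(paths, write1(sim$physiology, "physiology.csv"))
  invisible(paths)
}
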