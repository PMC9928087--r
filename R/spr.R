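# Quantitative SPR analysis: theoretical Rmax, percent Rmax, binding calls,
# and two-factor comparisons of binding-site x protein-variant panels.

#' Theoretical maximum SPR response
#'
#' The standard mass-ratio relation: `Rmax = s * (MW_analyte / MW_ligand) *
#' RU_immobilised`, where `s` is the assumed binding stoichiometry (analyte
#' molecules per immobilised ligand). By default the analyte is treated as
#' the regulator homodimer with `s = 1`.
#'
#' @param mw_analyte,mw_ligand Molecular weights (Da), > 0.
#' @param ru_immob Immobilised ligand level (RU), > 0.
#' @param stoichiometry Analyte per ligand, > 0 (default 1).
#' @return Theoretical Rmax in RU (vectorised).
#' @examples
#' theoretical_rmax(13800, 9200, 50) # 75 RU
#' @export
theoretical_rmax <- function(mw_analyte, mw_ligand, ru_immob,
                             stoichiometry = 1) {
  if (any(mw_analyte <= 0) || any(mw_ligand <= 0) || any(ru_immob <= 0) ||
      any(stoichiometry <= 0)) {
    abort("molecular weights, immobilisation level and stoichiometry must be > 0")
  }
  stoichiometry * (mw_analyte / mw_ligand) * ru_immob
}

#' Observed response as a percentage of theoretical Rmax
#'
#' Values above 100% are legitimate and flag potential higher-order binding
#' (see [spr_percent_rmax()] for the flag); negative observed responses
#' (baseline drift) are clipped to zero with a warning.
#'
#' @param r_obs Observed response (RU).
#' @param rmax_theor Theoretical Rmax (RU), > 0.
#' @return Percent Rmax (vectorised).
#' @export
percent_rmax <- function(r_obs, rmax_theor) {
  if (any(rmax_theor <= 0)) abort("`rmax_theor` must be > 0")
  if (any(r_obs < 0)) {
    warn("negative observed responses clipped to zero")
    r_obs <- pmax(r_obs, 0)
  }
  100 * r_obs / rmax_theor
}

#' Three-way binding call from percent Rmax
#'
#' `BOUND` above the call threshold (strictly greater, matching the
#' "greater than 50%" convention), `NONE` at or below the noise floor,
#' `WEAK` in between.
#'
#' @param percent Percent Rmax values.
#' @param threshold Call threshold (default 50).
#' @param noise_floor Noise floor (default 10).
#' @return Character vector of `"BOUND"`, `"WEAK"`, `"NONE"`.
#' @export
binding_call <- function(percent, threshold = 50, noise_floor = 10) {
  dplyr::case_when(
    percent > threshold ~ "BOUND",
    percent > noise_floor ~ "WEAK",
    TRUE ~ "NONE"
  )
}

#' Percent Rmax and binding calls for a measurement table
#'
#' Adds `rmax_theor`, `pct_rmax`, an `over_stoichiometry` flag (percent
#' above 100 suggests more than the assumed number of analytes per ligand)
#' and the three-way `call` to a tidy table of SPR measurements.
#'
#' @param measurements Tibble with `r_obs`, `ru_immob`, `mw_ligand`,
#'   `mw_analyte` and optionally `stoichiometry` (default 1).
#' @param threshold,noise_floor Passed to [binding_call()].
#' @return The input tibble with the derived columns appended.
#' @export
spr_percent_rmax <- function(measurements, threshold = 50, noise_floor = 10) {
  s <- if ("stoichiometry" %in% names(measurements)) {
    measurements$stoichiometry
  } else 1
  measurements %>%
    dplyr::mutate(
      rmax_theor = theoretical_rmax(.data$mw_analyte, .data$mw_ligand,
                                    .data$ru_immob, s),
      pct_rmax = percent_rmax(.data$r_obs, .data$rmax_theor),
      over_stoichiometry = .data$pct_rmax > 100,
      call = binding_call(.data$pct_rmax, threshold, noise_floor)
    )
}

#' Two-factor comparison of percent Rmax across sites and variants
#'
#' Technical replicates are averaged per cell first, then percent Rmax is
#' decomposed by a two-factor fixed-effects ANOVA (binding site x protein
#' variant). With replicate cell means the interaction is included;
#' otherwise the model degrades to main effects and the interaction is
#' flagged untestable. Empty cells are listed and excluded with a warning.
#'
#' @param measurements Tibble from [spr_percent_rmax()] with `pct_rmax`,
#'   plus the factor columns.
#' @param site_col,variant_col Names of the two factor columns.
#' @param replicate_col Optional column distinguishing biological
#'   replicates; when present, replicates are the ANOVA's error stratum
#'   (technical replicates inside each site x variant x replicate cell are
#'   averaged first).
#' @return List with `anova` (tidy term table: `term`, `df`, `statistic`,
#'   `p_value`), `cells` (mean, sd, n per cell), `interaction_testable`,
#'   `empty_cells`.
#' @export
compare_spr_groups <- function(measurements, site_col = "oligo_id",
                               variant_col = "variant",
                               replicate_col = NULL) {
  df <- tibble(
    site = factor(measurements[[site_col]]),
    variant = factor(measurements[[variant_col]]),
    pct = measurements$pct_rmax
  )
  if (!is.null(replicate_col)) {
    df$rep <- measurements[[replicate_col]]
    df <- df %>%
      dplyr::group_by(.data$site, .data$variant, .data$rep) %>%
      dplyr::summarise(pct = mean(.data$pct), .groups = "drop")
  }
  if (nlevels(df$site) < 2 || nlevels(df$variant) < 2) {
    abort("need at least two levels of both site and variant")
  }
  cells <- df %>%
    dplyr::group_by(.data$site, .data$variant) %>%
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$pct),
                     sd = stats::sd(.data$pct), .groups = "drop")
  full_grid <- tidyr::expand_grid(site = levels(df$site),
                                  variant = levels(df$variant))
  empty <- dplyr::anti_join(
    full_grid,
    dplyr::mutate(cells, site = as.character(.data$site),
                  variant = as.character(.data$variant)),
    by = c("site", "variant")
  )
  if (nrow(empty) > 0) {
    warn(sprintf("%d empty cell(s); analysis uses available cells only",
                 nrow(empty)))
  }
  interaction_testable <- all(cells$n >= 2) && nrow(empty) == 0
  fit <- if (interaction_testable) {
    stats::aov(pct ~ site * variant, data = df)
  } else {
    stats::aov(pct ~ site + variant, data = df)
  }
  sm <- summary(fit)[[1]]
  terms <- trimws(rownames(sm))
  anova <- tibble(
    term = terms,
    df = sm$Df,
    statistic = sm$`F value`,
    p_value = sm$`Pr(>F)`
  )
  list(anova = anova, cells = cells,
       interaction_testable = interaction_testable, empty_cells = empty)
}
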