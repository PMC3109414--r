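#' Sample CAMCOG total scores for a two-group cohort
#'
#' Draws integer CAMCOG scores (0--107) for a non-demented group and an AD
#' group. The non-demented component is a left-skewed mixture concentrated
#' high (target median 99, interquartile range roughly 81--106): with
#' probability 0.52 a score near the ceiling, `107 - floor(Exp(mean 2.8))`
#' truncated to \[99, 107\], otherwise a discretized Normal(81, 15) truncated
#' to \[0, 98\]. The AD component is a widely spread U-flavoured
#' `round(107 * Beta(0.374, 0.359))` (target median 57, interquartile range
#' roughly 10--96).
#'
#' @param n_control,n_ad group sizes (non-negative integers).
#' @param seed integer seed; draws are deterministic given the seed.
#' @return data.frame with columns `group` (factor `non-demented`/`AD`) and
#'   `camcog` (integer), `n_control + n_ad` rows.
#' @export
sample_camcog <- function(n_control, n_ad, seed) {
  if (length(n_control) != 1 || length(n_ad) != 1 ||
      is.na(n_control) || is.na(n_ad) || n_control < 0 || n_ad < 0)
    stop("group sizes must be non-negative", call. = FALSE)
  n_control <- as.integer(n_control); n_ad <- as.integer(n_ad)
  set.seed(seed)
  ctrl <- integer(0)
  if (n_control > 0) {
    hi <- runif(n_control) < 0.52
    top <- pmin(107L, pmax(99L, 107L - as.integer(floor(rexp(n_control,
                                                             1 / 2.8)))))
    low <- pmin(98L, pmax(0L, as.integer(round(rnorm(n_control, 81, 15)))))
    ctrl <- ifelse(hi, top, low)
  }
  ad <- integer(0)
  if (n_ad > 0)
    ad <- as.integer(round(107 * rbeta(n_ad, 0.374, 0.359)))
  data.frame(
    group = factor(rep(c("non-demented", "AD"), c(n_control, n_ad)),
                   levels = c("non-demented", "AD")),
    camcog = c(ctrl, ad)
  )
}

#' Generate a synthetic cohort with piecewise-linear biomarker responses
#'
#' Builds a per-participant analysis table: CAMCOG scores from
#' [sample_camcog()], covariates (age, gender, CSF storage time, assay
#' group), an MMSE score loosely tracking CAMCOG, and one column per
#' biomarker generated as broken-stick mean ([piecewise_mean()]) plus
#' side-specific Gaussian noise, with a `contamination_rate` fraction of
#' observations drawing their residual at `contamination_scale` times the
#' side SD (symmetric gross outliers), plus any configured batch and
#' covariate effects. Values are floored at zero (concentrations cannot be
#' negative). Batch and covariate effects default to zero in
#' [default_scenarios()] so change-point analyses are unconfounded unless a
#' caller opts in.
#'
#' @param cfgs named list of [scenario_config()]s, one per biomarker.
#' @param n_control,n_ad group sizes.
#' @param seed integer seed; the whole table is reproducible from it.
#' @param missing_rate fraction of biomarker cells set missing at random.
#' @return data.frame (a cohort table) with columns `id`, `group`, `camcog`,
#'   `mmse`, `age`, `gender`, `storage_time`, `assay_group`, then one numeric
#'   column per biomarker.
#' @export
generate_cohort <- function(cfgs, n_control, n_ad, seed, missing_rate = 0) {
  stopifnot(is.list(cfgs), length(cfgs) > 0)
  for (cfg in cfgs) validate_scenario(cfg)
  base <- sample_camcog(n_control, n_ad, seed)
  n <- nrow(base)
  tab <- data.frame(
    id = sprintf("P%04d", seq_len(max(n, 1))[seq_len(n)]),
    group = base$group,
    camcog = base$camcog,
    stringsAsFactors = FALSE
  )
  tab$mmse <- pmin(30L, pmax(0L, as.integer(round(
    base$camcog * 30 / 107 + rnorm(n, 0, 1.5)))))
  tab$age <- round(pmin(95, pmax(55, rnorm(n, 74, 7))), 1)
  tab$gender <- factor(sample(c("F", "M"), n, replace = TRUE),
                       levels = c("F", "M"))
  tab$storage_time <- round(runif(n, 0.5, 10), 2)
  n_batch <- max(vapply(cfgs, function(cfg) length(cfg$batch_effects),
                        integer(1)))
  tab$assay_group <- sample.int(n_batch, n, replace = TRUE)
  for (cfg in cfgs) {
    mu <- piecewise_mean(tab$camcog, cfg)
    side_sd <- ifelse(tab$camcog > cfg$theta, cfg$sd_above, cfg$sd_below)
    gross <- runif(n) < cfg$contamination_rate
    noise <- rnorm(n, 0,
                   side_sd * ifelse(gross, cfg$contamination_scale, 1))
    batch <- cfg$batch_effects[pmin(tab$assay_group,
                                    length(cfg$batch_effects))]
    covar <- cfg$covariate_coeffs[["age"]] * tab$age +
      cfg$covariate_coeffs[["gender"]] * (tab$gender == "M") +
      cfg$covariate_coeffs[["storage_time"]] * tab$storage_time
    val <- pmax(0, mu + noise + batch + covar)
    if (missing_rate > 0)
      val[runif(n) < missing_rate] <- NA_real_
    tab[[cfg$name]] <- val
  }
  tab
}

cohort_meta_cols <- c("id", "group", "camcog", "mmse", "age", "gender",
                      "storage_time", "assay_group")

#' Biomarker columns of a cohort table
#'
#' @param table a cohort table as returned by [generate_cohort()] or
#'   [read_cohort()].
#' @return character vector of biomarker column names.
#' @export
biomarker_names <- function(table) {
  setdiff(names(table), cohort_meta_cols)
}

#' Write / read a cohort table as CSV
#'
#' The CSV carries the fixed header `id, group, camcog, mmse, age, gender,
#' storage_time, assay_group` followed by one column per biomarker; missing
#' biomarker cells are empty fields.
#'
#' @param table a cohort table.
#' @param path file path.
#' @return `read_cohort` returns the cohort data.frame with `group` and
#'   `gender` restored as factors; `write_cohort` returns `path` invisibly.
#' @export
write_cohort <- function(table, path) {
  stopifnot(all(cohort_meta_cols %in% names(table)))
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_meta_cols, names(tab))
  if (length(missing))
    stop("cohort CSV lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab$group <- factor(tab$group, levels = c("non-demented", "AD"))
  tab$gender <- factor(tab$gender, levels = c("F", "M"))
  if (any(tab$camcog < 0 | tab$camcog > 107, na.rm = TRUE))
    stop("camcog scores outside [0, 107]", call. = FALSE)
  tab
}
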