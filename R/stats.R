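# Between-group and correlation statistics.
#
# Every test returns a one-row tibble with a common set of columns so results
# bind into tidy tables: statistic_name, statistic, df (or NA), n, p_value,
# plus per-group summaries where they apply.

test_result <- function(statistic_name, statistic, p_value, df = NA_real_,
                        n = NA_real_, ...) {
  tibble::tibble(
    statistic_name = statistic_name,
    statistic = statistic,
    df = df,
    n = n,
    p_value = p_value,
    ...
  )
}

#' Pooled-variance independent-samples t test from summaries
#'
#' Student's t with the pooled variance and `n1 + n2 - 2` degrees of freedom,
#' two-tailed — computable directly from printed group summaries
#' (mean, SD, n).
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return one-row tibble (see module header).
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) abort("Both groups need n >= 2.")
  if (sd1 <= 0 || sd2 <= 0) abort("Standard deviations must be > 0.")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  test_result(
    "t", t, 2 * pt(-abs(t), df), df = df, n = n1 + n2,
    mean_1 = mean1, sd_1 = sd1, mean_2 = mean2, sd_2 = sd2
  )
}

#' Pooled-variance independent-samples t test from raw samples
#'
#' Identical to [t_test_from_summary()] applied to the samples' own mean/SD/n,
#' so the two entry points always agree.
#'
#' @param x,y numeric sample vectors.
#' @export
independent_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("Both groups need n >= 2.")
  t_test_from_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction, df = 1, two-sided.
#'
#' @param table 2x2 matrix of counts (rows = category, columns = group), or
#'   four counts `c(a, b, c, d)` filled row-wise.
#' @export
chi_square_2x2 <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, 2, 2, byrow = TRUE)
  if (any(table < 0) || sum(table) == 0) abort("Counts must be >= 0 with a positive total.")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("A zero marginal makes the chi-square test undefined.")
  }
  # the Pearson statistic is exact regardless of expected-count size; the
  # small-count approximation warning is not useful here
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  test_result("chi_square", unname(ht$statistic), ht$p.value,
              df = unname(ht$parameter), n = sum(table))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided. By default (`exact = NULL`) the exact distribution is used when
#' both groups have n <= 10 and there are no ties; otherwise the tie-corrected
#' normal approximation with continuity correction. The reported statistic is
#' the normal-approximation z (continuity-corrected); `u` is the Mann-Whitney
#' U for group `x`.
#'
#' @param x,y numeric sample vectors.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact p-value.
#' @export
rank_sum_test <- function(x, y, exact = NULL) {
  if (length(x) < 1 || length(y) < 1) abort("Both samples must be non-empty.")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  # tie-corrected normal approximation with continuity correction
  nties <- table(r)
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - sum(nties^3 - nties) /
                              ((n1 + n2) * (n1 + n2 - 1)))
  cc <- sign(u - mu) * 0.5
  z <- if (sigma2 > 0) (u - mu - cc) / sqrt(sigma2) else 0
  use_exact <- if (is.null(exact)) (n1 <= 10 && n2 <= 10 && !any(duplicated(c(x, y)))) else exact
  p <- if (use_exact) {
    stats::wilcox.test(x, y, exact = TRUE)$p.value
  } else {
    min(1, 2 * pnorm(-abs(z)))
  }
  test_result("rank_sum_z", z, p, n = n1 + n2, u = u,
              median_1 = median(x), median_2 = median(y))
}

#' Shapiro-Wilk normality check
#'
#' @param x numeric sample, 3 <= n <= 5000, non-constant.
#' @param alpha significance level for the `normal` verdict (default 0.05).
#' @return one-row tibble with the W statistic, p-value and logical `normal`.
#' @export
normality_check <- function(x, alpha = 0.05) {
  if (length(x) < 3) abort("Normality check needs n >= 3.")
  if (sd(x) == 0) abort("Normality is undefined for a constant sample.")
  ht <- stats::shapiro.test(x)
  dplyr::mutate(
    test_result("shapiro_w", unname(ht$statistic), ht$p.value, n = length(x)),
    normal = .data$p_value > alpha
  )
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors of equal length (n >= 3), non-constant.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("Need equal-length samples with n >= 3.")
  }
  if (sd(x) == 0 || sd(y) == 0) abort("Correlation is undefined for constant input.")
  ht <- stats::cor.test(x, y, method = "pearson")
  test_result("pearson_r", unname(ht$estimate), ht$p.value,
              df = unname(ht$parameter), n = length(x))
}

#' Per-pair between-group comparison of PLI values
#'
#' Runs a Wilcoxon rank-sum test for every channel pair in every band,
#' comparing the two groups' subject-level PLI values. No multiplicity
#' correction is applied by default; set `adjust = TRUE` to add a
#' Benjamini-Hochberg column.
#'
#' @param conn connectivity tibble from [cohort_connectivity()].
#' @param cohort cohort tibble with `subject_id` and `group`.
#' @param bands band names to test (default: all present).
#' @param adjust add a BH-adjusted p-value column.
#' @return tibble with one row per (band, pair): `band`, `chan_1`, `chan_2`,
#'   `statistic` (z), `p_value`, group medians, and `p_adjusted` if requested.
#' @export
pairwise_band_comparison <- function(conn, cohort, bands = NULL, adjust = FALSE) {
  long <- conn |>
    dplyr::mutate(
      pairs = purrr::map(.data$matrix, function(m) dplyr::select(tidy(m), -"band"))
    ) |>
    dplyr::select("subject_id", "band", "pairs") |>
    tidyr::unnest("pairs") |>
    dplyr::inner_join(dplyr::select(cohort, "subject_id", "group"), by = "subject_id")
  if (!is.null(bands)) long <- dplyr::filter(long, .data$band %in% bands)

  chan_sets <- long |>
    dplyr::distinct(.data$subject_id, .data$chan_1, .data$chan_2) |>
    dplyr::count(.data$subject_id)
  if (dplyr::n_distinct(chan_sets$n) > 1) {
    abort("All subjects must share the same channel set.")
  }

  out <- long |>
    dplyr::group_by(.data$band, .data$chan_1, .data$chan_2) |>
    dplyr::group_modify(function(d, key) {
      g1 <- d$pli[d$group == "MCI"]
      g2 <- d$pli[d$group == "NC"]
      rank_sum_test(g1, g2, exact = FALSE) |>
        dplyr::select("statistic", "p_value", "median_1", "median_2")
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(median_mci = "median_1", median_nc = "median_2")
  if (adjust) {
    out <- out |>
      dplyr::group_by(.data$band) |>
      dplyr::mutate(p_adjusted = stats::p.adjust(.data$p_value, "BH")) |>
      dplyr::ungroup()
  }
  out
}

#' Between-group comparison of global PLI per band
#'
#' @inheritParams pairwise_band_comparison
#' @return tibble with one row per band (rank-sum z, p, group means).
#' @export
global_band_comparison <- function(conn, cohort) {
  conn |>
    dplyr::inner_join(dplyr::select(cohort, "subject_id", "group"), by = "subject_id") |>
    dplyr::group_by(.data$band) |>
    dplyr::group_modify(function(d, key) {
      g1 <- d$global_pli[d$group == "MCI"]
      g2 <- d$global_pli[d$group == "NC"]
      rank_sum_test(g1, g2, exact = FALSE) |>
        dplyr::mutate(
          mean_mci = mean(g1), sd_mci = sd(g1),
          mean_nc = mean(g2), sd_nc = sd(g2)
        ) |>
        dplyr::select("statistic", "p_value", dplyr::starts_with("mean_"),
                      dplyr::starts_with("sd_"))
    }) |>
    dplyr::ungroup()
}

#' Cohort characteristics table with group-comparison statistics
#'
#' Continuous covariates are compared with the pooled t test when both groups
#' pass the Shapiro-Wilk normality check (and with the rank-sum test
#' otherwise); sex uses the 2x2 chi-square test.
#'
#' @param cohort cohort tibble (columns `group`, `sex`, `age`,
#'   `education_years`, `moca`, `t2dm_duration_years`).
#' @return tidy tibble, one row per characteristic.
#' @export
cohort_characteristics <- function(cohort) {
  vars <- c(
    age = "age", education = "education_years",
    moca = "moca", t2dm_duration = "t2dm_duration_years"
  )
  g1 <- cohort[cohort$group == "MCI", ]
  g2 <- cohort[cohort$group == "NC", ]
  rows <- purrr::imap_dfr(vars, function(col, label) {
    x <- g1[[col]]; y <- g2[[col]]
    use_t <- normality_check(x)$normal && normality_check(y)$normal
    res <- if (use_t) independent_t_test(x, y) else rank_sum_test(x, y, exact = FALSE)
    tibble::tibble(
      characteristic = label,
      mci_summary = sprintf("%.2f ± %.2f", mean(x), sd(x)),
      nc_summary = sprintf("%.2f ± %.2f", mean(y), sd(y)),
      test = res$statistic_name,
      statistic = res$statistic,
      p_value = res$p_value
    )
  })
  sex_tab <- rbind(
    c(sum(g1$sex == "M"), sum(g1$sex == "F")),
    c(sum(g2$sex == "M"), sum(g2$sex == "F"))
  )
  chi <- chi_square_2x2(t(sex_tab))
  dplyr::bind_rows(
    tibble::tibble(
      characteristic = "sex",
      mci_summary = sprintf("%d/%d", sex_tab[1, 1], sex_tab[1, 2]),
      nc_summary = sprintf("%d/%d", sex_tab[2, 1], sex_tab[2, 2]),
      test = "chi_square",
      statistic = chi$statistic,
      p_value = chi$p_value
    ),
    rows
  )
}
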