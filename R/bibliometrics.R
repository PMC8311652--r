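#' @name bibliometrics
#' @title Citation statistics and the citation-expectation model
#'
#' @description
#' A publication cohort observed \eqn{\Delta t} years after publication has
#' accumulated only part of the citations it will eventually receive.
#' Citation accrual is modelled as a saturating exponential
#' \deqn{C(t) = N (1 - e^{-\Delta t/\beta})}
#' where \eqn{N} is the eventual total and \eqn{\beta} is the
#' discipline-specific time (in years) by which an article has achieved
#' 63\% of its total citations. Inverting the model extrapolates the
#' expected eventual mean \eqn{\langle N \rangle =
#' \bar n_{\mathrm{cit},\Delta t} / (1 - e^{-\Delta t/\beta})} from the
#' observed mean. Preset constants: biochemistry/molecular biology
#' \eqn{\beta = 5.4}, pharmacology \eqn{\beta = 7.1}.
NULL

#' Discipline presets for the citation-expectation constant
#'
#' @format Named numeric vector: `bio` = 5.4 years (biochemistry and
#'   molecular biology), `pharma` = 7.1 years (pharmacology).
#' @export
beta_presets <- c(bio = 5.4, pharma = 7.1)

#' Mean cumulative citations of a publication-year cohort
#'
#' @param citations Non-empty numeric vector of cumulative citation counts,
#'   one per publication of the cohort.
#' @return List with `mean` (exact arithmetic mean) and `reported`
#'   (the tabular display value, truncated toward zero so a cohort mean of
#'   274.5 prints as 274).
#' @export
mean_cumulative_citations <- function(citations) {
  if (length(citations) == 0)
    abort2("cannot form a citation observation from an empty cohort",
           "undefined_observation")
  if (any(citations < 0)) abort2("negative citation counts", "domain_error")
  m <- mean(citations)
  list(mean = m, reported = trunc(m))
}

#' Expected eventual citations from an interim observation
#'
#' Applies the saturating accrual model: the observed cohort mean at
#' \eqn{\Delta t} years is divided by \eqn{1 - e^{-\Delta t/\beta}}.
#'
#' @param mean_citations Observed mean cumulative citations (\eqn{\ge 0}).
#' @param years_since_publication \eqn{\Delta t > 0}, years from publication
#'   to the query date.
#' @param beta Discipline constant \eqn{\beta > 0} in years.
#' @return Exact expected total (numeric); round for tabular display.
#' @export
expected_total_citations <- function(mean_citations, years_since_publication,
                                     beta) {
  if (years_since_publication <= 0)
    abort2("years_since_publication must be > 0", "domain_error")
  if (beta <= 0) abort2("beta must be > 0", "domain_error")
  if (mean_citations < 0) abort2("mean_citations must be >= 0", "domain_error")
  mean_citations / (1 - exp(-years_since_publication / beta))
}

#' Per-year observed and expected citation trend
#'
#' For each publication year present in the corpus subset, computes the
#' observed mean cumulative citations and, per discipline constant, the
#' expected eventual mean. Years without publications are omitted.
#'
#' @param corpus Data frame with `year` and `cumulative_citations` columns
#'   (typically the `matches` element of [filter_corpus()]).
#' @param betas Named numeric vector of discipline constants
#'   (default [beta_presets]).
#' @param query_year Year of the literature query; \eqn{\Delta t} is
#'   `query_year - year` in integer years.
#' @return Data frame with columns `year`, `n_publications`, `delta_t`,
#'   `observed_mean`, `observed_reported`, and one `expected_<name>` column
#'   per constant.
#' @export
citation_trend <- function(corpus, betas = beta_presets, query_year) {
  stopifnot(all(c("year", "cumulative_citations") %in% names(corpus)))
  years <- sort(unique(corpus$year))
  years <- years[years < query_year]
  rows <- lapply(years, function(y) {
    cit <- corpus$cumulative_citations[corpus$year == y]
    obs <- mean_cumulative_citations(cit)
    dt <- query_year - y
    row <- data.frame(year = y, n_publications = length(cit), delta_t = dt,
                      observed_mean = obs$mean,
                      observed_reported = obs$reported)
    for (nm in names(betas))
      row[[paste0("expected_", nm)]] <-
        expected_total_citations(obs$mean, dt, betas[[nm]])
    row
  })
  do.call(rbind, rows) %||% data.frame()
}

#' Fit the saturating accrual model to a citation time series
#'
#' Least-squares fit of \eqn{C(t) = N(1 - e^{-t/\beta})} to cumulative
#' citation counts observed at \eqn{\ge 3} time points.
#'
#' @param time Numeric vector of years since publication (> 0).
#' @param cumulative Cumulative citation counts at `time`.
#' @return List with `N`, `beta` and the fitted object in `fit`.
#' @export
fit_beta <- function(time, cumulative) {
  if (length(time) < 3 || length(cumulative) != length(time))
    abort2("need >= 3 matched (time, cumulative) points", "fit_error")
  if (all(cumulative == 0) || stats::var(cumulative) == 0)
    abort2("degenerate series: no accrual signal", "fit_error")
  if (any(diff(cumulative[order(time)]) < 0))
    warn2("cumulative series is not monotone non-decreasing", "fit_warning")
  start <- list(N = max(cumulative) * 1.2, beta = max(time) / 3)
  fit <- tryCatch(
    stats::nls(cumulative ~ N * (1 - exp(-time / beta)), start = start,
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e)
      minpack.lm::nlsLM(cumulative ~ N * (1 - exp(-time / beta)),
                        start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 500)))
  co <- stats::coef(fit)
  list(N = unname(co[["N"]]), beta = unname(co[["beta"]]), fit = fit)
}

#' Normalize per-country publication counts
#'
#' @param hits Named integer vector: publication hits per country.
#' @param denominator_table For `mode = "per_capita"`, a data frame with
#'   columns `country`, `year`, `population` (yearly populations; the
#'   denominator is the mean over `window`); for `mode = "per_output"`, a
#'   data frame with columns `country`, `n_publications` (the country's
#'   total non-review output).
#' @param mode `"per_capita"` or `"per_output"`.
#' @param window Integer years over which populations are averaged
#'   (ignored for `per_output`); default: all years in the table.
#' @return Data frame sorted by decreasing `normalized_rate` with columns
#'   `country`, `hit_count`, `denominator`, `normalized_rate`. Countries
#'   without a denominator row are excluded with a warning.
#' @export
normalize_country_counts <- function(hits, denominator_table,
                                     mode = c("per_capita", "per_output"),
                                     window = NULL) {
  mode <- match.arg(mode)
  countries <- names(hits)
  denom <- vapply(countries, function(cn) {
    if (mode == "per_capita") {
      rows <- denominator_table[denominator_table$country == cn, , drop = FALSE]
      if (!is.null(window)) rows <- rows[rows$year %in% window, , drop = FALSE]
      if (nrow(rows) == 0) NA_real_ else mean(rows$population)
    } else {
      rows <- denominator_table[denominator_table$country == cn, , drop = FALSE]
      if (nrow(rows) == 0) NA_real_ else sum(rows$n_publications)
    }
  }, numeric(1))
  missing <- is.na(denom) | denom <= 0
  if (any(missing))
    warn2(sprintf("no usable denominator for: %s (excluded)",
                  paste(countries[missing], collapse = ", ")),
          "missing_denominator")
  out <- data.frame(country = countries[!missing],
                    hit_count = as.integer(hits[!missing]),
                    denominator = denom[!missing],
                    stringsAsFactors = FALSE)
  out$normalized_rate <- out$hit_count / out$denominator
  out <- out[order(-out$normalized_rate, out$country), , drop = FALSE]
  rownames(out) <- NULL
  out
}
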