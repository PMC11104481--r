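#' Per-site connectivity summaries
#'
#' The five per-site response variables used in the archipelago comparison:
#' the number of sites each site donated larvae to and received larvae from
#' (display-threshold rule: transfers that round to 0.00 at two decimals do
#' not count as edges), the total larval mass exported and imported
#' (off-diagonal, full precision), the retained mass, and the complementary
#' failures (released minus retained).
#'
#' @param cm A [connectivity_matrix()].
#' @param categories Tibble mapping `site_id` to `category`
#'   (`inner`/`outer`); a [place_sites()] table works directly.
#' @param digits Display rounding for degree counts (default 2).
#' @return A `site_summary` tibble: `site_id`, `category`, `n_donated_to`,
#'   `n_received_from`, `larvae_donated`, `larvae_received`, `retained`,
#'   `released`, `failed`.
#' @export
summarize_sites <- function(cm, categories, digits = 2) {
  deg <- connectivity_degrees(cm, digits = digits)
  vals <- cm$values
  off <- vals
  diag(off) <- 0
  rel <- cm$released
  out <- deg |>
    dplyr::mutate(
      larvae_donated = unname(rowSums(off) / 100 * rel),
      larvae_received = as.vector(t(off) %*% (rel / 100)),
      retained = unname(diag(vals) / 100 * rel),
      released = as.numeric(rel),
      failed = .data$released - .data$retained
    )
  cat_tbl <- tibble::as_tibble(categories)[, c("site_id", "category")]
  out <- dplyr::left_join(out, cat_tbl, by = "site_id") |>
    dplyr::select("site_id", "category", dplyr::everything())
  if (any(is.na(out$category)))
    stop_lc("category missing for site(s): ",
            paste(out$site_id[is.na(out$category)], collapse = ", "))
  class(out) <- c("site_summary", class(out))
  out
}

#' Inner vs. outer archipelago comparison by quasi-likelihood GLM
#'
#' Fits a generalized linear model of one connectivity response on the
#' archipelago category with a quasi-Poisson (log link; counts and larval
#' masses) or quasi-binomial (logit link; retention) error structure. The
#' quasi families estimate the dispersion by the Pearson chi-square divided by
#' the residual degrees of freedom, giving conservative tests under
#' overdispersion; point estimates equal those of the plain Poisson/binomial
#' fits. The retention response is supplied as the two-vector
#' (successes = retained, failures = released - retained). The inner-vs-outer
#' contrast is reported as estimate (link scale) with SE, t and a two-sided p
#' on the residual degrees of freedom (n_sites - 2).
#'
#' @param summaries A [summarize_sites()] tibble (or any data frame with a
#'   `category` column and the response columns).
#' @param response Name of a count/mass column, or `"retention"` for the
#'   two-vector success/failure response.
#' @param family `"quasipoisson"` or `"quasibinomial"` (default chosen from
#'   the response).
#' @return An object of class `archipelago_glm` wrapping the fit, with
#'   [tidy()] and [glance()] methods.
#' @export
fit_group_comparison <- function(summaries, response,
                                 family = NULL) {
  stopifnot("category" %in% names(summaries))
  cats <- unique(summaries$category)
  if (length(cats) < 2)
    stop_lc("need both inner and outer sites for the comparison")
  if (any(table(summaries$category) < 2))
    warn("fewer than 2 sites in a category; the contrast is weakly identified")
  summaries$category <- factor(summaries$category, levels = c("outer", "inner"))
  if (response == "retention") {
    family <- family %||% "quasibinomial"
    if (all(summaries$retained == 0))
      stop_lc("all-zero response: no retention anywhere")
    fit <- glm(cbind(retained, failed) ~ category, data = summaries,
               family = quasibinomial())
  } else {
    family <- family %||% "quasipoisson"
    y <- summaries[[response]]
    if (is.null(y)) stop_lc("unknown response column: ", response)
    if (all(y == 0)) stop_lc("all-zero response: ", response)
    fam <- if (family == "quasipoisson") quasipoisson() else quasibinomial()
    fit <- glm(y ~ category, data = summaries, family = fam)
  }
  sm <- summary(fit)
  co <- sm$coefficients["categoryinner", ]
  structure(list(fit = fit, response = response, family = family,
                 estimate = co[["Estimate"]], se = co[["Std. Error"]],
                 t = co[["t value"]], p = co[["Pr(>|t|)"]],
                 dispersion = sm$dispersion,
                 df_residual = fit$df.residual),
            class = "archipelago_glm")
}

#' @export
print.archipelago_glm <- function(x, digits = 3, ...) {
  cat(sprintf(
    "%s (%s): inner - outer = %.*f +/- %.*f, t = %.*f, p = %.4g (df = %d)\n",
    x$response, x$family, digits, x$estimate, digits, x$se, digits, x$t,
    x$p, x$df_residual))
  invisible(x)
}

#' @export
tidy.archipelago_glm <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"])
  )
}

#' @export
glance.archipelago_glm <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    family = x$family,
    dispersion = x$dispersion,
    df.residual = x$df_residual,
    deviance = x$fit$deviance,
    null.deviance = x$fit$null.deviance
  )
}
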