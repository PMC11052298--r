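# Cross-species statistical layer: OLS with class dummies and interactions,
# per-class equation derivation, midrank transforms, rank regressions, and
# floor-exponential nonlinear fits of machinery counts on ranked generation
# time.

#' Ordinary least squares with class dummies and optional interactions
#'
#' Thin wrapper around [stats::lm()] that standardises the reporting used
#' throughout the cross-species analyses: per-term coefficient, standard
#' error (from the unbiased residual variance), t statistic, two-tailed p,
#' and R-squared. Gene expression enters these models as a dummy (HEG = 0,
#' REST = 1; see [encode_ge()]). When a directional prediction is declared
#' for a term, a one-tailed p (p/2) is reported alongside — never silently.
#'
#' @param data Data frame of model variables.
#' @param formula Model formula, e.g. `aug_percent ~ rank_gt + gc + ge`.
#' @param one_tailed Character vector of term names with a declared
#'   directional hypothesis.
#' @return An `ols_fit` object; see [tidy()] and [glance()] methods.
#' @export
ols_fit <- function(data, formula, one_tailed = character(0)) {
  fit <- lm(formula, data = data)
  if (any(is.na(coef(fit)))) {
    abort(paste0("singular design; collinear terms: ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  tb <- tibble::tibble(
    term = rownames(ct),
    estimate = unname(ct[, 1]), std_error = unname(ct[, 2]),
    statistic = unname(ct[, 3]), p_value = unname(ct[, 4])
  )
  if (length(one_tailed)) {
    tb$p_one_tailed <- ifelse(tb$term %in% one_tailed, tb$p_value / 2, NA_real_)
  }
  structure(list(
    fit = fit, coefficients = tb,
    r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
    n = length(sm$residuals), formula = formula
  ), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("<ols_fit> ", deparse(x$formula), "\n", sep = "")
  print(as.data.frame(x$coefficients), digits = 6)
  cat(sprintf("R-squared: %.4f  n = %d\n", x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.ols_fit <- function(x, ...) x$coefficients

#' @export
glance.ols_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
                 n = x$n)
}

#' Encode expression class as the regression dummy
#'
#' HEG = 0, REST = 1, the convention used in all class-contrast models here
#' (so the GE coefficient is the REST-minus-HEG offset).
#'
#' @param class Character vector of `"HEG"` / `"REST"`.
#' @return Numeric 0/1 vector.
#' @export
encode_ge <- function(class) {
  if (!all(class %in% c("HEG", "REST"))) abort("class must be HEG or REST")
  ifelse(class == "HEG", 0, 1)
}

#' Per-class linear equations from a fitted class-contrast model
#'
#' Substitutes the expression dummy (HEG = 0, REST = 1) and any
#' `predictor:GE` interactions into the fitted model, returning one linear
#' equation per class: the class intercept and per-predictor slopes.
#'
#' @param x An `ols_fit` whose model contains a `ge` dummy term.
#' @param ge_term Name of the dummy term (default `"ge"`).
#' @return Tibble with `class`, `term` (`"(Intercept)"` or predictor name)
#'   and `value`.
#' @export
derive_class_equations <- function(x, ge_term = "ge") {
  tb <- x$coefficients
  if (!ge_term %in% tb$term) {
    abort(sprintf("model has no '%s' term; class equations undefined", ge_term))
  }
  est <- setNames(tb$estimate, tb$term)
  is_inter <- grepl(":", tb$term)
  main <- tb$term[!is_inter & tb$term != ge_term]
  inter <- tb$term[is_inter]
  # map each interaction to its non-GE partner
  inter_partner <- vapply(strsplit(inter, ":"), function(p) {
    p <- setdiff(p, ge_term)
    if (length(p) != 1) abort("only pairwise interactions with the GE dummy are supported")
    p
  }, character(1))
  rows <- purrr::map(c(0, 1), function(g) {
    vals <- est[main]
    names(vals) <- main
    vals["(Intercept)"] <- est["(Intercept)"] + g * est[ge_term]
    for (k in seq_along(inter)) {
      vals[inter_partner[k]] <- vals[inter_partner[k]] + g * est[inter[k]]
    }
    tibble::tibble(class = if (g == 0) "HEG" else "REST",
                   term = names(vals), value = unname(vals))
  })
  dplyr::bind_rows(rows)
}

#' Midrank transform
#'
#' Ranks smallest to largest with ties replaced by their average rank
#' (midranks), the transform used for rank regressions of generation time
#' and adaptation indices.
#'
#' @param values Numeric vector.
#' @return Numeric vector of midranks (sums to n(n+1)/2).
#' @examples
#' rank_transform(c(10, 20, 20, 30))  # 1 2.5 2.5 4
#' @export
rank_transform <- function(values) {
  if (length(values) < 1) abort("need at least one value")
  rank(values, ties.method = "average")
}

#' Simple OLS on two ranked variables
#'
#' @param rank_y,rank_x Equal-length rank vectors (n >= 3).
#' @return An `ols_fit` of `rank_y ~ rank_x`.
#' @export
rank_regression <- function(rank_y, rank_x) {
  if (length(rank_y) != length(rank_x)) abort("rank vectors must have equal length")
  if (length(rank_y) < 3) abort("need at least 3 observations")
  ols_fit(tibble::tibble(rank_y = rank_y, rank_x = rank_x),
          rank_y ~ rank_x)
}

#' Floor-exponential least squares fit
#'
#' Fits `y = floor + a * exp(-b * x)` by unweighted least squares. The
#' floor is either a fixed constant (e.g. 1, the minimum number of rrn
#' operons a genome can carry) or a free parameter `c` (e.g. the minimal
#' tRNA gene set). Because the model is linear in `(c, a)` given `b`, the
#' fit profiles the residual sum of squares over `b`: each start in a
#' documented multi-start grid (`b` in 0.05, 0.1, 0.2, 0.5, 1, 2) is refined
#' by one-dimensional local optimisation and the best RSS is kept, making
#' the result deterministic without a global solver.
#'
#' @param x Strictly positive predictor (typically the generation-time rank).
#' @param y Response counts.
#' @param floor Fixed floor value, or `NULL` (default) to estimate `c`.
#' @param b_starts Multi-start grid for the decay rate.
#' @return A `floor_exp_fit` object with elements `a`, `b`, `c`,
#'   `floor_fixed`, `rss`, `converged`, `degenerate`, `starts`.
#' @examples
#' x <- 1:9
#' fit <- fit_floor_exponential(x, 1 + 50 * exp(-0.5 * x), floor = 1)
#' @export
fit_floor_exponential <- function(x, y, floor = NULL,
                                  b_starts = c(0.05, 0.1, 0.2, 0.5, 1, 2)) {
  free_floor <- is.null(floor)
  if (any(x <= 0)) abort("x must be strictly positive")
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < (if (free_floor) 4L else 3L)) {
    abort("too few observations for the requested parameterisation")
  }
  if (stats::var(y) == 0) {
    return(structure(list(
      a = 0, b = NA_real_, c = if (free_floor) mean(y) else floor,
      floor_fixed = !free_floor, rss = 0, converged = FALSE,
      degenerate = TRUE, starts = b_starts, x = x, y = y
    ), class = "floor_exp_fit"))
  }
  solve_ab <- function(b) {
    e <- exp(-b * x)
    if (free_floor) {
      X <- cbind(1, e)
      cf <- tryCatch(qr.coef(qr(X), y), error = function(err) c(NA, NA))
      if (anyNA(cf)) return(list(rss = Inf, c = NA, a = NA))
      r <- y - X %*% cf
      list(rss = sum(r^2), c = cf[1], a = cf[2])
    } else {
      z <- y - floor
      a <- sum(z * e) / sum(e^2)
      list(rss = sum((z - a * e)^2), c = floor, a = a)
    }
  }
  refine <- function(b0) {
    op <- optimize(function(b) solve_ab(b)$rss,
                   interval = c(b0 / 5, b0 * 5), tol = 1e-10)
    list(b = op$minimum, rss = op$objective)
  }
  tried <- purrr::map(b_starts, refine)
  grid_rss <- vapply(b_starts, function(b) solve_ab(b)$rss, numeric(1))
  best <- tried[[which.min(purrr::map_dbl(tried, "rss"))]]
  sol <- solve_ab(best$b)
  structure(list(
    a = unname(sol$a), b = best$b, c = unname(sol$c),
    floor_fixed = !free_floor, rss = sol$rss,
    converged = is.finite(sol$rss) && sol$rss <= min(grid_rss) + 1e-9,
    degenerate = FALSE, starts = b_starts, x = x, y = y
  ), class = "floor_exp_fit")
}

#' @export
print.floor_exp_fit <- function(x, ...) {
  cat(sprintf("<floor_exp_fit> y = %s + %.4g * exp(-%.4g x)  RSS = %.4g%s\n",
              if (x$floor_fixed) format(x$c) else sprintf("c=%.4g", x$c),
              x$a, x$b, x$rss,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' @export
tidy.floor_exp_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c"),
                 estimate = c(x$a, x$b, x$c),
                 fixed = c(FALSE, FALSE, x$floor_fixed))
}

#' @export
glance.floor_exp_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged,
                 degenerate = x$degenerate, n = length(x$y))
}

#' @export
predict.floor_exp_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  object$c + object$a * exp(-object$b * x)
}

#' @export
autoplot.floor_exp_fit <- function(object, ...) {
  grid <- seq(min(object$x), max(object$x), length.out = 200)
  ggplot2::ggplot(tibble::tibble(x = object$x, y = object$y),
                  ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_line(data = tibble::tibble(x = grid,
                                             y = predict(object, grid)),
                       colour = "grey30") +
    ggplot2::labs(x = "rank of generation time", y = "count")
}
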