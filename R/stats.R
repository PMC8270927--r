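#' Pearson correlation with regression line
#'
#' Product-moment correlation with a two-sided p-value from the t-transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, plus
#' the least-squares regression line of `y` on `x`. A data frame may be
#' piped in as the first argument with bare column names.
#'
#' @param data optional data frame supplying `x` and `y` columns.
#' @param x,y numeric vectors (or bare column names of `data`), n >= 3.
#' @return Object of class `pf_correlation` with fields `r`, `p`, `n`,
#'   `slope`, `intercept`, `t`, `df`, and the data; `r` is `NA` and flagged
#'   when either input has zero variance. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' pearson(x = c(1, 2, 3, 5), y = c(2.1, 3.9, 6.2, 9.8))
#' @export
pearson <- function(data = NULL, x, y) {
  if (!is.null(data) && is.data.frame(data)) {
    x <- rlang::eval_tidy(rlang::enquo(x), data)
    y <- rlang::eval_tidy(rlang::enquo(y), data)
  } else if (!is.null(data) && is.numeric(data)) {
    # called as pearson(x, y) without a data frame
    y <- x
    x <- data
  }
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("at least 3 complete pairs are required")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    out <- list(r = NA_real_, p = NA_real_, n = n, slope = NA_real_,
                intercept = NA_real_, t = NA_real_, df = n - 2L,
                degenerate = TRUE, x = x, y = y)
    class(out) <- "pf_correlation"
    warning("zero variance in x or y: correlation undefined")
    return(out)
  }
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  slope <- r * sy / sx
  intercept <- mean(y) - slope * mean(x)
  out <- list(r = r, p = p, n = n, slope = slope, intercept = intercept,
              t = tstat, df = n - 2L, degenerate = FALSE, x = x, y = y)
  class(out) <- "pf_correlation"
  out
}

#' @export
print.pf_correlation <- function(x, ...) {
  cat(sprintf("<pf_correlation> r = %.3f (r^2 = %.3f), p = %.3g, n = %d\n",
              x$r, x$r^2, x$p, x$n))
  cat(sprintf("  regression: y = %.4g + %.4g x\n", x$intercept, x$slope))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.pf_correlation <- function(x, ...) {
  tibble::tibble(r = x$r, r_squared = x$r^2, statistic = x$t, p_value = x$p,
                 n = x$n, slope = x$slope, intercept = x$intercept)
}

#' @export
glance.pf_correlation <- function(x, ...) tidy(x)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
#' @export
autoplot.pf_correlation <- function(object, ...) {
  df <- tibble::tibble(x = object$x, y = object$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed") +
    ggplot2::labs(subtitle = sprintf("r = %.3f, p = %.3g, n = %d",
                                     object$r, object$p, object$n)) +
    ggplot2::theme_minimal()
}

#' Permutation p-value for a Pearson correlation
#'
#' Two-sided Monte-Carlo permutation test: `y` is permuted `n_perm` times
#' and the p-value is `(1 + #{|r_perm| >= |r_obs|}) / (n_perm + 1)`. Used as
#' an independent cross-check of the t-transform p-value.
#'
#' @param x,y numeric vectors.
#' @param n_perm number of permutations (default 1e4).
#' @param seed integer seed.
#' @return scalar p-value.
#' @export
permutation_pvalue <- function(x, y, n_perm = 1e4, seed = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("at least 3 complete pairs are required")
  r_obs <- abs(stats::cor(x, y))
  xc <- x - mean(x)
  denom <- sqrt(sum(xc^2))
  with_phantom_seed(seed, {
    yc <- y - mean(y)
    sy <- sqrt(sum(yc^2))
    hits <- 0L
    block <- 1e4L
    done <- 0L
    while (done < n_perm) {
      nb <- min(block, n_perm - done)
      P <- vapply(seq_len(nb), function(i) yc[sample.int(n)], numeric(n))
      r_perm <- abs(as.numeric(crossprod(xc, P)) / (denom * sy))
      hits <- hits + sum(r_perm >= r_obs - 1e-12)
      done <- done + nb
    }
    (1 + hits) / (n_perm + 1)
  })
}

#' Group summary: mean and sample standard deviation
#'
#' Continuous variables summarized as mean and the n-1 (sample) standard
#' deviation.
#'
#' @param values numeric vector, n >= 2 for a defined SD.
#' @return tibble with columns `mean`, `sd`, `n`; `sd` is `NA` and flagged
#'   with a warning when n < 2.
#' @examples
#' group_summary(c(0, 2))  # mean 1, sd sqrt(2)
#' @export
group_summary <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) {
    warning("fewer than 2 values: SD undefined")
    return(tibble::tibble(mean = if (n) mean(values) else NA_real_,
                          sd = NA_real_, n = n))
  }
  tibble::tibble(mean = mean(values), sd = stats::sd(values), n = n)
}

#' Slice-by-slice composition and uptake profiles
#'
#' Reshapes a joined ROI table into tidy long format for slice-profile
#' plotting (fat fraction and R2* against TBR along the vessel axis) and
#' appends each subject's slice-wise Pearson correlations. Subjects with
#' fewer than 3 slices keep their profile rows but get no correlation.
#'
#' @param roi tibble with columns `subject`, `slice_id`, `ff_mean`,
#'   `r2star_mean` and a `tbr` (or `suv_mean`) column per slice.
#' @param uptake_col name of the uptake column (default `"tbr"`).
#' @return list with `profiles` (long tibble: subject, slice_id, measure,
#'   value) and `correlations` (tibble: subject, measure, r, p, n).
#' @export
slice_profiles <- function(roi, uptake_col = "tbr") {
  stopifnot(all(c("subject", "slice_id", "ff_mean", "r2star_mean",
                  uptake_col) %in% names(roi)))
  long <- tidyr::pivot_longer(
    dplyr::select(roi, "subject", "slice_id", "ff_mean", "r2star_mean",
                  dplyr::all_of(uptake_col)),
    cols = c("ff_mean", "r2star_mean", dplyr::all_of(uptake_col)),
    names_to = "measure", values_to = "value")

  cors <- dplyr::bind_rows(purrr::map(split(roi, roi$subject), function(d) {
    if (nrow(d) < 3) return(NULL)
    up <- d[[uptake_col]]
    rows <- purrr::map(c("ff_mean", "r2star_mean"), function(col) {
      fit <- tryCatch(suppressWarnings(pearson(x = d[[col]], y = up)),
                      error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      tibble::tibble(measure = col, r = fit$r, p = fit$p, n = fit$n)
    })
    dplyr::mutate(dplyr::bind_rows(rows), subject = d$subject[1], .before = 1)
  }))
  list(profiles = long, correlations = cors)
}

#' Slice-profile plot for one or more subjects
#'
#' @param profiles long tibble from [slice_profiles()]`$profiles`.
#' @return a ggplot object, faceted by subject and measure.
#' @export
plot_slice_profiles <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$slice_id, y = .data$value,
                               colour = .data$measure)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(measure ~ subject, scales = "free_y") +
    ggplot2::labs(x = "slice (vessel axis)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
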