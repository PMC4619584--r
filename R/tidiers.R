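#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Null replicate values of a null-model test
#'
#' @param x a [null_test()] object.
#' @param ... unused.
#' @return a tibble with one row per null replicate: `replicate`, `value`.
#' @exportS3Method generics::tidy
#' @export
tidy.null_test <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$null_values),
                 value = x$null_values)
}

#' One-row summary of a null-model test
#'
#' @param x a [null_test()] object.
#' @param ... unused.
#' @return a one-row tibble: statistic, model, observed value, null mean
#'   and SD, z, p, replicates.
#' @exportS3Method generics::glance
#' @export
glance.null_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic_name, model = x$model,
                 observed = x$observed, null_mean = x$null_mean,
                 null_sd = x$null_sd, z = x$z, p = x$p,
                 replicates = x$replicates)
}

#' Mean extinction curve of a robustness result
#'
#' @param x a [random_robustness()] object.
#' @param ... unused.
#' @return the mean curve tibble (`removed_frac`, `surviving_frac`).
#' @exportS3Method generics::tidy
#' @export
tidy.robustness <- function(x, ...) x$curve

#' One-row summary of a robustness result
#'
#' @param x a [random_robustness()] object.
#' @param ... unused.
#' @return a one-row tibble: removal level, mean R, SD, orders.
#' @exportS3Method generics::glance
#' @export
glance.robustness <- function(x, ...) {
  tibble::tibble(removal_level = x$removal_level, R = x$R, R_sd = x$R_sd,
                 n_orders = x$n_orders)
}
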