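# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained meta-classifier
#'
#' @param x An `istable_model`.
#' @param ... Unused.
#' @return Tibble of configuration terms (kernel, gamma, cost, mode, window
#'   size).
#' @export
tidy.istable_model <- function(x, ...) {
  tibble(
    term = c("kernel", "gamma", "cost", "mode", "window_size"),
    value = c("radial", format(x$config$gamma), format(x$config$cost),
              x$mode, format(x$window_size))
  )
}

#' @rdname tidy.istable_model
#' @return `glance`: one-row tibble with training size, class counts and
#'   support-vector count.
#' @export
glance.istable_model <- function(x, ...) {
  tibble(
    n_train = x$n_train,
    n_positive = as.integer(x$class_counts[["POSITIVE"]]),
    n_negative = as.integer(x$class_counts[["NEGATIVE"]]),
    n_support_vectors = nrow(x$fit$SV),
    gamma = x$config$gamma,
    cost = x$config$cost,
    mode = x$mode
  )
}

#' Tidy a cross-validation result
#'
#' @param x A `stab_cv` object.
#' @param ... Unused.
#' @return `tidy`: the per-record held-out predictions; `glance`: the pooled
#'   one-row metrics (Sn, Sp, Acc, MCC and counts).
#' @export
tidy.stab_cv <- function(x, ...) x$predictions

#' @rdname tidy.stab_cv
#' @export
glance.stab_cv <- function(x, ...) {
  dplyr::bind_cols(
    x$metrics,
    tibble(k = x$config$k, mode = x$config$mode, n = x$config$n)
  )
}
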