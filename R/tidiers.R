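#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted PLS-DA model
#'
#' One row per feature: regression coefficient and VIP score.
#'
#' @param x A `plsda_model`.
#' @param ... Unused.
#' @return A tibble with `feature_id`, `estimate`, `vip`.
#' @export
tidy.plsda_model <- function(x, ...) {
  vip <- vip_scores(x)
  tibble(feature_id = vip$feature_id,
         estimate = unname(x$coefficients),
         vip = vip$vip)
}

#' @rdname tidy.plsda_model
#' @export
glance.plsda_model <- function(x, ...) {
  tibble(n_lv = x$n_lv, n_features = length(x$feature_ids),
         n_train = nrow(x$T))
}

#' Tidy a discriminant-fit pipeline
#'
#' @param x A `discriminant_fit`.
#' @param ... Unused.
#' @return Per-feature tibble of the full model (see
#'   [tidy.plsda_model()]) with a `selected` flag.
#' @export
tidy.discriminant_fit <- function(x, ...) {
  out <- tidy(x$model)
  out$selected <- out$feature_id %in% (x$selected_features %||% character())
  out
}

#' @rdname tidy.discriminant_fit
#' @export
glance.discriminant_fit <- function(x, ...) {
  tibble(
    n_lv = x$n_lv,
    rmsecv = if (is.null(x$cv)) NA_real_ else
      x$cv$rmsecv[x$cv$n_lv == x$n_lv],
    n_features = length(x$model$feature_ids),
    n_selected = length(x$selected_features %||% character()),
    n_train = length(x$train_ids)
  )
}

#' Tidy discriminant figures of merit
#'
#' @param x A `discriminant_metrics`.
#' @param ... Unused.
#' @return Long tibble `metric`, `estimate`, `lower`, `upper`
#'   (percent for proportions, ratio scale for PLR/NLR, plus an `auroc`
#'   row on the 0-1 scale).
#' @export
tidy.discriminant_metrics <- function(x, ...) {
  dplyr::bind_rows(
    x$metrics,
    tibble(metric = "auroc", estimate = x$auroc,
           lower = NA_real_, upper = NA_real_)
  )
}

#' @rdname tidy.discriminant_metrics
#' @export
glance.discriminant_metrics <- function(x, ...) {
  c0 <- x$counts
  tibble(tp = c0$tp, fn = c0$fn, tn = c0$tn, fp = c0$fp,
         auroc = x$auroc)
}
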