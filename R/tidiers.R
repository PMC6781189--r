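# broom-style tidiers for fitted objects and result types.

#' Tidy a training history
#'
#' @param x A `cam_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble (epoch, ce, cam, total, val_loss,
#'   val_accuracy).
#' @export
tidy.cam_fit <- function(x, ...) x$history

#' One-row summary of a training run
#'
#' @param x A `cam_fit`.
#' @param ... Unused.
#' @export
glance.cam_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(loss_mode = x$config$loss_mode,
                 epochs = nrow(h),
                 selected_epoch = x$selected_epoch,
                 best_val_loss = if (nrow(h)) min(h$val_loss) else NA_real_,
                 final_train_total = if (nrow(h)) h$total[nrow(h)] else NA_real_,
                 final_val_accuracy = if (nrow(h)) h$val_accuracy[nrow(h)] else NA_real_)
}

#' Tidy an odds-ratio result
#'
#' @param x An `odds_ratio_result`.
#' @param ... Unused.
#' @return Tibble with broom-style columns: estimate, std.error, conf.low,
#'   conf.high.
#' @export
tidy.odds_ratio_result <- function(x, ...) {
  tibble::tibble(term = "odds_ratio", estimate = x$odds_ratio,
                 std.error = x$se, conf.low = x$ci_low, conf.high = x$ci_high)
}

#' Tidy ROC curve points
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) x$points

#' One-row ROC summary
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}
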