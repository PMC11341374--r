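#' Agreement metrics between two artifact grids
#'
#' Element-wise confusion counts over all channel-segment elements, treating
#' `ref_grid` as ground truth, plus the derived metrics: accuracy,
#' sensitivity (TPR), specificity (TNR), precision (PPV), F1, and Cohen's
#' kappa with chance agreement
#' `pe = prev_test * prev_ref + (1 - prev_test) * (1 - prev_ref)`.
#' Ratios with zero denominators are reported as `NaN`.
#'
#' @param test_grid,ref_grid [artifact_grid()]s of identical shape.
#' @return An object of class `scrub_confusion`.
#' @export
confusion_from_grids <- function(test_grid, ref_grid) {
  if (!identical(dim(test_grid$values), dim(ref_grid$values))) {
    abort("Grids must have identical shapes.")
  }
  a <- test_grid$values
  b <- ref_grid$values
  confusion_metrics(tp = sum(a & b), fp = sum(a & !b),
                    fn = sum(!a & b), tn = sum(!a & !b))
}

confusion_metrics <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  rat <- function(num, den) if (den <= 0) NaN else num / den
  acc <- rat(tp + tn, n)
  sens <- rat(tp, tp + fn)
  spec <- rat(tn, tn + fp)
  prec <- rat(tp, tp + fp)
  f1 <- if (is.nan(prec) || is.nan(sens) || (prec + sens) == 0) NaN else
    2 * prec * sens / (prec + sens)
  prev_ref <- rat(tp + fn, n)
  prev_test <- rat(tp + fp, n)
  pe <- prev_test * prev_ref + (1 - prev_test) * (1 - prev_ref)
  kappa <- if (is.nan(pe) || pe == 1) {
    if (!is.nan(acc) && acc == 1) 1 else NaN
  } else {
    (acc - pe) / (1 - pe)
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = n,
                 prevalence_ref = prev_ref, prevalence_test = prev_test,
                 accuracy = acc, kappa = kappa, sensitivity = sens,
                 specificity = spec, precision = prec, f1 = f1),
            class = "scrub_confusion")
}

#' @export
print.scrub_confusion <- function(x, ...) {
  cat(sprintf(paste0("<scrub_confusion> n=%g acc=%.3f kappa=%.3f sens=%.3f ",
                     "spec=%.3f prec=%.3f f1=%.3f\n"),
              x$n, x$accuracy, x$kappa, x$sensitivity, x$specificity,
              x$precision, x$f1))
  invisible(x)
}

#' @export
tidy.scrub_confusion <- function(x, ...) {
  tibble::tibble(metric = c("tp", "fp", "fn", "tn", "prevalence_ref",
                            "prevalence_test", "accuracy", "kappa",
                            "sensitivity", "specificity", "precision", "f1"),
                 value = c(x$tp, x$fp, x$fn, x$tn, x$prevalence_ref,
                           x$prevalence_test, x$accuracy, x$kappa,
                           x$sensitivity, x$specificity, x$precision, x$f1))
}

#' @export
glance.scrub_confusion <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy, kappa = x$kappa,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 precision = x$precision, f1 = x$f1)
}

#' Reconstruct a full metric set from printed summary values
#'
#' Published agreement tables often report only the element count, the two
#' prevalences and the sensitivity. Those four values determine the whole
#' (real-valued) confusion matrix: `P = prev_ref * N`, `TP = sens * P`,
#' `FP = prev_test * N - TP`, `FN = P - TP`, `TN = N - P - FP`. Counts are
#' kept real-valued (not rounded to integers) so that the tolerance of
#' metrics derived from rounded inputs stays transparent.
#'
#' @param n_elements Total channel-segment elements N.
#' @param prevalence_ref Artifact prevalence in the reference annotation.
#' @param prevalence_test Artifact prevalence in the test (automatic) grids.
#' @param sensitivity True-positive rate of the test against the reference.
#' @return A `scrub_confusion` with real-valued counts.
#' @export
metrics_from_summary <- function(n_elements, prevalence_ref, prevalence_test,
                                 sensitivity) {
  if (n_elements <= 0 || prevalence_ref < 0 || prevalence_ref > 1 ||
      prevalence_test < 0 || prevalence_test > 1 ||
      sensitivity < 0 || sensitivity > 1) {
    abort("Summary inputs out of range.")
  }
  p <- prevalence_ref * n_elements
  tp <- sensitivity * p
  fp <- prevalence_test * n_elements - tp
  if (fp < 0) {
    abort("Inconsistent summary: prevalence_test * N < sensitivity * prevalence_ref * N.")
  }
  fn <- p - tp
  tn <- n_elements - p - fp
  confusion_metrics(tp, fp, fn, tn)
}

#' Event-level matching against ground truth
#'
#' A reference event is recovered when some test event on the same channel
#' overlaps at least `min_overlap` of the reference span; a test event is a
#' true detection when it overlaps at least `min_overlap` of some reference
#' span on its channel. Sensitivity is the recovered fraction of reference
#' events, precision the true fraction of test events.
#'
#' @param test,ref [event_table()]s.
#' @param min_overlap Required overlap as a fraction of the reference span.
#' @return A tibble with `n_test`, `n_ref`, `tp_ref` (reference events
#'   recovered), `tp_test`, `sensitivity`, `precision`.
#' @export
match_events <- function(test, ref, min_overlap = 0.5) {
  overlap_ok <- function(ts, te, rs, re) {
    pmax(0, pmin(te, re) - pmax(ts, rs)) >= min_overlap * (re - rs)
  }
  ref_hit <- vapply(seq_len(nrow(ref)), function(i) {
    same <- test$channel == ref$channel[i]
    any(overlap_ok(test$start_s[same], test$end_s[same],
                   ref$start_s[i], ref$end_s[i]))
  }, TRUE)
  test_hit <- vapply(seq_len(nrow(test)), function(j) {
    same <- ref$channel == test$channel[j]
    any(overlap_ok(test$start_s[j], test$end_s[j],
                   ref$start_s[same], ref$end_s[same]))
  }, TRUE)
  tibble::tibble(
    n_test = nrow(test), n_ref = nrow(ref),
    tp_ref = sum(ref_hit), tp_test = sum(test_hit),
    sensitivity = if (nrow(ref)) mean(ref_hit) else NaN,
    precision = if (nrow(test)) mean(test_hit) else NaN)
}
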