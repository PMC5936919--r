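# Solvent screening: validation of predicted against measured partition
# coefficients and transparent, policy-driven solvent ranking.

#' Validate predicted partition coefficients against experiments
#'
#' Per-solvent absolute deviation |logP_pred - logP_exp| with a summary
#' (mean absolute deviation, count exceeding the acceptance threshold).
#' Records lacking either value are listed as unvalidatable rather than
#' dropped silently.
#'
#' @param records data.frame with at least `solvent`, `logP_pred`,
#'   `logP_exp` (either logP may be `NA`).
#' @param threshold acceptable absolute logP deviation (default 0.2, the
#'   conventional accuracy band for COSMO-type predictions).
#' @return list of class `prediction_validation`: `table` (with `deviation`
#'   and `exceeds_threshold`), `unvalidatable` (solvent names), `mad`,
#'   `n_exceeding`, `threshold`.
#' @export
validate_predictions <- function(records, threshold = 0.2) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("empty record table", call. = FALSE)
  needed <- c("solvent", "logP_pred", "logP_exp")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop(sprintf("records lack column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  both <- is.finite(records$logP_pred) & is.finite(records$logP_exp)
  if (!any(both)) {
    stop("no record has both predicted and experimental logP", call. = FALSE)
  }
  tab <- records[both, , drop = FALSE]
  tab$deviation <- abs(tab$logP_pred - tab$logP_exp)
  tab$exceeds_threshold <- tab$deviation > threshold
  structure(list(
    table = tab,
    unvalidatable = records$solvent[!both],
    mad = mean(tab$deviation),
    n_exceeding = sum(tab$exceeds_threshold),
    threshold = threshold
  ), class = "prediction_validation")
}

#' Ranking policy for solvent selection
#'
#' The default lexicographic policy orders by ICH Q3C toxicity class
#' (higher class = less problematic solvent, so descending), then partition
#' coefficient (descending), then vapour pressure (ascending: lower loss and
#' easier handling). A weighted-score alternative ranks by the weighted sum
#' of direction-adjusted, rescaled keys.
#'
#' @param keys character vector of column names to order on.
#' @param directions `"desc"`/`"asc"` per key (`"desc"` = larger is better).
#' @param method `"lexicographic"` or `"weighted"`.
#' @param weights numeric weights per key (weighted method only).
#' @return object of class `ranking_policy`.
#' @export
ranking_policy <- function(keys = c("toxicity_class", "logP", "vapour_pressure"),
                           directions = c("desc", "desc", "asc"),
                           method = c("lexicographic", "weighted"),
                           weights = NULL) {
  method <- match.arg(method)
  stopifnot(length(keys) == length(directions),
            all(directions %in% c("asc", "desc")))
  if (method == "weighted") {
    if (is.null(weights)) weights <- rep(1, length(keys))
    stopifnot(length(weights) == length(keys), all(weights >= 0))
  }
  structure(list(keys = keys, directions = directions, method = method,
                 weights = weights),
            class = "ranking_policy")
}

#' Rank candidate solvents under a stated policy
#'
#' Stable, deterministic ranking of solvent records, with a human-readable
#' rationale line per solvent and explicit tie reporting. The `logP` key is
#' resolved as the experimental value where present, else the predicted one.
#' Solvents flagged water-miscible (whose two-phase partition data are
#' unreliable) keep their rank but are annotated in the rationale.
#'
#' @param records data.frame with `solvent` plus the policy keys (typically
#'   `toxicity_class`, `logP_pred`/`logP_exp`, `vapour_pressure`, and
#'   optionally logical `miscible_with_water`).
#' @param policy [ranking_policy()].
#' @return data.frame of class `solvent_ranking`: records ordered best-first
#'   with `rank`, `tied_with_next`, `reliability_flag`, `rationale` columns
#'   (plus `score` under the weighted method).
#' @export
rank_solvents <- function(records, policy = ranking_policy()) {
  stopifnot(is.data.frame(records), inherits(policy, "ranking_policy"))
  if (nrow(records) == 0L) stop("empty record table", call. = FALSE)
  records <- as.data.frame(records)
  if (!"logP" %in% names(records) && "logP" %in% policy$keys) {
    pred <- if ("logP_pred" %in% names(records)) records$logP_pred else NA_real_
    expv <- if ("logP_exp" %in% names(records)) records$logP_exp else NA_real_
    records$logP <- ifelse(is.finite(expv), expv, pred)
  }
  missing_keys <- setdiff(policy$keys, names(records))
  if (length(missing_keys)) {
    stop(sprintf("ranking policy references missing field(s): %s",
                 paste(missing_keys, collapse = ", ")), call. = FALSE)
  }
  miscible <- if ("miscible_with_water" %in% names(records)) {
    isTRUE_vec <- records$miscible_with_water
    !is.na(isTRUE_vec) & isTRUE_vec
  } else rep(FALSE, nrow(records))

  signed <- mapply(function(key, dir) {
    v <- records[[key]]
    if (!is.numeric(v)) stop(sprintf("ranking key '%s' is not numeric", key),
                             call. = FALSE)
    if (dir == "desc") -v else v
  }, policy$keys, policy$directions, SIMPLIFY = FALSE)

  if (policy$method == "lexicographic") {
    ord <- do.call(order, signed)       # stable radix/merge order
    out <- records[ord, , drop = FALSE]
    key_mat <- do.call(cbind, signed)[ord, , drop = FALSE]
    tied <- c(vapply(seq_len(nrow(out) - 1L), function(i) {
      isTRUE(all(key_mat[i, ] == key_mat[i + 1L, ]))
    }, logical(1)), FALSE)
  } else {
    rescale <- function(v) {
      rng <- range(v, na.rm = TRUE)
      if (diff(rng) == 0) rep(0, length(v)) else (v - rng[1]) / diff(rng)
    }
    # direction-adjust so that larger score = better, then weight
    score <- Reduce(`+`, mapply(function(v, w) w * rescale(-v),
                                signed, policy$weights, SIMPLIFY = FALSE))
    ord <- order(-score)
    out <- records[ord, , drop = FALSE]
    out$score <- score[ord]
    tied <- c(diff(out$score) == 0, FALSE)
  }
  out$rank <- seq_len(nrow(out))
  out$tied_with_next <- tied
  out$reliability_flag <- ifelse(miscible[ord], "polar-unreliable", "reliable")
  out$rationale <- vapply(seq_len(nrow(out)), function(i) {
    bits <- vapply(seq_along(policy$keys), function(j) {
      sprintf("%s=%g (%s)", policy$keys[j], out[[policy$keys[j]]][i],
              ifelse(policy$directions[j] == "desc", "higher better", "lower better"))
    }, character(1))
    note <- if (out$reliability_flag[i] == "polar-unreliable") {
      "; water-miscible: partition data unreliable"
    } else ""
    paste0(out$solvent[i], ": ", paste(bits, collapse = ", "), note)
  }, character(1))
  rownames(out) <- NULL
  class(out) <- c("solvent_ranking", "data.frame")
  out
}

#' @export
print.solvent_ranking <- function(x, ...) {
  cat("Solvent ranking (best first):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %d. %s%s\n", x$rank[i], x$rationale[i],
                ifelse(x$tied_with_next[i], "  [tied with next]", "")))
  }
  invisible(x)
}

#' @export
print.prediction_validation <- function(x, ...) {
  cat(sprintf("Prediction validation: MAD = %.3f logP units, %d of %d exceed %.2f\n",
              x$mad, x$n_exceeding, nrow(x$table), x$threshold))
  if (length(x$unvalidatable)) {
    cat("  unvalidatable (missing a value):", paste(x$unvalidatable, collapse = ", "), "\n")
  }
  invisible(x)
}
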