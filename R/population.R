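# Population pipeline: basal x apical simulation grid, majority-vote basal
# profiling, Mann-Whitney feature comparison, balanced Bayes classification
# and feature correlation.

#' Run a basal x apical morphology grid
#'
#' Grafts every basal donor with every apical donor onto the standard soma,
#' runs the normalized current-step protocol on each combination and
#' records the firing category.  The control input resistance that anchors
#' the normalization is measured once, from `control` if given, otherwise
#' from the graft of the first basal with the first apical donor.
#' Simulation failures are recorded per cell (in the `error` column) and do
#' not abort the grid.
#'
#' @param basal_set,apical_set Named lists of morphologies (donor trees).
#'   Unnamed entries are named `b1, b2, ...` / `a1, a2, ...`.
#' @param soma Morphology donating the soma (default: single-point soma
#'   fixture).
#' @param basal_mode Basal channel distribution, `"uniform"` or
#'   `"nonuniform"` (see [build_cell_spec()]).
#' @param config Channel configuration for every cell.
#' @param passive Passive profile for every cell.
#' @param control Optional control cell morphology (a full cell, not a
#'   donor) whose input resistance anchors the step normalization.
#' @param factor Reference step amplitude in nA.
#' @param step_ms Depolarizing step duration, ms.
#' @param max_seg_length Spatial discretization limit, um.
#' @param dt Time step, ms.
#' @param isi_threshold_ms RS/IB boundary on the first interspike interval.
#' @param normalization Passed to [normalized_step()].
#' @return A `grid_result`: tibble with columns `basal_id`, `apical_id`,
#'   `category`, `first_isi_ms`, `rin_mohm`, `injected_na`, `error`, with
#'   the control input resistance in `attr(, "rin_control")`.
#' @export
run_grid <- function(basal_set, apical_set,
                     soma = fixture_suite()$soma_only,
                     basal_mode = c("uniform", "nonuniform"),
                     config = default_channel_config(),
                     passive = passive_profile(),
                     control = NULL, factor = 0.35, step_ms = 600,
                     max_seg_length = 20, dt = 0.025,
                     isi_threshold_ms = 20,
                     normalization = "equal-dv") {
  basal_mode <- match.arg(basal_mode)
  basal_set <- name_set(basal_set, "b")
  apical_set <- name_set(apical_set, "a")
  if (length(basal_set) == 0L || length(apical_set) == 0L) {
    abort("basal_set and apical_set must be non-empty",
          class = "dendrofire_argument_error")
  }
  for (m in c(basal_set, apical_set)) stopifnot(inherits(m, "morphology"))

  if (is.null(control)) {
    control <- graft(soma, basal_set[[1L]], apical_set[[1L]])
  }
  stopifnot(inherits(control, "morphology"))
  ctrl_spec <- build_cell_spec(control, basal_mode = basal_mode,
                               config = config, passive = passive)
  rin_control <- measure_input_resistance(
    discretize(ctrl_spec, max_seg_length = max_seg_length), dt = dt)

  combos <- tidyr::expand_grid(basal_id = names(basal_set),
                               apical_id = names(apical_set))
  rows <- purrr::pmap(combos, function(basal_id, apical_id) {
    out <- tryCatch({
      cell <- graft(soma, basal_set[[basal_id]], apical_set[[apical_id]])
      spec <- build_cell_spec(cell, basal_mode = basal_mode,
                              config = config, passive = passive)
      lab <- firing_response(spec, rin_control = rin_control,
                             factor = factor, step_ms = step_ms,
                             max_seg_length = max_seg_length, dt = dt,
                             isi_threshold_ms = isi_threshold_ms,
                             normalization = normalization)
      tibble(basal_id = basal_id, apical_id = apical_id,
             category = lab$category, first_isi_ms = lab$first_isi_ms,
             rin_mohm = lab$rin_mohm, injected_na = lab$injected_na,
             error = NA_character_)
    }, error = function(e) {
      tibble(basal_id = basal_id, apical_id = apical_id,
             category = NA_character_, first_isi_ms = NA_real_,
             rin_mohm = NA_real_, injected_na = NA_real_,
             error = conditionMessage(e))
    })
    out
  })
  res <- dplyr::bind_rows(rows)
  structure(res, rin_control = rin_control,
            class = c("grid_result", class(res)))
}

# assign default names b1.. / a1.. to unnamed set entries
name_set <- function(set, prefix) {
  if (inherits(set, "morphology")) set <- list(set)
  nm <- names(set)
  if (is.null(nm)) nm <- rep("", length(set))
  blank <- !nzchar(nm)
  nm[blank] <- paste0(prefix, seq_along(set))[blank]
  names(set) <- nm
  set
}

#' Broom-style summaries of a grid result
#'
#' `tidy()` returns the per-combination rows as a plain tibble; `glance()`
#' returns one row with category counts, proportions and the failure count.
#'
#' @param x A `grid_result`.
#' @param ... Unused.
#' @export
tidy.grid_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.grid_result
#' @export
glance.grid_result <- function(x, ...) {
  n <- nrow(x)
  ok <- is.na(x$error)
  tibble(
    n = n,
    n_rs = sum(x$category == "RS", na.rm = TRUE),
    n_ib = sum(x$category == "IB", na.rm = TRUE),
    n_q = sum(x$category == "Q", na.rm = TRUE),
    n_failed = sum(!ok),
    prop_rs = sum(x$category == "RS", na.rm = TRUE) / max(sum(ok), 1L),
    prop_ib = sum(x$category == "IB", na.rm = TRUE) / max(sum(ok), 1L),
    rin_control = attr(x, "rin_control")
  )
}

#' @export
print.grid_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<grid_result> %d combinations: %d RS, %d IB, %d Q, %d failed (control Rin %.1f MOhm)\n",
    g$n, g$n_rs, g$n_ib, g$n_q, g$n_failed, g$rin_control))
  NextMethod()
}

#' Majority-vote basal profiles
#'
#' Assigns each basal tree the profile `"RS"` if strictly more than half of
#' its grid row (its combinations across all apical donors) fired RS, and
#' `"IB"` otherwise.  Quiescent cells count in the denominator; failed
#' simulations are dropped from both numerator and denominator.
#'
#' @param grid A `grid_result` (or its tidy tibble).
#' @return A tibble with `basal_id`, `n_rs`, `n_total`, `profile`.
#' @export
basal_profile <- function(grid) {
  g <- tibble::as_tibble(grid)
  g <- dplyr::filter(g, is.na(.data$error))
  if (nrow(g) == 0L) {
    abort("no successful grid cells to profile",
          class = "dendrofire_value_error")
  }
  g |>
    dplyr::group_by(.data$basal_id) |>
    dplyr::summarise(
      n_rs = sum(.data$category == "RS"),
      n_total = dplyr::n(),
      profile = ifelse(.data$n_rs > .data$n_total / 2, "RS", "IB")
    ) |>
    dplyr::ungroup()
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparison of two samples:
#' exact null distribution when both samples are small (`min(n, m)` at most
#' 8) and tie-free, normal approximation with tie correction otherwise.
#' When the pooled sample is constant the test is degenerate; a warning is
#' raised and p = 1 reported.
#'
#' @param x,y Numeric samples (non-empty).
#' @return A one-row tibble: `u`, `p_value`, `n_x`, `n_y`, `method`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    abort("samples must be non-empty", class = "dendrofire_argument_error")
  }
  if (length(unique(c(x, y))) == 1L) {
    warn("degenerate samples: all pooled values identical; p = 1")
    return(tibble(u = length(x) * length(y) / 2, p_value = 1,
                  n_x = length(x), n_y = length(y),
                  method = "degenerate"))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && min(length(x), length(y)) <= 8L
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  tibble(u = unname(ht$statistic), p_value = ht$p.value,
         n_x = length(x), n_y = length(y),
         method = if (use_exact) "exact" else "normal approximation")
}

#' Train a one-dimensional Bayes classifier
#'
#' Fits class-conditional densities of a single scalar feature for the two
#' firing profiles, with equal priors.  `"gaussian"` fits a mean and
#' standard deviation per class; `"kde"` a Gaussian kernel density
#' estimate.
#'
#' @param x Numeric feature values.
#' @param labels Character vector in `{"RS", "IB"}`, same length as `x`.
#' @param method `"gaussian"` or `"kde"`.
#' @return A `bayes_model`.
#' @export
bayes_train <- function(x, labels, method = c("gaussian", "kde")) {
  method <- match.arg(method)
  if (length(x) != length(labels)) {
    abort("x and labels must have the same length",
          class = "dendrofire_argument_error")
  }
  bad <- setdiff(unique(labels), c("RS", "IB"))
  if (length(bad) > 0) {
    abort(paste0("unknown class label(s): ", paste(bad, collapse = ", ")),
          class = "dendrofire_argument_error")
  }
  if (!all(c("RS", "IB") %in% labels)) {
    abort("both classes RS and IB must be present in the training data",
          class = "dendrofire_value_error")
  }
  fit1 <- function(v) {
    if (method == "gaussian") {
      s <- stats::sd(v)
      # a constant training sample has zero spread; use a sliver of the
      # overall scale so the density stays proper
      if (!is.finite(s) || s == 0) s <- max(1e-8, 1e-8 * abs(mean(v)))
      list(mean = mean(v), sd = s)
    } else {
      stats::density(v, n = 512)
    }
  }
  structure(list(method = method,
                 classes = c("RS", "IB"),
                 fits = list(RS = fit1(x[labels == "RS"]),
                             IB = fit1(x[labels == "IB"]))),
            class = "bayes_model")
}

#' Predict firing profiles from a trained Bayes model
#'
#' Maximum-posterior prediction with equal priors; exact posterior ties go
#' to `"IB"` (documented constant).
#'
#' @param model A [bayes_train()] model.
#' @param x Numeric feature values.
#' @return Character vector of `"RS"` / `"IB"`.
#' @export
bayes_predict <- function(model, x) {
  stopifnot(inherits(model, "bayes_model"))
  lik <- function(fit, v) {
    if (model$method == "gaussian") {
      stats::dnorm(v, fit$mean, fit$sd)
    } else {
      stats::approx(fit$x, fit$y, xout = v, yleft = 0, yright = 0)$y
    }
  }
  l_rs <- lik(model$fits$RS, x)
  l_ib <- lik(model$fits$IB, x)
  ifelse(l_rs > l_ib, "RS", "IB")
}

#' Balanced, repeated train/test evaluation of the Bayes classifier
#'
#' Runs the study's evaluation loop: in each repeat, downsample the larger
#' class to the size of the smaller (without replacement), split each class
#' 80/20 into train and test, fit the class-conditional densities on the
#' training portion only, and score sensitivity, specificity and accuracy
#' on the held-out portion.  The positive class for sensitivity is `"IB"`.
#' Reported values are means over the repeats.
#'
#' @param x Numeric feature values.
#' @param labels Character vector in `{"RS", "IB"}`.
#' @param n_repeats Number of balanced resampling repeats.
#' @param train_frac Training fraction per class.
#' @param seed Master seed; per-repeat seeds are drawn from it and recorded.
#' @param method Density estimator, see [bayes_train()].
#' @return A `classifier_report`: list with `summary` (one-row tibble of
#'   means), `repeats` (per-repeat tibble) and the evaluation settings.
#' @export
bayes_evaluate <- function(x, labels, n_repeats = 10, train_frac = 0.8,
                           seed = 1L, method = "gaussian") {
  keep <- labels %in% c("RS", "IB")
  x <- x[keep]; labels <- labels[keep]
  n_rs <- sum(labels == "RS"); n_ib <- sum(labels == "IB")
  if (n_rs < 2L || n_ib < 2L) {
    abort("need at least 2 cells per class to balance, split and test",
          class = "dendrofire_value_error")
  }
  n_bal <- min(n_rs, n_ib)
  n_train <- floor(train_frac * n_bal)
  if (n_train < 1L || n_train >= n_bal) {
    abort("train_frac leaves an empty training or test set",
          class = "dendrofire_value_error")
  }
  repeat_seeds <- local_seed(as.integer(seed),
                             sample.int(.Machine$integer.max - 1L, n_repeats))
  idx_rs <- which(labels == "RS"); idx_ib <- which(labels == "IB")
  reps <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    local_seed(repeat_seeds[r], {
      bal_rs <- sample(idx_rs, n_bal)
      bal_ib <- sample(idx_ib, n_bal)
      tr_rs <- sample(bal_rs, n_train)
      tr_ib <- sample(bal_ib, n_train)
      te_rs <- setdiff(bal_rs, tr_rs)
      te_ib <- setdiff(bal_ib, tr_ib)
      model <- bayes_train(x[c(tr_rs, tr_ib)],
                           labels[c(tr_rs, tr_ib)], method = method)
      pred <- bayes_predict(model, x[c(te_rs, te_ib)])
      truth <- labels[c(te_rs, te_ib)]
      tp <- sum(pred == "IB" & truth == "IB")
      tn <- sum(pred == "RS" & truth == "RS")
      fp <- sum(pred == "IB" & truth == "RS")
      fn <- sum(pred == "RS" & truth == "IB")
      tibble(repeat_id = r, seed = repeat_seeds[r],
             sensitivity = tp / (tp + fn),
             specificity = tn / (tn + fp),
             accuracy = (tp + tn) / (tp + tn + fp + fn))
    })
  })
  structure(list(
    summary = tibble(
      sensitivity = mean(reps$sensitivity),
      specificity = mean(reps$specificity),
      accuracy = mean(reps$accuracy),
      n_repeats = n_repeats, n_per_class = n_bal,
      train_frac = train_frac, method = method, seed = as.integer(seed)
    ),
    repeats = reps,
    positive_class = "IB"
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<classifier_report> %s, %d repeats, %d per class: accuracy %.3f (sens %.3f, spec %.3f)\n",
    s$method, s$n_repeats, s$n_per_class, s$accuracy, s$sensitivity,
    s$specificity))
  invisible(x)
}

#' Broom-style summaries of a classifier report
#'
#' `tidy()` returns the per-repeat metrics; `glance()` the one-row means.
#'
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @export
tidy.classifier_report <- function(x, ...) x$repeats

#' @rdname tidy.classifier_report
#' @export
glance.classifier_report <- function(x, ...) x$summary

#' Pairwise correlation of morphometric features
#'
#' Product-moment correlation between each pair of the requested feature
#' columns.  Zero-variance features give an undefined correlation; these
#' pairs are flagged and reported as `NA` with a warning.
#'
#' @param features A tibble of per-cell features ([morpho_features()]).
#' @param columns Feature columns to correlate.
#' @return A tibble with `feature_a`, `feature_b`, `r`, `n`, `defined`.
#' @export
feature_correlation <- function(features,
                                columns = c("total_length_um", "volume_um3",
                                            "branch_number")) {
  missing_cols <- setdiff(columns, names(features))
  if (length(missing_cols) > 0) {
    abort(paste0("missing feature column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "dendrofire_argument_error")
  }
  if (nrow(features) < 3L) {
    abort("need at least 3 cells to correlate features",
          class = "dendrofire_value_error")
  }
  pairs <- utils::combn(columns, 2L, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(p) {
    a <- features[[p[1L]]]; b <- features[[p[2L]]]
    ok <- stats::sd(a) > 0 && stats::sd(b) > 0
    tibble(feature_a = p[1L], feature_b = p[2L],
           r = if (ok) stats::cor(a, b) else NA_real_,
           n = length(a), defined = ok)
  })
  if (any(!out$defined)) {
    warn("zero-variance feature: correlation undefined for flagged pairs")
  }
  out
}
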