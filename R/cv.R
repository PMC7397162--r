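#' Generate cross-validation partitions over lines
#'
#' The default `"random"` method draws each partition's test set
#' independently (test sets may overlap across partitions), matching the
#' random cross-validation design in which individuals can appear in both
#' training and testing populations across repetitions. The `"kfold"`
#' method instead splits the lines into `n_partitions` disjoint folds (one
#' partition per fold), as used for the GBLUP comparison.
#'
#' @param line_ids Character vector of unique line ids.
#' @param n_partitions Number of partitions (or folds).
#' @param test_fraction Fraction of lines in each test set; the test size
#'   is `round(test_fraction * n)`. Ignored for `"kfold"`.
#' @param seed Optional integer seed; the plan is deterministic given the
#'   seed.
#' @param method `"random"` (default) or `"kfold"`.
#' @return A `cv_plan`: tibble with columns `partition`, `line`, `role`
#'   (`"train"`/`"test"`), carrying the settings as attributes.
#' @export
#' @examples
#' plan <- make_partitions(sprintf("L%03d", 1:100), 10, 0.25, seed = 1)
#' dplyr::count(plan, partition, role)
make_partitions <- function(line_ids, n_partitions = 10, test_fraction = 0.25,
                            seed = NULL, method = c("random", "kfold")) {
  method <- match.arg(method)
  line_ids <- as.character(line_ids)
  if (anyDuplicated(line_ids)) abort("line_ids must be unique")
  n <- length(line_ids)
  if (method == "random") {
    if (test_fraction <= 0 || test_fraction >= 1) {
      abort("test_fraction must be strictly between 0 and 1")
    }
    n_test <- round(test_fraction * n)
    if (n_test == 0L || n_test == n) {
      abort("test set would be empty or contain every line")
    }
  }
  parts <- with_seed(seed, {
    if (method == "random") {
      lapply(seq_len(n_partitions), function(k) sample(line_ids, n_test))
    } else {
      fold <- sample(rep_len(seq_len(n_partitions), n))
      lapply(seq_len(n_partitions), function(k) line_ids[fold == k])
    }
  })
  plan <- dplyr::bind_rows(lapply(seq_len(n_partitions), function(k) {
    tibble::tibble(
      partition = k, line = line_ids,
      role = ifelse(line_ids %in% parts[[k]], "test", "train")
    )
  }))
  structure(plan,
    class = c("cv_plan", class(plan)),
    n_partitions = as.integer(n_partitions),
    test_fraction = if (method == "random") test_fraction else NA_real_,
    seed = seed, method = method
  )
}

# Run `code` under a temporary RNG state seeded with `seed` (NULL = use the
# current stream).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

test_lines <- function(plan, k) {
  plan$line[plan$partition == k & plan$role == "test"]
}

new_scenario <- function(scenario, predictions, metrics, settings) {
  structure(
    list(scenario = scenario, predictions = predictions, metrics = metrics,
         settings = settings),
    class = "gs_scenario"
  )
}

# Per-partition, per-item metric table from a predictions tibble.
scenario_metrics <- function(predictions) {
  dplyr::summarise(
    dplyr::group_by(predictions, .data$partition, .data$item),
    predictive_ability = suppressWarnings(
      predictive_ability(.data$predicted, .data$observed)
    ),
    maape = maape(.data$predicted, .data$observed),
    rmse = rmse(.data$predicted, .data$observed),
    n = dplyr::n(),
    .groups = "drop"
  )
}

#' Multi-environment cross-validation scenario
#'
#' For each partition of the plan, the target items' cells of the test
#' lines are masked (test lines keep their other trait-environment cells,
#' so the recommender has neighbors), the IBCF predictor imputes the masked
#' cells from the remaining observed data, and per-item metrics are
#' computed against the held-out truth.
#'
#' @param pheno Wide phenotype tibble.
#' @param plan A `cv_plan` over the table's lines.
#' @param target_items Character vector of item keys to predict.
#' @param top_k,min_abs_weight Neighbor policy passed to [ibcf_impute()].
#' @return A `gs_scenario` object with per-partition `predictions` and
#'   `metrics` tibbles; see [summarize_scenario()].
#' @export
scenario_multi_env <- function(pheno, plan, target_items,
                               top_k = NULL, min_abs_weight = 0) {
  m <- pheno_matrix(validate_phenotypes(pheno))
  items <- colnames(m)
  if (length(items) < 2L) abort("IBCF needs at least two items (no neighbors otherwise)")
  if (!all(target_items %in% items)) {
    abort(sprintf(
      "target item(s) not in table: %s",
      paste(setdiff(target_items, items), collapse = ", ")
    ))
  }
  n_parts <- attr(plan, "n_partitions") %||% max(plan$partition)
  out <- lapply(seq_len(n_parts), function(k) {
    test <- intersect(test_lines(plan, k), rownames(m))
    masked <- m
    masked[test, target_items] <- NA
    for (j in target_items) {
      if (all(is.na(masked[, j]))) {
        abort(sprintf("target item '%s' fully masked in training (partition %d)", j, k))
      }
    }
    fit <- ibcf_impute(matrix_to_pheno(masked), top_k = top_k,
                       min_abs_weight = min_abs_weight)
    truth <- tidyr::pivot_longer(
      matrix_to_pheno(m[test, target_items, drop = FALSE]),
      -"line", names_to = "item", values_to = "observed"
    )
    pred <- dplyr::inner_join(fit$cells, truth, by = c("line", "item"))
    pred <- dplyr::filter(pred, !is.na(.data$observed))
    tibble::tibble(
      partition = k, line = pred$line, item = pred$item,
      observed = pred$observed, predicted = pred$y_hat,
      flagged = pred$flagged
    )
  })
  predictions <- dplyr::bind_rows(out)
  new_scenario(
    "multi_env", predictions, scenario_metrics(predictions),
    list(target_items = target_items, n_partitions = n_parts,
         test_fraction = attr(plan, "test_fraction"),
         seed = attr(plan, "seed"), top_k = top_k,
         min_abs_weight = min_abs_weight)
  )
}

#' Next-season prediction scenario
#'
#' Emulates predicting a trait for an upcoming season: the target trait's
#' test-year columns are masked for every line and imputed from the
#' remaining items (the same trait in previous years and the other traits).
#' Because the masked columns have no observed cells, their standardization
#' parameters and their similarities to the other items are computed from
#' the full table before masking; this is an evaluation design (the
#' reference workflow's year-wise cross-validation behaves the same way),
#' not a deployable forecast of an unmeasured season.
#'
#' @param pheno Wide phenotype tibble with `trait_location_year` item keys.
#' @param target_trait Trait label to predict (e.g. `"GY"`).
#' @param train_years Integer vector of training seasons; must strictly
#'   precede `test_year`.
#' @param test_year Integer season to predict.
#' @param location Optional location label(s) to restrict the table to.
#' @param top_k,min_abs_weight Neighbor policy passed to [ibcf_impute()].
#' @return A `gs_scenario` with a single partition.
#' @export
scenario_next_season <- function(pheno, target_trait, train_years, test_year,
                                 location = NULL, top_k = NULL,
                                 min_abs_weight = 0) {
  if (any(train_years >= test_year)) {
    abort("train_years must strictly precede test_year")
  }
  m <- pheno_matrix(validate_phenotypes(pheno))
  info <- parse_item_key(colnames(m))
  keep <- !is.na(info$year) & info$year %in% c(train_years, test_year)
  if (!is.null(location)) keep <- keep & info$location %in% location
  info <- info[keep, , drop = FALSE]
  m <- m[, info$item, drop = FALSE]
  targets <- info$item[info$trait == target_trait & info$year == test_year]
  if (length(targets) == 0L) {
    abort(sprintf("no '%s' items for test year %d", target_trait, test_year))
  }
  train_items <- setdiff(info$item, targets)
  if (length(train_items) == 0L) abort("no training items left after masking")
  has_truth <- rowSums(!is.na(m[, targets, drop = FALSE])) > 0
  has_train <- rowSums(!is.na(m[, train_items, drop = FALSE])) > 0
  if (!any(has_truth & has_train)) {
    abort("no lines shared between training items and test-year target items")
  }
  std <- standardize_phenotypes(matrix_to_pheno(m))
  sim <- similarity_matrix(std$z)
  masked <- m
  masked[, targets] <- NA
  fit <- ibcf_impute(matrix_to_pheno(masked), similarity = sim,
                     params = std$params, top_k = top_k,
                     min_abs_weight = min_abs_weight)
  truth <- tidyr::pivot_longer(
    matrix_to_pheno(m[, targets, drop = FALSE]),
    -"line", names_to = "item", values_to = "observed"
  )
  pred <- dplyr::inner_join(fit$cells, truth, by = c("line", "item"))
  pred <- dplyr::filter(pred, !is.na(.data$observed))
  predictions <- tibble::tibble(
    partition = 1L, line = pred$line, item = pred$item,
    observed = pred$observed, predicted = pred$y_hat, flagged = pred$flagged
  )
  new_scenario(
    "next_season", predictions, scenario_metrics(predictions),
    list(target_trait = target_trait, train_years = train_years,
         test_year = test_year, location = location, top_k = top_k,
         min_abs_weight = min_abs_weight)
  )
}

#' Secondary-trait prediction scenario
#'
#' Predicts a target trait (typically grain yield) from sets of secondary
#' spectral items: for each predictor set, only the target items and that
#' set's items enter the IBCF table, the target cells of each partition's
#' test lines are masked, and metrics are computed per set.
#'
#' @param pheno Wide phenotype tibble holding the target and spectral items.
#' @param plan A `cv_plan`.
#' @param target_items Item keys of the target trait.
#' @param predictor_sets Named list of character vectors of predictor item
#'   keys, one entry per set (e.g. NDVI alone, NDVI plus SR, all three).
#' @param top_k,min_abs_weight Neighbor policy passed to [ibcf_impute()].
#' @return A named list of `gs_scenario` objects (class
#'   `gs_scenario_set`), one per predictor set.
#' @export
scenario_secondary <- function(pheno, plan, target_items, predictor_sets,
                               top_k = NULL, min_abs_weight = 0) {
  if (is.null(names(predictor_sets)) || any(names(predictor_sets) == "")) {
    names(predictor_sets) <- vapply(
      predictor_sets, function(s) paste(s, collapse = "+"), character(1)
    )
  }
  items <- setdiff(names(pheno), "line")
  for (nm in names(predictor_sets)) {
    set <- predictor_sets[[nm]]
    if (length(set) == 0L) abort(sprintf("predictor set '%s' is empty", nm))
    missing_items <- setdiff(set, items)
    if (length(missing_items) > 0L) {
      abort(sprintf("predictor set '%s' names absent item(s): %s",
                    nm, paste(missing_items, collapse = ", ")))
    }
  }
  out <- lapply(names(predictor_sets), function(nm) {
    sub <- pheno[, c("line", union(target_items, predictor_sets[[nm]])),
                 drop = FALSE]
    res <- scenario_multi_env(sub, plan, target_items, top_k = top_k,
                              min_abs_weight = min_abs_weight)
    res$scenario <- "secondary"
    res$settings$predictor_set <- nm
    res
  })
  names(out) <- names(predictor_sets)
  structure(out, class = "gs_scenario_set")
}

#' Summarize a scenario over partitions
#'
#' Metrics are computed per partition and then averaged (never pooled); the
#' standard error is `sd / sqrt(n_partitions)` and is `NA` for a single
#' partition.
#'
#' @param result A `gs_scenario`.
#' @return A tibble with columns `item`, `metric`, `mean`, `se`, `min`,
#'   `max`, `n_partitions`, ordered by item then metric.
#' @export
summarize_scenario <- function(result) {
  stopifnot(inherits(result, "gs_scenario"))
  long <- tidyr::pivot_longer(
    result$metrics, c("predictive_ability", "maape", "rmse"),
    names_to = "metric", values_to = "value"
  )
  long$metric <- factor(long$metric,
                        levels = c("predictive_ability", "maape", "rmse"))
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$item, .data$metric),
    mean = mean(.data$value, na.rm = TRUE),
    se = if (dplyr::n() > 1L) sd(.data$value, na.rm = TRUE) / sqrt(dplyr::n()) else NA_real_,
    min = min(.data$value, na.rm = TRUE),
    max = max(.data$value, na.rm = TRUE),
    n_partitions = dplyr::n(),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$item, .data$metric)
}

#' @export
print.gs_scenario <- function(x, ...) {
  cat(sprintf("<gs_scenario: %s>\n", x$scenario))
  print(summarize_scenario(x), n = 20)
  invisible(x)
}

#' @rdname summarize_scenario
#' @param x,object A `gs_scenario`.
#' @param ... Unused.
#' @return `tidy()` returns the per-partition metric tibble; `glance()` one
#'   row per target item with mean and SE of each metric.
#' @method tidy gs_scenario
#' @export
tidy.gs_scenario <- function(x, ...) x$metrics

#' @rdname summarize_scenario
#' @method glance gs_scenario
#' @export
glance.gs_scenario <- function(x, ...) {
  s <- summarize_scenario(x)
  wide <- tidyr::pivot_wider(
    s[, c("item", "metric", "mean", "se")],
    names_from = "metric", values_from = c("mean", "se"),
    names_glue = "{metric}_{.value}"
  )
  wide$n_partitions <- s$n_partitions[match(wide$item, s$item)]
  wide
}

#' @method tidy gs_scenario_set
#' @export
tidy.gs_scenario_set <- function(x, ...) {
  dplyr::bind_rows(lapply(x, tidy), .id = "predictor_set")
}

#' @export
print.gs_scenario_set <- function(x, ...) {
  for (nm in names(x)) {
    cat(sprintf("== predictor set: %s ==\n", nm))
    print(x[[nm]])
  }
  invisible(x)
}

#' Mean predictive ability per item with standard-error bars
#'
#' @param object A `gs_scenario`.
#' @param metric Metric to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gs_scenario
#' @export
autoplot.gs_scenario <- function(object, metric = "predictive_ability", ...) {
  s <- summarize_scenario(object)
  s <- dplyr::filter(s, .data$metric == !!metric)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$item, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
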