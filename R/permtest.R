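#' Permute a response column within studies
#'
#' Shuffles the response values among rows within each study while leaving
#' every explanatory column (including weights) untouched; the within-study
#' multiset of response values is preserved. Deterministic given `seed`.
#'
#' @param data A data frame with a `study_id` column.
#' @param response Name of the response column to shuffle.
#' @param seed Integer seed.
#' @return `data` with the response permuted within studies.
#' @export
permute_within_study <- function(data, response, seed) {
  check_columns(data, c("study_id", response), "data")
  out <- tibble::as_tibble(data)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  for (sid in unique(out$study_id)) {
    rows <- which(out$study_id == sid)
    if (length(rows) > 1) {
      out[[response]][rows] <- out[[response]][rows[sample.int(length(rows))]]
    }
  }
  out
}

new_permutation_result <- function(observed, null_values, tails, seed) {
  n_perm <- length(null_values)
  extreme <- if (tails == "two") {
    sum(abs(null_values) >= abs(observed))
  } else {
    sum(null_values >= observed)
  }
  structure(list(observed = observed,
                 null_values = null_values,
                 p_value = (1 + extreme) / (1 + n_perm),
                 tails = tails,
                 n_perm = n_perm,
                 seed = seed),
            class = "islandiv_perm")
}

#' @export
print.islandiv_perm <- function(x, ...) {
  cat(sprintf(
    "<permutation test> observed = %.4f, n_perm = %d, %s-tailed, p = %.4g\n",
    x$observed, x$n_perm, x$tails, x$p_value))
  invisible(x)
}

fit_lr_pair <- function(data, full, reduced) {
  ff <- fit_mixed(data, full, estimation = "ML")
  rf <- fit_mixed(data, reduced, estimation = "ML")
  list(lr = lr_statistic(ff, rf), full = ff, reduced = rf,
       ok = ff$converged && rf$converged)
}

#' Permutation likelihood-ratio test for nested mixed models
#'
#' The observed ML likelihood ratio between a full and a nested reduced model
#' is compared against the ratios obtained after permuting the response
#' within studies `n_perm` times (explanatory data held constant). The
#' p-value is the inclusive Monte-Carlo form
#' `(1 + #(null >= observed)) / (1 + n_perm)`, upper-tailed, with attainable
#' floor `1 / (1 + n_perm)` (0.005 at 199 permutations).
#'
#' @param data Model data (one row per pairwise comparison or site).
#' @param full,reduced Nested [model_spec()]s sharing the response.
#' @param n_perm Number of permutations (default 199).
#' @param seed Master seed; per-permutation streams are spawned from it, so
#'   results are independent of execution order.
#' @return An `islandiv_perm` object.
#' @export
permutation_lr_test <- function(data, full, reduced, n_perm = 199, seed = 1) {
  stopifnot(full$response == reduced$response)
  obs <- fit_lr_pair(data, full, reduced)
  if (!obs$ok) {
    stop_islandiv("full or reduced model failed to converge on observed data",
                  class = "islandiv_convergence_error")
  }
  seeds <- spawn_seeds(seed, n_perm)
  failures <- 0L
  null_lr <- vapply(seq_len(n_perm), function(b) {
    perm <- permute_within_study(data, full$response, seeds[b])
    res <- tryCatch(fit_lr_pair(perm, full, reduced),
                    error = function(e) NULL)
    if (is.null(res) || !res$ok) {
      failures <<- failures + 1L
      return(NA_real_)
    }
    res$lr$lr
  }, numeric(1))
  if (failures > 0.05 * n_perm) {
    stop_islandiv(sprintf(
      "%d of %d permutation fits failed to converge", failures, n_perm),
      class = "islandiv_convergence_error")
  }
  null_lr[is.na(null_lr)] <- -Inf   # conservative for the upper tail
  new_permutation_result(obs$lr$lr, null_lr, tails = "upper", seed = seed)
}

#' Two-tailed permutation test of a model coefficient
#'
#' Compares the absolute value of a fitted coefficient against coefficients
#' from within-study response permutations:
#' `p = (1 + #(|null| >= |observed|)) / (1 + n_perm)`.
#'
#' @param data Model data.
#' @param spec The [model_spec()] containing the term.
#' @param coef_name Name of the coefficient (as in the fitted fixed effects).
#' @param n_perm,seed As in [permutation_lr_test()].
#' @return An `islandiv_perm` object.
#' @export
permutation_coef_test <- function(data, spec, coef_name, n_perm = 199,
                                  seed = 1) {
  fit <- fit_mixed(data, spec, estimation = "ML")
  if (!coef_name %in% names(fit$coefficients)) {
    stop_islandiv(sprintf("coefficient '%s' not present in the model; available: %s",
                          coef_name,
                          paste(names(fit$coefficients), collapse = ", ")))
  }
  obs <- unname(fit$coefficients[coef_name])
  seeds <- spawn_seeds(seed, n_perm)
  failures <- 0L
  null_coef <- vapply(seq_len(n_perm), function(b) {
    perm <- permute_within_study(data, spec$response, seeds[b])
    pf <- tryCatch(fit_mixed(perm, spec, estimation = "ML"),
                   error = function(e) NULL)
    if (is.null(pf) || !pf$converged ||
        !coef_name %in% names(pf$coefficients)) {
      failures <<- failures + 1L
      return(NA_real_)
    }
    unname(pf$coefficients[coef_name])
  }, numeric(1))
  if (failures > 0.05 * n_perm) {
    stop_islandiv(sprintf(
      "%d of %d permutation fits failed to converge", failures, n_perm),
      class = "islandiv_convergence_error")
  }
  null_coef[is.na(null_coef)] <- 0   # conservative for the two-tailed test
  new_permutation_result(obs, null_coef, tails = "two", seed = seed)
}

#' Backward simplification with permutation likelihood-ratio tests
#'
#' Identical control flow to [backward_simplify()], but every
#' likelihood-ratio p-value comes from [permutation_lr_test()] — the
#' appropriate inference when observations are non-independent pairwise
#' comparisons. Each term test regenerates its permutations from a seed tree
#' (master seed, term-test index, permutation index).
#'
#' @param data Model data.
#' @param spec The full [model_spec()].
#' @param alpha Retention threshold.
#' @param n_perm Permutations per term test.
#' @param seed Master seed.
#' @return A list with `fit`, `spec`, `trail` (as [backward_simplify()], with
#'   permutation p-values).
#' @export
stepwise_with_permutation <- function(data, spec, alpha = 0.05,
                                      n_perm = 199, seed = 1) {
  test_idx <- 0L
  test_seeds <- spawn_seeds(seed, 10000L)
  simplify_engine(data, spec, alpha, function(full, red, term, st) {
    test_idx <<- test_idx + 1L
    res <- permutation_lr_test(data, full, red, n_perm = n_perm,
                               seed = test_seeds[test_idx])
    res$p_value
  })
}
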