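RANDOM_STRUCTURES <- c("slopes_study_block_island", "slopes_study_block",
                       "study_block_island", "study_block",
                       "study_island", "study")

#' Describe a mixed-effects model
#'
#' A declarative model specification: response, fixed-effect terms, one of
#' six candidate random-effect structures, error family, whether an
#' observation-level random effect (OLRE) is added to absorb extra-Poisson
#' variance, and an optional weights column.
#'
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect term labels (main effects
#'   and `:` interactions; `poly(x, 2)` terms allowed).
#' @param random One of `"slopes_study_block_island"` (random land-use slopes
#'   within study plus random intercepts of study, block nested in study and
#'   island), `"slopes_study_block"`, `"study_block_island"`, `"study_block"`,
#'   `"study_island"`, `"study"`.
#' @param family `"gaussian"` (identity link) or `"poisson"` (log link).
#' @param olre Add an observation-level random intercept (Poisson only).
#' @param weights Optional name of a weights column in `[0, 1]`; weights act
#'   as per-observation precision multipliers (gaussian) or log-likelihood
#'   contribution multipliers (Poisson).
#' @return A `model_spec` object.
#' @export
model_spec <- function(response, fixed, random = "study",
                       family = c("gaussian", "poisson"),
                       olre = FALSE, weights = NULL) {
  family <- match.arg(family)
  random <- match.arg(random, RANDOM_STRUCTURES)
  if (olre && family != "poisson") {
    stop_islandiv("an observation-level random effect is only supported with the poisson family")
  }
  structure(list(response = response, fixed = fixed, random = random,
                 family = family, olre = olre, weights = weights),
            class = "model_spec")
}

re_terms_for <- function(random, olre = FALSE) {
  base <- switch(
    random,
    slopes_study_block_island = c("(land_use | study_id)", "(1 | block_id)",
                                  "(1 | island_id)"),
    slopes_study_block = c("(land_use | study_id)", "(1 | block_id)"),
    study_block_island = c("(1 | study_id)", "(1 | block_id)",
                           "(1 | island_id)"),
    study_block = c("(1 | study_id)", "(1 | block_id)"),
    study_island = c("(1 | study_id)", "(1 | island_id)"),
    study = "(1 | study_id)")
  if (olre) base <- c(base, "(1 | .obs)")
  base
}

spec_formula <- function(spec) {
  rhs <- c(if (length(spec$fixed) > 0) spec$fixed else "1",
           re_terms_for(spec$random, spec$olre))
  as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")))
}

fixed_formula <- function(spec) {
  reformulate(if (length(spec$fixed) > 0) spec$fixed else "1",
              response = spec$response)
}

spec_vars <- function(spec) {
  v <- all.vars(spec_formula(spec))
  v <- setdiff(v, ".obs")
  if (!is.null(spec$weights)) v <- c(v, spec$weights)
  unique(v)
}

#' Fit a mixed-effects model from a specification
#'
#' Gaussian specs are fitted as (weighted) linear mixed models by REML or ML;
#' Poisson specs as log-link generalized linear mixed models by the Laplace
#' approximation, with an observation-level random intercept when
#' `spec$olre`. Convergence and singularity flags are always recorded;
#' rank-deficient fixed effects raise an error naming the aliased columns.
#' Rows with missing model variables or zero weight are dropped.
#'
#' @param data A data frame with all referenced columns.
#' @param spec A [model_spec()].
#' @param estimation `"REML"` or `"ML"` for gaussian fits (Poisson fits
#'   always use Laplace ML).
#' @return An object of class `ln_fit`: the underlying `merMod` plus
#'   coefficients, covariance of the fixed effects, log-likelihood,
#'   convergence/singularity flags and prediction metadata.
#' @export
fit_mixed <- function(data, spec, estimation = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(estimation)) {
    estimation <- if (spec$family == "gaussian") "REML" else "Laplace"
  }
  if (spec$family == "poisson") estimation <- "Laplace"

  dd <- tibble::as_tibble(data)
  vars <- spec_vars(spec)
  check_columns(dd, vars, "model data")
  dd <- dd[complete.cases(dd[, vars, drop = FALSE]), , drop = FALSE]
  if (!is.null(spec$weights)) {
    w <- dd[[spec$weights]]
    if (any(w < 0)) stop_islandiv("weights must be >= 0")
    n_zero <- sum(w == 0)
    if (n_zero > 0) {
      rlang::inform(sprintf(
        "dropping %d observation(s) with zero weight", n_zero))
      dd <- dd[w > 0, , drop = FALSE]
    }
    dd$.w <- dd[[spec$weights]]
  } else {
    dd$.w <- 1
  }
  for (v in vars) if (is.factor(dd[[v]])) dd[[v]] <- droplevels(dd[[v]])
  if (spec$olre) dd$.obs <- factor(seq_len(nrow(dd)))

  # fixed-effects design; rank check before handing to the optimizer
  ff <- fixed_formula(spec)
  mf <- model.frame(ff, dd)
  tt <- terms(mf)
  X <- model.matrix(tt, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_islandiv(sprintf("rank-deficient fixed effects; aliased: %s",
                          paste(aliased, collapse = ", ")),
                  class = "islandiv_rank_error")
  }

  f <- spec_formula(spec)
  converged <- TRUE
  capture_conv <- function(expr) {
    withCallingHandlers(
      expr,
      warning = function(w) {
        if (grepl("converge|Hessian|pwrssUpdate", conditionMessage(w),
                  ignore.case = TRUE)) {
          converged <<- FALSE
        }
        invokeRestart("muffleWarning")
      },
      message = function(m) invokeRestart("muffleMessage")
    )
  }
  if (spec$family == "gaussian") {
    model <- capture_conv(lme4::lmer(
      f, data = dd, weights = .w, REML = (estimation == "REML"),
      control = lme4::lmerControl(calc.derivs = FALSE)))
  } else {
    model <- capture_conv(lme4::glmer(
      f, data = dd, weights = .w, family = stats::poisson(link = "log"),
      control = lme4::glmerControl(calc.derivs = FALSE,
                                   optimizer = "bobyqa")))
  }
  if (!is.null(model@optinfo$conv$opt) && model@optinfo$conv$opt != 0) {
    converged <- FALSE
  }
  msgs <- unlist(model@optinfo$conv$lme4$messages)
  if (length(msgs) > 0 &&
      any(grepl("converge", msgs, ignore.case = TRUE))) {
    converged <- FALSE
  }

  beta <- lme4::fixef(model)
  structure(list(
    model = model,
    spec = spec,
    estimation = estimation,
    coefficients = beta,
    vcov = as.matrix(vcov(model)),
    loglik = as.numeric(logLik(model)),
    n_obs = nrow(dd),
    converged = converged,
    singular = lme4::isSingular(model),
    terms_fixed = delete.response(tt),
    xlev = stats::.getXlevels(tt, mf),
    assign = attr(X, "assign"),
    term_labels = attr(tt, "term.labels"),
    data = dd
  ), class = "ln_fit")
}

#' @export
print.ln_fit <- function(x, ...) {
  cat(sprintf("<ln_fit> %s model: %s\n", x$spec$family,
              deparse(fixed_formula(x$spec))))
  cat(sprintf("  random: %s%s | estimation: %s | n = %d\n",
              x$spec$random, if (x$spec$olre) " + OLRE" else "",
              x$estimation, x$n_obs))
  cat(sprintf("  logLik = %.3f | converged: %s | singular fit: %s\n",
              x$loglik, x$converged, x$singular))
  invisible(x)
}

#' @export
logLik.ln_fit <- function(object, ...) logLik(object$model)

#' Select the best-supported random-effects structure
#'
#' Fits the spec under each candidate random structure (REML for gaussian,
#' Laplace ML for Poisson), drops candidates that fail to converge, and
#' returns the spec with the lowest-AIC convergent structure. The full
#' comparison (including the fallback path when richer structures fail) is
#' attached as attribute `selection`.
#'
#' @param data Model data.
#' @param spec A [model_spec()]; its `random` entry is ignored.
#' @param candidates Ordered character vector of candidate structures
#'   (richest first).
#' @return The winning `model_spec`, with attributes `selection` (tibble) and
#'   `fit` (the winning `ln_fit`).
#' @export
select_random_structure <- function(data, spec,
                                    candidates = RANDOM_STRUCTURES[1:4]) {
  stopifnot(length(candidates) >= 1)
  fits <- vector("list", length(candidates))
  rows <- purrr::map_dfr(seq_along(candidates), function(i) {
    cand_spec <- spec
    cand_spec$random <- match.arg(candidates[i], RANDOM_STRUCTURES)
    res <- tryCatch({
      ft <- fit_mixed(data, cand_spec)
      fits[[i]] <<- ft
      tibble::tibble(random = candidates[i], fitted = TRUE,
                     converged = ft$converged, singular = ft$singular,
                     aic = AIC(ft$model))
    }, error = function(e) {
      tibble::tibble(random = candidates[i], fitted = FALSE,
                     converged = FALSE, singular = NA, aic = NA_real_)
    })
    res
  })
  ok <- which(rows$fitted & rows$converged)
  if (length(ok) == 0) {
    stop_islandiv("no candidate random structure converged",
                  class = "islandiv_convergence_error")
  }
  best <- ok[which.min(rows$aic[ok])]
  rows$selected <- seq_len(nrow(rows)) == best
  out <- spec
  out$random <- candidates[best]
  attr(out, "selection") <- rows
  attr(out, "fit") <- fits[[best]]
  out
}

# terms whose variable set is not a strict subset of any other retained term
droppable_terms <- function(term_labels) {
  vars <- lapply(strsplit(term_labels, ":", fixed = TRUE), unique)
  keep <- vapply(seq_along(term_labels), function(i) {
    !any(vapply(seq_along(term_labels), function(j) {
      i != j && all(vars[[i]] %in% vars[[j]]) &&
        length(vars[[j]]) > length(vars[[i]])
    }, logical(1)))
  }, logical(1))
  term_labels[keep]
}

lr_statistic <- function(full_fit, reduced_fit) {
  lr <- 2 * (full_fit$loglik - reduced_fit$loglik)
  # nested ML fits: tiny negative values are optimizer noise, clamp to 0
  if (lr < 0 && lr > -0.02) lr <- 0
  df <- length(full_fit$coefficients) - length(reduced_fit$coefficients)
  list(lr = lr, df = df)
}

# shared engine for chi-square and permutation-based backward simplification
simplify_engine <- function(data, spec, alpha, p_fun) {
  empty_trail <- tibble::tibble(step = integer(), term = character(),
                                df = integer(), lr = numeric(),
                                p_value = numeric(), dropped = logical())
  if (alpha <= 0) {
    # a retention threshold of zero disables dropping entirely
    return(list(fit = fit_mixed(data, spec, estimation = "ML"),
                spec = spec, trail = empty_trail))
  }
  current <- spec
  trail <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    cand <- droppable_terms(current$fixed)
    if (length(cand) == 0) break
    full_fit <- fit_mixed(data, current, estimation = "ML")
    tests <- purrr::map_dfr(cand, function(tm) {
      red <- current
      red$fixed <- setdiff(current$fixed, tm)
      red_fit <- fit_mixed(data, red, estimation = "ML")
      st <- lr_statistic(full_fit, red_fit)
      if (st$lr < 0) {
        stop_islandiv(sprintf(
          "log-likelihood increased when dropping '%s' (nesting violated)",
          tm))
      }
      p <- p_fun(current, red, tm, st)
      tibble::tibble(step = step, term = tm, df = st$df,
                     lr = st$lr, p_value = p)
    })
    worst <- which.max(tests$p_value)
    tests$dropped <- seq_len(nrow(tests)) == worst &
      tests$p_value[worst] >= alpha
    trail[[step]] <- tests
    if (tests$p_value[worst] >= alpha) {
      current$fixed <- setdiff(current$fixed, tests$term[worst])
      if (length(current$fixed) == 0) break
    } else break
  }
  final_fit <- fit_mixed(data, current, estimation = "ML")
  list(fit = final_fit, spec = current,
       trail = if (length(trail) > 0) dplyr::bind_rows(trail) else
         empty_trail)
}

#' Backward stepwise simplification by likelihood-ratio tests
#'
#' Repeatedly drops the least significant droppable fixed-effect term
#' (respecting marginality: a main effect is only droppable once absent from
#' all retained interactions) whose likelihood-ratio p-value is at or above
#' `alpha`; models are compared under maximum likelihood with chi-square
#' reference distributions (df = parameter-count difference).
#'
#' @param data Model data.
#' @param spec The full [model_spec()].
#' @param alpha Retention threshold (default 0.05).
#' @return A list with `fit` (final `ln_fit`, ML), `spec`, and `trail` (a
#'   tibble recording every comparison).
#' @export
backward_simplify <- function(data, spec, alpha = 0.05) {
  simplify_engine(data, spec, alpha, function(full, red, term, st) {
    pchisq(st$lr, df = st$df, lower.tail = FALSE)
  })
}

#' Generalized variance inflation factors
#'
#' Computes per-term GVIFs from the correlation matrix of the fixed-effect
#' estimates (Fox & Monette determinant formula):
#' `GVIF = det(R11) det(R22) / det(R)`, where `R11` is the block for the
#' term's coefficients and `R22` the block for all other non-intercept
#' coefficients. Also reports `GVIF^(1/(2 df))`, comparable across terms of
#' different dimension.
#'
#' @param fit An `ln_fit` with at least two non-intercept terms.
#' @return A tibble with `term`, `df`, `gvif`, `gvif_adj`.
#' @export
gvif <- function(fit) {
  stopifnot(inherits(fit, "ln_fit"))
  asn <- fit$assign
  labels <- fit$term_labels
  keep <- asn > 0
  if (length(unique(asn[keep])) < 2) {
    stop_islandiv("GVIF needs at least two non-intercept terms")
  }
  V <- fit$vcov[keep, keep, drop = FALSE]
  R <- stats::cov2cor(V)
  detR <- det(R)
  if (!is.finite(detR) || detR < 1e-100) {
    stop_islandiv("singular fixed-effects correlation matrix",
                  class = "islandiv_singular_error")
  }
  asn <- asn[keep]
  purrr::map_dfr(sort(unique(asn)), function(a) {
    g <- asn == a
    gv <- det(R[g, g, drop = FALSE]) * det(R[!g, !g, drop = FALSE]) / detR
    tibble::tibble(term = labels[a], df = sum(g), gvif = gv,
                   gvif_adj = gv^(1 / (2 * sum(g))))
  })
}

# one-row fixed-effects design vector at specified factor levels;
# numeric covariates sit at `covariate_values` (default 0) and, when
# `zero_covariates`, every column from a term involving a numeric covariate
# is set to zero (the reference point for orthogonal polynomial bases)
design_row <- function(fit, at = list(), zero_covariates = TRUE,
                       covariate_values = list()) {
  tt <- fit$terms_fixed
  vars <- all.vars(tt)
  nd <- list()
  for (v in vars) {
    if (v %in% names(at)) {
      nd[[v]] <- at[[v]]
    } else if (v %in% names(fit$xlev)) {
      nd[[v]] <- fit$xlev[[v]][1]
    } else if (v %in% names(covariate_values)) {
      nd[[v]] <- covariate_values[[v]]
    } else {
      nd[[v]] <- 0
    }
  }
  nd <- tibble::as_tibble(nd)
  for (v in names(fit$xlev)) {
    if (!as.character(nd[[v]]) %in% fit$xlev[[v]]) {
      stop_islandiv(sprintf("level '%s' of '%s' not present in the fit",
                            as.character(nd[[v]]), v),
                    class = "islandiv_missing_level")
    }
    nd[[v]] <- factor(as.character(nd[[v]]), levels = fit$xlev[[v]])
  }
  mm <- model.matrix(tt, model.frame(tt, nd, xlev = fit$xlev))
  x <- mm[1, ]
  if (zero_covariates) {
    factors_only <- vapply(seq_along(fit$term_labels), function(a) {
      tl_vars <- unique(unlist(strsplit(fit$term_labels[a], ":",
                                        fixed = TRUE)))
      tl_base <- unique(unlist(lapply(tl_vars, function(tv) {
        av <- all.vars(str2lang(tv))
        if (length(av) == 0) tv else av
      })))
      all(tl_base %in% names(fit$xlev))
    }, logical(1))
    zero_cols <- fit$assign > 0 & !factors_only[pmax(fit$assign, 1)]
    x[zero_cols] <- 0
  }
  x
}

#' Post-hoc per-level slope tests
#'
#' For a fit containing a `land use x covariate` interaction, computes each
#' land-use level's slope of the focal covariate (the linear combination of
#' the main effect and that level's interaction coefficient), its standard
#' error from the coefficient covariance, a Wald chi-square (1 df) and
#' p-value.
#'
#' @param fit An `ln_fit`.
#' @param focal Name of the focal numeric covariate (e.g. an island trait).
#' @param by Name of the grouping factor (default `"land_use"`).
#' @return A tibble with `level`, `estimate`, `se`, `chisq`, `p_value`.
#' @export
posthoc_slopes <- function(fit, focal, by = "land_use") {
  stopifnot(inherits(fit, "ln_fit"))
  has_int <- any(vapply(strsplit(fit$term_labels, ":", fixed = TRUE),
                        function(v) focal %in% v && by %in% v, logical(1)))
  if (!has_int) {
    stop_islandiv(sprintf("fit contains no %s x %s interaction", by, focal))
  }
  levels_by <- fit$xlev[[by]]
  purrr::map_dfr(levels_by, function(lv) {
    at1 <- setNames(list(lv), by)
    x1 <- design_row(fit, at = c(at1, setNames(list(1), focal)),
                     zero_covariates = FALSE)
    x0 <- design_row(fit, at = c(at1, setNames(list(0), focal)),
                     zero_covariates = FALSE)
    d <- x1 - x0
    est <- sum(d * fit$coefficients)
    se <- sqrt(drop(t(d) %*% fit$vcov %*% d))
    chisq <- (est / se)^2
    tibble::tibble(level = lv, estimate = est, se = se, chisq = chisq,
                   p_value = pchisq(chisq, 1, lower.tail = FALSE))
  })
}
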