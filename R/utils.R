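#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats as.formula coef logLik median model.frame model.matrix
#'   pchisq plogis qlogis qnorm quantile rbinom reformulate rgamma rlnorm
#'   rnbinom rnorm rpois runif sd setNames terms update vcov delete.response
#'   AIC anova complete.cases ks.test
#' @importFrom utils head
NULL

# Seven land-use / use-intensity classes; PriMin is the minimally disturbed
# baseline throughout.
LAND_USES <- c("PriMin", "Primary", "Secondary", "Plantation",
               "Cropland", "Pasture", "Urban")

STATUS_LEVELS <- c("native", "alien", "unknown")

land_use_factor <- function(x) factor(as.character(x), levels = LAND_USES)

status_factor <- function(x) factor(as.character(x), levels = STATUS_LEVELS)

#' @keywords internal
stop_islandiv <- function(msg, class = "islandiv_error") {
  rlang::abort(msg, class = class)
}

# Deterministic child seeds: one master seed spawns a reproducible,
# order-independent stream of 31-bit seeds (one per permutation / replicate).
spawn_seeds <- function(master_seed, n) {
  stopifnot(length(master_seed) == 1, n >= 0)
  if (n == 0) return(integer(0))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

# check a data frame has the required columns; error names the missing ones
check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_islandiv(
      sprintf("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", ")),
      class = "islandiv_schema_error"
    )
  }
  invisible(df)
}
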