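# Shared internal helpers: the ordinal IHC vocabulary, seeded evaluation,
# and small argument validators used across modules.

#' Ordinal IHC expression levels
#'
#' The fixed ordinal vocabulary used for immunohistochemistry scoring,
#' from lowest to highest: `NotDetected < Low < Medium < High`.
#'
#' @return Character vector of the four canonical level names, in order.
#' @export
ihc_levels <- function() {
  c("NotDetected", "Low", "Medium", "High")
}

# ordinal rank, 0-based: NotDetected = 0 ... High = 3
.level_rank <- function(level) {
  match(level, ihc_levels()) - 1L
}

# Case/spacing-insensitive normalization of level strings to canonical form.
# "not detected", "Not_Detected", "NOTDETECTED" all map to "NotDetected".
.normalize_level <- function(x) {
  key <- tolower(gsub("[ _-]", "", x))
  canon <- ihc_levels()
  idx <- match(key, tolower(canon))
  out <- canon[idx]
  bad <- which(is.na(idx) & !is.na(x))
  if (length(bad)) {
    stop("unrecognized IHC level value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_scalar_num <- function(x, name, positive = FALSE, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("'%s' must be a single finite number", name)
  if (positive && x <= 0) .stopf("'%s' must be > 0", name)
  if (x < min) .stopf("'%s' must be >= %s", name, format(min))
  invisible(x)
}

.check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    .stopf("'%s' must be a single integer", name)
  if (x < min) .stopf("'%s' must be >= %d", name, min)
  invisible(as.integer(x))
}

.check_prob_vector <- function(p, name) {
  if (!is.numeric(p) || length(p) != 4L || anyNA(p) || any(p < 0))
    .stopf("'%s' must be 4 non-negative probabilities (one per IHC level)", name)
  if (abs(sum(p) - 1) > 1e-9)
    .stopf("'%s' must sum to 1 (got %.12g)", name, sum(p))
  invisible(as.numeric(p))
}
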