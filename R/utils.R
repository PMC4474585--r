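#' @useDynLib phenoNER, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim rpois runif
#' @importFrom utils head tail
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# wrap an objective returning value + "gradient" attribute so optim's fn
# and gr calls at the same parameter vector share one evaluation
cache_objective <- function(objective) {
  last_par <- NULL; last <- NULL
  fetch <- function(par) {
    if (is.null(last_par) || !identical(par, last_par)) {
      last <<- objective(par); last_par <<- par
    }
    last
  }
  list(fn = function(p) as.numeric(fetch(p)),
       gr = function(p) attr(fetch(p), "gradient"))
}

# Compressed word-shape class: runs of upper/lower/digit/other collapse to
# X/x/d/p, e.g. "Hypertension" -> "Xx", "12mg" -> "dx", "B-type" -> "Xpx".
word_shape <- function(x) {
  vapply(strsplit(x, ""), function(ch) {
    cls <- ifelse(grepl("[A-Z]", ch), "X",
           ifelse(grepl("[a-z]", ch), "x",
           ifelse(grepl("[0-9]", ch), "d", "p")))
    paste(rle(cls)$values, collapse = "")
  }, character(1))
}
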